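Package: aasig
Title: Detection of Aristolochic Acid Mutagenesis in Somatic Mutation Catalogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting the mutational footprint of aristolochic acid
    (AA) in per-sample somatic single-nucleotide-variant catalogs:
    trinucleotide-context spectra with exome opportunity adjustment,
    transcriptional strand-bias tallies for A>T mutations, exact one-sided
    binomial tests for A:T>T:A excess against a Signature-5 null with
    Benjamini-Hochberg false-discovery-rate control, cosine-similarity
    matching against a reference AA signature, and de novo signature
    extraction by opportunity-weighted Poisson matrix factorization with
    BIC model selection. Includes a synthetic catalog generator (signature
    mixtures, exome-like opportunities, mechanically realized strand bias)
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    withr,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
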