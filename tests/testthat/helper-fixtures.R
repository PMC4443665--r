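# Shared fixtures, built in code. The synthetic genome is comparatively
# expensive, so one instance is shared across test files.

shared_genome <- function() {
  if (is.null(.fixture_env$genome)) {
    .fixture_env$genome <- synthetic_genome(length = 1e5, seed = 424242)
  }
  .fixture_env$genome
}
.fixture_env <- new.env()

# one-sequence reference as a DNAStringSet
tiny_reference <- function(seq, name = "chr1") {
  ref <- Biostrings::DNAStringSet(seq)
  names(ref) <- name
  ref
}

# hand-built catalog rows
tiny_catalog <- function(pos, ref, alt, sample = "S1", chrom = "chr1",
                         tx_strand = NA_character_) {
  df <- data.frame(sample = sample, chrom = chrom, pos = as.integer(pos),
                   ref = ref, alt = alt, stringsAsFactors = FALSE)
  df$tx_strand <- tx_strand
  aasig:::new_catalog(df)
}

# brute-force per-window trinucleotide counter (independent of the
# Biostrings-based implementation)
brute_opportunities <- function(seq) {
  seq <- toupper(seq)
  tri32 <- pyrimidine_trinucleotides()
  out <- stats::setNames(numeric(32), tri32)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(s) paste(rev(unname(comp[strsplit(s, "")[[1]]])),
                          collapse = "")
  if (nchar(seq) < 3) return(out)
  for (i in 1:(nchar(seq) - 2)) {
    w <- substr(seq, i, i + 2)
    if (grepl("[^ACGT]", w)) next
    key <- if (substr(w, 2, 2) %in% c("C", "T")) w else rc(w)
    out[key] <- out[key] + 1
  }
  out
}
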