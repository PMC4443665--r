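---
title: "Methods: detecting aristolochic acid mutagenesis in SNV catalogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting aristolochic acid mutagenesis in SNV catalogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aasig)
```

# The problem

Aristolochic acid (AA) is a nephrotoxic, mutagenic compound of
*Aristolochia* plants used in herbal remedies. Its metabolites form bulky
adenine adducts; replication across the unrepaired adduct produces A:T>T:A
transversions. Two features distinguish AA mutagenesis from other
A:T>T:A-producing processes: a strong preference for the CAG and TAG
adenine contexts, and depletion of A>T mutations on the transcribed strand,
because transcription-coupled repair removes adducts from the template
(antisense) strand while adducts on the non-transcribed (coding) strand
persist. `aasig` formalizes both features into per-sample hypothesis tests
and complements them with de novo signature extraction.

# Spectra and opportunity adjustment

Every SNV is assigned to one of 96 channels: six pyrimidine-centred
substitution classes (C>A, C>G, C>T, T>A, T>C, T>G) times 16 flanking
contexts, 5' base outer and 3' base inner, each in A<C<G<T order.
Purine-centred representations are folded onto their reverse complement, so
`channel_index()` is a 2-to-1 map from the 192 stranded representations
onto 96 channels. The internal representation is always pyrimidine-centred;
the adenine-centric view of the A:T>T:A class (where the AA hotspots read
CAG and TAG) is produced only at the comparison boundary by
`at_ta_subvector()`. A single canonical index avoids double bookkeeping;
tests assert the bijection explicitly.

Raw channel counts confound process intensity with target abundance: a
territory rich in a trinucleotide yields more mutations in it under any
process. The opportunity vector `o` counts each pyrimidine-centred
trinucleotide (with its reverse complement) across the analyzed territory,
merged so shared bases are not double-counted, with `N`-containing windows
skipped. The adjusted spectrum is

$$ p_c = \frac{n_c / o_c}{\sum_d n_d / o_d}, $$

which is the scale on which signatures are defined throughout the package
(probability per trinucleotide occurrence, as in the factorization model
below). Which interval set defines the territory is the user's choice; the
opportunity table is a required input rather than a built-in constant, and
the synthetic genome provides one for testing.

# Strand-bias counting

Transcript annotations are 0-based half-open BED intervals with mandatory
strand; mutation records are 1-based (MAF/VCF convention), converted at the
boundary. A position covered only by plus-strand transcripts gets
`tx_strand = "plus"`, only minus `"minus"`, both `"ambiguous"`, neither
`"none"`. For an A:T>T:A mutation the mutated adenine lies on the
non-transcribed strand exactly when the forward-strand reference base (A or
T) matches the transcript orientation: forward A in a plus transcript, or
forward T in a minus transcript.

Ambiguously covered positions (bidirectionally transcribed loci) are
excluded from strand counting but kept in spectra. Both strands are
simultaneously transcribed there, so neither label is defensible; exclusion
is the conservative choice and the skipped count is reported.

# The exposure tests

**A:T>T:A excess.** The null is that all of a sample's A:T>T:A mutations
derive from Signature 5, whose A:T>T:A content is 12.5% — the highest among
signatures previously reported in bladder tumors, which makes the test
conservative against every other background process. The p-value is the
exact binomial upper tail $P(X \ge k)$, $X \sim \mathrm{Bin}(n, 0.125)$,
with $n$ the sample's total SNV count (all valid substitutions, not only
strand-annotated ones — the strand annotation covers a subset of the
territory and would otherwise leak into the excess test).

**Strand bias.** One-sided binomial with $p_0 = 1/2$ on the strand-labeled
A>T counts.

Both tails are computed by log-space summation of the exact mass
(`lchoose`-based log-sum-exp), so p-values retain about 13 significant
digits down to the smallest magnitudes the data produce (an AA-saturated
exome can reach $10^{-230}$ and below); values under `1e-300` display as
`"0"` in the formatted table while `log10_p` is preserved in machine
output. A frozen arbitrary-precision oracle grid (computed with mpmath at
60 decimal digits) pins the implementation to 10 significant digits over
$n \le 2500$.

**FDR and the call.** The two p-value families are adjusted separately by
Benjamini–Hochberg across all samples in the run (`stats::p.adjust`,
`fdr`). The final call conjoins three conditions:

* `fdr_excess < 0.05` and `fdr_strand < 0.05` and cosine ≥ cutoff →
  `AA-exposed`;
* both FDRs pass, cosine fails (or is undefined) →
  `AA-possible-dissimilar` — a strong strand-biased A:T>T:A excess whose
  context profile does not match AA, i.e. a candidate for another adenine
  mutagen;
* otherwise `not-detected`.

The conjunction rule is this package's formalization: the source analyses
report the two tests side by side and flag the dissimilar case narratively
rather than stating a formal decision rule. Making the rule explicit (and
configurable) seemed preferable to leaving classification to the reader.

**Cosine cutoff 0.90.** Observed AA-matched tumors cluster at cosine
0.93–0.99 against a reference AA profile while the known dissimilar case
sits near 0.53, leaving a wide margin; 0.90 splits it with room on both
sides and is exposed as a parameter and recorded in output. The cosine is
computed on opportunity-adjusted adenine-centric 16-vectors (signatures
live on the adjusted scale); a raw-count option exists. The reference
profile defaults to the bundled AA fixture's A:T>T:A profile and accepts
any extracted signature instead — with real cohorts one would extract the
signature de novo and feed it back.

# Opportunity-weighted Poisson factorization

De novo extraction uses the model

$$ V_{cg} \sim \mathrm{Poisson}\!\left(o_c \sum_k S_{ck} E_{kg}\right), $$

with $S$ column-stochastic (96 × K) and $E \ge 0$ (K × G, expected
mutations). This is the likelihood that EMu-style extraction and
KL-divergence NMF both instantiate; it is fitted here directly by the
weighted multiplicative updates

$$ S_{ck} \leftarrow S_{ck}
   \frac{\sum_g (V_{cg}/\Lambda_{cg})\,E_{kg}}{o_c \sum_g E_{kg}}, \qquad
   E_{kg} \leftarrow E_{kg}
   \frac{\sum_c (V_{cg}/\Lambda_{cg})\,S_{ck}}{\sum_c o_c S_{ck}}, $$

$\Lambda = SE$, which monotonically non-decrease the log-likelihood
(asserted along the stored trace in tests). Numerical choices: entries
initialized uniform(0.1, 1) from a seeded generator with exposures scaled
to the data's magnitude; denominators floored at `1e-12`; entries below
`1e-10` zeroed at the end before renormalization; convergence when the
relative log-likelihood change over ten iterations falls below `1e-8`, cap
5000 iterations (a fit still moving is returned flagged
`converged = FALSE`); default 10 random restarts, best likelihood wins;
identical seeds give bitwise-identical results, with the caller's RNG state
restored afterwards.

The number of signatures is selected over K = 2…8 by
$\mathrm{BIC}(K) = -2\,\mathrm{LL} + (96K + KG - K)\ln \sum V$ (each
stochastic column loses one free parameter). All per-K scores are reported;
on data generated from a single process the criterion is minimized at the
range floor, and the per-K table makes the absence of improvement visible.

Identifiability caveats: the factorization is unique only up to column
permutation and scale, which the package fixes by column-stochastic `S` and
columns ordered by total attributed mutations. Exact (noiseless) instances
are non-unique unless the ground truth has both anchor channels and pure
samples — the recovery test constructs such an instance deliberately; on
realistic Poisson-noise data with well-separated signatures, matched-column
cosines ≥ 0.95 are achieved without that construction. `attribute_exposures()`
re-fits only the exposure column with `S` frozen, giving per-sample
attribution proportions; greedy cosine pairing (`compare_signatures()`)
aligns independently obtained signature sets.

# The synthetic-data generator

The generator exists so every stage — context lookup, strand annotation,
spectra, tests, factorization — can be validated end to end with known
truth. It emulates:

* **Signature mixtures.** Four bundled fixtures: AA-like (0.90 A:T>T:A
  mass peaked at CAG/TAG), CpG>TpG deamination (C>T at NCG), APOBEC (C>T
  and C>G at TCW), and a flat Signature-5-like background whose A:T>T:A
  mass is 0.125 *exactly* (`2^-7`, exact in binary), matching the test's
  null proportion. Channel draws are multinomial over the
  opportunity-weighted mixed signature, mirroring the Poisson model.
* **Opportunity structure.** A uniform-random 100 kb chromosome carries
  every trinucleotide at usable frequency (~3000 windows each), so the
  opportunity vector is realistic in form but approximately uniform —
  which also keeps the raw A:T>T:A fraction of pure-background samples at
  the nominal 12.5%.
* **Mechanical strand bias.** Non-overlapping plus/minus transcripts tile
  80% of the territory; an A:T>T:A mutation is placed, with probability
  `q`, at a site whose adenine falls on the non-transcribed strand of the
  covering transcript. The bias is realized through placement, never by
  label stamping, so `annotate_tx_strand()` is exercised for real. `q`
  defaults to 0.75 for exposed samples in the power cohort, the value
  observed in heavily mutagenized tumors (0.72–0.77).
* **Burden.** Default log-uniform on [100, 2000] mutations per sample,
  spanning the exome totals the analysis targets (observed range 59–2386).

It does **not** emulate real exome interval structure, regional
mutation-rate covariates (replication timing, expression level),
within-gene repair gradients, germline contamination, or sequencing error.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated generative model, not robustness to those
real-data complications; with real catalogs the quality of the opportunity
table and transcript annotation is the user's responsibility.

# Validation problem sizes

The shipped tests validate: type-I control of the excess test on 500 pure
Signature-5 catalogs of 500 mutations (empirical rejection at
$\alpha = 0.05$ stays below $0.05 + 2\,\mathrm{SE}$; the test is
conservative by discreteness); sensitivity 100% and specificity ≥ 99% for
`classify_exposure()` on 50 replicate cohorts of 10 exposed (70% AA,
burden 700, q = 0.75) and 90 unexposed samples; and BIC selection of K = 3
with matched cosines ≥ 0.95 on 60 samples drawn from three signatures at
burdens 300–1000. These sizes give stable operating-characteristic
estimates while keeping the default suite quick on a laptop.

# Degenerate inputs and edge behavior

Empty catalogs are flagged, not silently passed; positions at sequence
edges, windows containing `N`, and reference-allele mismatches invalidate
a record's context (excluded from spectra, counted in messages); a zero
opportunity under observed mutations is an error naming the channel; a
sample with no A:T>T:A mass has an undefined cosine and can never be
called `AA-exposed`; all-zero spectra and zero-burden simulations return
explicit empty results. BH adjustment passes `NA` p-values through without
letting them enter the family.

# Known limitations

* The Signature-5 null is a point null at 12.5%; cohorts whose background
  A:T>T:A content genuinely exceeds it (other adenine mutagens) will
  inflate excess calls — the strand-bias conjunction and the cosine gate
  are the guard.
* The factorization is a maximum-likelihood point estimate; it reports no
  uncertainty on signatures or exposures.
* BIC over-penalizes weak signatures at small cohort sizes; the per-K
  table should be inspected rather than trusting the argmin blindly.
* Strand-bias power depends on transcript coverage of the territory;
  sparsely annotated genomes lose A>T mutations to `tx_strand = "none"`.
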