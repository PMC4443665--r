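#' Null hypothesis parameters for the AA exposure tests
#'
#' `p0_excess` is the A:T>T:A proportion of Signature 5 (12.5%), the most
#' A:T>T:A-rich signature previously seen in bladder tumors, which makes the
#' excess test conservative. `p0_strand` is the equal-strands null for the
#' A>T strand-bias test. `fdr_threshold` is the Benjamini-Hochberg FDR at
#' which exposure is called.
#'
#' @param p0_excess,p0_strand,fdr_threshold Probabilities in (0, 1).
#' @return A list of class `aa_null_spec`.
#' @export
null_spec <- function(p0_excess = 0.125, p0_strand = 0.5,
                      fdr_threshold = 0.05) {
  stopifnot(p0_excess > 0, p0_excess < 1, p0_strand > 0, p0_strand < 1,
            fdr_threshold > 0, fdr_threshold < 1)
  structure(list(p0_excess = p0_excess, p0_strand = p0_strand,
                 fdr_threshold = fdr_threshold), class = "aa_null_spec")
}

#' Exact one-sided binomial upper tail
#'
#' Computes `P(X >= k)` for `X ~ Binomial(n, p0)` by summation of the exact
#' probability mass in log space (log-sum-exp over `log C(n,i) + i log p0 +
#' (n-i) log(1-p0)`), so values far below the double-precision underflow
#' threshold are preserved via their log10.
#'
#' @param k Number of successes observed (0 <= k <= n).
#' @param n Number of trials (>= 1).
#' @param p0 Null success probability.
#' @return List with `p` (the tail probability; 0 when below ~1e-320) and
#'   `log10_p` (always finite for k <= n).
#' @export
#' @examples
#' binom_upper_tail(38, 42, 0.5)$p  # ~2.8e-8
binom_upper_tail <- function(k, n, p0) {
  stopifnot(length(k) == 1, length(n) == 1, n >= 1, k >= 0, k <= n,
            p0 > 0, p0 < 1)
  k <- as.integer(k); n <- as.integer(n)
  if (k == 0) return(list(p = 1, log10_p = 0))
  i <- k:n
  lt <- lchoose(n, i) + i * log(p0) + (n - i) * log1p(-p0)
  m <- max(lt)
  lp <- m + log(sum(exp(lt - m)))
  lp <- min(lp, 0)  # guard against rounding above 1
  list(p = exp(lp), log10_p = lp / log(10))
}

#' Test for A:T>T:A excess against the Signature-5 null
#'
#' The probability that Signature 5 alone (A:T>T:A proportion
#' `null$p0_excess`, default 12.5%), with no AA contribution, produced at
#' least the observed number of A:T>T:A mutations among all the sample's
#' SNVs.
#'
#' @param n_atta Observed A:T>T:A count.
#' @param n_total Total SNV count of the sample (all valid substitutions,
#'   not only strand-annotated ones).
#' @param null A [null_spec()].
#' @return As [binom_upper_tail()]; `p` and `log10_p` are `NA` when
#'   `n_total` is 0.
#' @export
aa_excess_test <- function(n_atta, n_total, null = null_spec()) {
  if (n_total == 0) return(list(p = NA_real_, log10_p = NA_real_))
  stopifnot(n_atta <= n_total)
  binom_upper_tail(n_atta, n_total, null$p0_excess)
}

#' Test for A>T strand bias
#'
#' One-sided binomial test of an excess of A>T mutations on the
#' non-transcribed strand against the null of equal numbers on both
#' strands: `P(X >= n_non)` with `X ~ Binomial(n_non + n_tr, 0.5)`.
#'
#' @param counts A list from [strand_counts()] (fields `n_nontranscribed`,
#'   `n_transcribed`).
#' @param null A [null_spec()].
#' @return As [binom_upper_tail()]; `NA` when no strand-annotated A>T
#'   mutations exist.
#' @export
strand_bias_test <- function(counts, null = null_spec()) {
  n <- counts$n_nontranscribed + counts$n_transcribed
  if (n == 0) return(list(p = NA_real_, log10_p = NA_real_))
  binom_upper_tail(counts$n_nontranscribed, n, null$p0_strand)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values in input order (`stats::p.adjust`, method
#' `"fdr"`). `NA` entries are passed through as `NA` without entering the
#' family.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) stop("empty p-value list")
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "fdr")
}

#' Cosine similarity between nonnegative spectra
#'
#' @param u,v Nonnegative numeric vectors of equal length, each with at
#'   least one positive entry.
#' @return `u . v / (|u| |v|)`, in \[0, 1\] for nonnegative inputs; `NA`
#'   if either vector is all zero or contains `NA`.
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  if (anyNA(u) || anyNA(v)) return(NA_real_)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  sum(u * v) / (nu * nv)
}

#' Per-sample AA exposure statistics
#'
#' Runs the two binomial tests and the cosine comparison for every sample of
#' an annotated catalog, then adjusts each p-value family (excess, strand)
#' across all samples by Benjamini-Hochberg.
#'
#' @param catalog A catalog with contexts and `tx_strand` attached.
#' @param opportunities 32- or 96-long opportunity vector (for the adjusted
#'   A:T>T:A subvector entering the cosine).
#' @param aa_reference Adenine-centric 16-vector of the reference AA
#'   signature's A:T>T:A profile (see [aa_reference_profile()]), or `NULL`
#'   to skip the cosine.
#' @param null A [null_spec()].
#' @param adjust_cosine Compute the cosine on opportunity-adjusted
#'   subvectors (default) or on raw counts.
#' @return `data.frame` of class `aa_exposure_results`, one row per sample:
#'   counts, raw and log10 p-values, FDRs, non-transcribed fraction and
#'   cosine similarity.
#' @export
test_exposure <- function(catalog, opportunities, aa_reference = NULL,
                          null = null_spec(), adjust_cosine = TRUE) {
  samples <- unique(catalog$sample)
  rows <- lapply(samples, function(s) {
    spec <- suppressMessages(suppressWarnings(build_spectrum(catalog, s)))
    n_total <- sum(spec)
    n_atta <- sum(spec[at_ta_channels()])
    ex <- aa_excess_test(n_atta, n_total, null)
    sc <- strand_counts(catalog, s)
    sb <- strand_bias_test(sc, null)
    n_str <- sc$n_nontranscribed + sc$n_transcribed
    cosine <- NA_real_
    if (!is.null(aa_reference) && n_atta > 0) {
      v <- if (adjust_cosine) opportunity_adjust(spec, opportunities) else spec
      cosine <- cosine_similarity(at_ta_subvector(v), aa_reference)
    }
    data.frame(
      sample = s, n_total = n_total, n_atta = n_atta,
      prop_atta = if (n_total > 0) n_atta / n_total else NA_real_,
      p_excess = ex$p, log10_p_excess = ex$log10_p,
      n_non = sc$n_nontranscribed, n_tr = sc$n_transcribed,
      frac_non = if (n_str > 0) sc$n_nontranscribed / n_str else NA_real_,
      p_strand = sb$p, log10_p_strand = sb$log10_p,
      cosine_aa = cosine, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr_excess <- bh_fdr(res$p_excess)
  res$fdr_strand <- bh_fdr(res$p_strand)
  class(res) <- c("aa_exposure_results", "data.frame")
  res
}

#' Call AA exposure from test results
#'
#' A sample is called `AA-exposed` when both FDRs fall below
#' `null$fdr_threshold` and its A:T>T:A profile resembles the reference AA
#' signature (`cosine_aa >= cosine_cutoff`); `AA-possible-dissimilar` when
#' both FDRs pass but the profile does not match (a strong A:T>T:A excess of
#' possibly different origin); `not-detected` otherwise, including when the
#' cosine is undefined for lack of A:T>T:A mutations. The conjunction rule
#' is this package's formalization; see the methods vignette.
#'
#' @param results An `aa_exposure_results` table from [test_exposure()].
#' @param null A [null_spec()].
#' @param cosine_cutoff Similarity required to attribute the excess to AA.
#' @return `results` with a `call` column added.
#' @export
classify_exposure <- function(results, null = null_spec(),
                              cosine_cutoff = 0.90) {
  fdr_ok <- !is.na(results$fdr_excess) & results$fdr_excess < null$fdr_threshold &
    !is.na(results$fdr_strand) & results$fdr_strand < null$fdr_threshold
  cos_ok <- !is.na(results$cosine_aa) & results$cosine_aa >= cosine_cutoff
  results$call <- ifelse(fdr_ok & cos_ok, "AA-exposed",
                  ifelse(fdr_ok, "AA-possible-dissimilar", "not-detected"))
  attr(results, "cosine_cutoff") <- cosine_cutoff
  results
}

#' Format a p-value the way result tables print it
#'
#' One significant figure in scientific notation (`3E-08`); values with
#' log10 below -300 print as `"0"`; probabilities >= 0.095 print with two
#' decimals.
#'
#' @param log10_p log10 of the p-value.
#' @return Character scalar.
#' @export
format_pvalue <- function(log10_p) {
  if (is.na(log10_p)) return("NA")
  if (log10_p < -300) return("0")
  p <- 10^log10_p
  if (p >= 0.095) return(formatC(p, format = "f", digits = 2))
  toupper(formatC(p, format = "e", digits = 0))
}
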