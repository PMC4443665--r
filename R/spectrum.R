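#' Build a per-sample 96-channel spectrum
#'
#' Counts the sample's valid SNVs in each of the 96 pyrimidine-centred
#' trinucleotide channels. Records flagged `valid_context = FALSE` are
#' excluded (their number is reported via `message()`).
#'
#' @param catalog A catalog `data.frame` with contexts attached.
#' @param sample Sample identifier; must be present in the catalog.
#' @return Named integer vector of length 96 (see [channel_names()]) with
#'   attribute `sample`.
#' @export
build_spectrum <- function(catalog, sample) {
  if (!sample %in% catalog$sample) stop("unknown sample: ", sample)
  rows <- catalog[catalog$sample == sample, , drop = FALSE]
  valid <- !is.na(rows$valid_context) & rows$valid_context
  if (any(!valid)) {
    message(sum(!valid), " record(s) with invalid context excluded for ",
            sample)
  }
  rows <- rows[valid, , drop = FALSE]
  counts <- integer(96)
  if (nrow(rows) > 0) {
    idx <- channel_index(rows$ref, rows$alt, rows$context5, rows$context3)
    counts <- tabulate(idx, nbins = 96)
  }
  out <- setNames(as.integer(counts), channel_names())
  attr(out, "sample") <- sample
  if (sum(out) == 0) warning("all-zero spectrum for sample ", sample)
  out
}

#' Multi-sample spectrum matrix
#'
#' @param catalog A catalog with contexts attached.
#' @param samples Samples to include; defaults to all present, in order of
#'   first appearance.
#' @return 96 x G integer matrix, rows named by channel, columns by sample.
#' @export
spectrum_matrix <- function(catalog, samples = unique(catalog$sample)) {
  m <- vapply(samples, function(s) suppressMessages(build_spectrum(catalog, s)),
              integer(96))
  m <- matrix(m, nrow = 96, dimnames = list(channel_names(), samples))
  m
}

#' Opportunity-adjust a spectrum
#'
#' Divides each channel count by its trinucleotide opportunity and
#' renormalizes, giving the proportion of mutations per channel corrected
#' for the trinucleotide composition of the analyzed territory:
#' `p_c = (n_c / o_c) / sum_d (n_d / o_d)`.
#'
#' @param spectrum Named 96-vector of counts (from [build_spectrum()]), or
#'   any nonnegative 96-vector.
#' @param opportunities 32- or 96-long opportunity vector.
#' @return Numeric 96-vector of proportions summing to 1 (zero where counts
#'   are zero).
#' @export
opportunity_adjust <- function(spectrum, opportunities) {
  stopifnot(length(spectrum) == 96)
  o <- expand_opportunities(opportunities)
  bad <- which(spectrum > 0 & o <= 0)
  if (length(bad) > 0) {
    stop("zero opportunity for channel with mutations: ",
         channel_names()[bad[1]])
  }
  w <- ifelse(o > 0, as.numeric(spectrum) / o, 0)
  tot <- sum(w)
  if (tot == 0) return(setNames(numeric(96), channel_names()))
  setNames(w / tot, channel_names())
}

#' Extract the adenine-centric A:T>T:A subvector
#'
#' Pulls the 16 `T>A` channels out of a (typically opportunity-adjusted)
#' spectrum, re-expressed in adenine-centric order (the context read along
#' the strand carrying the mutated adenine, so the AA hotspots appear as
#' `CAG` and `TAG`), renormalized to sum 1.
#'
#' @param spectrum Numeric 96-vector (adjusted proportions or raw counts).
#' @return Named numeric 16-vector summing to 1, or an all-`NA` vector with
#'   attribute `undefined = TRUE` when the A:T>T:A mass is zero (cosine
#'   similarity is undefined downstream).
#' @export
at_ta_subvector <- function(spectrum) {
  stopifnot(length(spectrum) == 96)
  map <- adenine_context_channels()
  v <- as.numeric(spectrum)[map]
  names(v) <- names(map)
  tot <- sum(v)
  if (tot == 0) {
    v[] <- NA_real_
    attr(v, "undefined") <- TRUE
    return(v)
  }
  v / tot
}

#' Tally A>T mutations by transcription strand
#'
#' For each A:T>T:A mutation with an unambiguous transcript strand, decides
#' whether the mutated adenine lies on the non-transcribed (coding/sense)
#' strand: a forward-strand `A` in a plus-strand transcript is
#' non-transcribed, in a minus-strand transcript transcribed; a
#' forward-strand `T` mirrors this (its adenine sits on the reverse strand).
#' Mutations with `tx_strand` `"ambiguous"` or `"none"` are skipped and
#' counted in the `n_skipped` attribute.
#'
#' @param catalog A catalog with `tx_strand` annotated.
#' @param sample Sample identifier.
#' @return List with `n_nontranscribed`, `n_transcribed`, `n_skipped`,
#'   `sample`.
#' @export
strand_counts <- function(catalog, sample) {
  if (!sample %in% catalog$sample) stop("unknown sample: ", sample)
  rows <- catalog[catalog$sample == sample, , drop = FALSE]
  is_at <- (rows$ref == "A" & rows$alt == "T") |
           (rows$ref == "T" & rows$alt == "A")
  rows <- rows[is_at, , drop = FALSE]
  usable <- rows$tx_strand %in% c("plus", "minus")
  non <- sum((rows$ref == "A" & rows$tx_strand == "plus") |
             (rows$ref == "T" & rows$tx_strand == "minus"))
  tr <- sum((rows$ref == "A" & rows$tx_strand == "minus") |
            (rows$ref == "T" & rows$tx_strand == "plus"))
  list(n_nontranscribed = as.integer(non), n_transcribed = as.integer(tr),
       n_skipped = as.integer(sum(!usable)), sample = sample)
}

#' Write a spectrum TSV
#'
#' 96 rows with columns `class`, `context`, `count` and, when an opportunity
#' vector is supplied, `adjusted_proportion`.
#'
#' @param spectrum Named 96-vector of counts.
#' @param path Output path.
#' @param opportunities Optional opportunity vector for the adjusted column.
#' @export
write_spectrum <- function(spectrum, path, opportunities = NULL) {
  ctx <- channel_contexts()
  df <- data.frame(class = ctx$class,
                   context = paste0(ctx$context5, ctx$ref, ctx$context3),
                   count = as.numeric(spectrum))
  if (!is.null(opportunities)) {
    df$adjusted_proportion <- opportunity_adjust(spectrum, opportunities)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
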