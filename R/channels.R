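#' @importFrom stats pbinom p.adjust rmultinom runif setNames rbinom
#' @importFrom utils read.delim write.table packageVersion
NULL

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")
SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
PYR_CENTERS <- c(rep("C", 3), rep("T", 3))

comp_base <- function(x) unname(COMP[x])

revcomp <- function(s) {
  vapply(strsplit(s, ""), function(b) paste(rev(unname(COMP[b])), collapse = ""),
         character(1))
}

# vectorized reverse complement for trinucleotide strings
revcomp3 <- function(s) {
  paste0(unname(COMP[substr(s, 3, 3)]),
         unname(COMP[substr(s, 2, 2)]),
         unname(COMP[substr(s, 1, 1)]))
}

#' Canonical 96-channel layout
#'
#' Channels are pyrimidine-centred (COSMIC convention): six substitution
#' classes `C>A, C>G, C>T, T>A, T>C, T>G`, each across 16 flanking contexts
#' ordered by the 5' base then the 3' base, each in `A < C < G < T` order.
#'
#' @return Character vector of 96 labels like `"A[C>A]A"`.
#' @export
channel_names <- function() {
  unlist(lapply(SUB_CLASSES, function(cl) {
    ctr <- substr(cl, 1, 1)
    unlist(lapply(BASES, function(f5) paste0(f5, "[", cl, "]", BASES)))
  }))
}

#' The 32 pyrimidine-centred trinucleotides
#'
#' Ordered to match [channel_names()]: the 16 `NCN` contexts first, then the
#' 16 `NTN` contexts, 5' base outer and 3' base inner, `A < C < G < T`.
#'
#' @return Character vector of length 32.
#' @export
pyrimidine_trinucleotides <- function() {
  unlist(lapply(c("C", "T"), function(ctr)
    unlist(lapply(BASES, function(f5) paste0(f5, ctr, BASES)))))
}

# context (5', 3') for each of the 96 channels, pyrimidine-centred
channel_contexts <- function() {
  lab <- channel_names()
  data.frame(
    channel = seq_along(lab),
    label = lab,
    class = rep(SUB_CLASSES, each = 16),
    ref = rep(PYR_CENTERS, each = 16),
    alt = rep(substr(SUB_CLASSES, 3, 3), each = 16),
    context5 = rep(rep(BASES, each = 4), 6),
    context3 = rep(BASES, 24),
    stringsAsFactors = FALSE
  )
}

#' Map a substitution with context to its 96-channel index
#'
#' Purine-centred substitutions are folded onto their pyrimidine-centred
#' reverse complement: ref `G`/`A` becomes `C`/`T` with the flanking bases
#' swapped and complemented. Reverse-complement pairs therefore always map to
#' the same channel. The index is 1-based, matching R vector indexing; the
#' order is that of [channel_names()].
#'
#' @param ref,alt Reference and alternate base, single characters in
#'   `A,C,G,T`; `ref != alt`. Vectorized.
#' @param context5,context3 The forward-strand bases flanking the mutated
#'   position 5' and 3'.
#' @return Integer vector of channel indices in `1:96`; `NA` where any base
#'   is not a valid nucleotide.
#' @export
#' @examples
#' channel_index("C", "A", "A", "A")  # 1
#' channel_index("G", "T", "T", "T")  # 1, the reverse complement
channel_index <- function(ref, alt, context5, context3) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(context5) == n, length(context3) == n)
  ok <- ref %in% BASES & alt %in% BASES & context5 %in% BASES &
    context3 %in% BASES & ref != alt
  if (n == 1 && !ok) {
    if (ref == alt) stop("ref and alt must differ")
    stop("invalid base in (", ref, ",", alt, ",", context5, ",", context3, ")")
  }
  idx <- rep(NA_integer_, n)
  if (!any(ok)) return(idx)
  r <- ref[ok]; a <- alt[ok]; c5 <- context5[ok]; c3 <- context3[ok]
  pur <- r %in% c("A", "G")
  r2 <- ifelse(pur, unname(COMP[r]), r)
  a2 <- ifelse(pur, unname(COMP[a]), a)
  c5_2 <- ifelse(pur, unname(COMP[c3]), c5)
  c3_2 <- ifelse(pur, unname(COMP[c5]), c3)
  cls <- match(paste0(r2, ">", a2), SUB_CLASSES)
  idx[ok] <- (cls - 1L) * 16L + (match(c5_2, BASES) - 1L) * 4L +
    match(c3_2, BASES)
  idx
}

# The 16 T>A channels (A:T>T:A class) in canonical channel order
at_ta_channels <- function() which(channel_contexts()$class == "T>A")

#' Adenine-centric ordering of the A:T>T:A channels
#'
#' The 16 `T>A` channels re-indexed by the context around the mutated
#' adenine (the reverse complement of the pyrimidine context), ordered by the
#' adenine's 5' then 3' flanking base, `A < C < G < T`. This is the display
#' convention in which the AA hotspot contexts read `CAG` and `TAG`.
#'
#' @return Named integer vector: names are adenine-centric trinucleotides
#'   (`"AAA"`, `"AAC"`, ...), values are the corresponding canonical channel
#'   indices in `1:96`.
#' @export
adenine_context_channels <- function() {
  ctx <- channel_contexts()
  ta <- ctx[ctx$class == "T>A", ]
  ade <- paste0(unname(COMP[ta$context3]), "A", unname(COMP[ta$context5]))
  ord <- order(ade)
  setNames(ta$channel[ord], ade[ord])
}
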