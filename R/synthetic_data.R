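# Synthetic mutation catalogs with the statistical structure the analysis
# assumes: trinucleotide-signature mixtures, exome-like opportunities, and
# mechanically realized transcriptional strand bias. Signatures here live on
# the opportunity-adjusted scale (probability per trinucleotide occurrence);
# the generator multiplies by the territory's opportunities, mirroring the
# Poisson factorization model.

#' Bundled fixture signatures
#'
#' Four column-stochastic 96-channel signatures used as simulation ground
#' truth:
#'
#' * `AA` — aristolochic-acid-like: >= 0.85 of its mass on A:T>T:A
#'   channels, peaked at the `CAG` and `TAG` adenine contexts.
#' * `CpG` — deamination of 5-methylcytosine: C>T at `NCG`.
#' * `APOBEC` — C>T and C>G at `TCW` (`W` = A or T).
#' * `Sig5` — a flat Signature-5-like background whose A:T>T:A mass is
#'   0.125 exactly (the null proportion of the exposure test).
#'
#' @return 96 x 4 matrix, rows [channel_names()], columns
#'   `AA, CpG, APOBEC, Sig5`.
#' @export
bundled_signatures <- function() {
  ctx <- channel_contexts()
  lab <- channel_names()
  zero <- setNames(numeric(96), lab)
  ade <- adenine_context_channels()  # adenine context -> channel

  # AA-like: mass 0.90 on A:T>T:A with CAG/TAG preference, 0.10 flat rest
  aa_w <- c(CAG = 5, TAG = 4, CAA = 1.2, CAC = 1, CAT = 1, TAA = 1,
            TAC = 0.8, TAT = 0.8, AAG = 0.8, GAG = 0.6, AAA = 0.5,
            AAC = 0.5, AAT = 0.5, GAA = 0.5, GAC = 0.4, GAT = 0.4)
  aa <- zero
  aa[ade[names(aa_w)]] <- 0.90 * aa_w / sum(aa_w)
  non_at <- setdiff(seq_len(96), at_ta_channels())
  aa[non_at] <- aa[non_at] + 0.10 / length(non_at)

  # CpG deamination: C>T at NCG
  cpg <- zero
  ncg <- which(ctx$class == "C>T" & ctx$context3 == "G")
  cpg[ncg] <- 0.80 / length(ncg)
  rest <- setdiff(seq_len(96), ncg)
  cpg[rest] <- 0.20 / length(rest)

  # APOBEC: C>T and C>G at TCA / TCT
  apo <- zero
  tcw_ct <- which(ctx$class == "C>T" & ctx$context5 == "T" &
                    ctx$context3 %in% c("A", "T"))
  tcw_cg <- which(ctx$class == "C>G" & ctx$context5 == "T" &
                    ctx$context3 %in% c("A", "T"))
  apo[tcw_ct] <- 0.25
  apo[tcw_cg] <- 0.15
  rest <- setdiff(seq_len(96), c(tcw_ct, tcw_cg))
  apo[rest] <- 0.20 / length(rest)

  # Signature-5-like: flat, with A:T>T:A mass exactly 1/8
  sig5 <- zero
  at <- at_ta_channels()
  sig5[at] <- 0.125 / 16          # = 2^-7, exact in binary
  sig5[non_at] <- 0.875 / length(non_at)

  m <- cbind(AA = aa, CpG = cpg, APOBEC = apo, Sig5 = sig5)
  rownames(m) <- lab
  m
}

#' Adenine-centric A:T>T:A profile of the reference AA signature
#'
#' The 16-vector against which sample subvectors are compared by cosine
#' similarity. Defaults to the bundled AA fixture's profile; any
#' column-stochastic 96-vector can be supplied instead (e.g. a de novo
#' extracted signature).
#'
#' @param signature 96-vector; default the bundled `AA` signature.
#' @return Named adenine-centric 16-vector summing to 1.
#' @export
aa_reference_profile <- function(signature = bundled_signatures()[, "AA"]) {
  at_ta_subvector(signature)
}

#' Generate a synthetic reference genome with transcripts
#'
#' A uniform-random chromosome (all 32 trinucleotides well represented)
#' tiled with non-overlapping plus- and minus-strand "transcripts" covering
#' `tx_fraction` of the territory, plus the position index the catalog
#' simulator draws from.
#'
#' @param length Chromosome length in bp.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @param tx_fraction Fraction of territory covered by transcripts.
#' @return An `aa_genome` list: `seq` (`DNAStringSet`), `transcripts`
#'   (`GRanges`), `opportunities` (32-vector), and internal site pools.
#' @export
synthetic_genome <- function(length = 1e5, seed = NULL, tx_fraction = 0.8) {
  if (!is.null(seed)) local_seed(seed)
  L <- as.integer(length)
  s <- sample(BASES, L, replace = TRUE)
  dna <- Biostrings::DNAStringSet(paste(s, collapse = ""))
  names(dna) <- "chrS1"

  # repeating 2500 bp unit: 1000 plus, 250 gap, 1000 minus, 250 gap
  unit <- 2500L
  tx_w <- as.integer(round(unit * tx_fraction / 2))
  starts0 <- seq(0L, L - unit, by = unit)  # 0-based
  plus_start <- starts0 + 1L
  minus_start <- starts0 + tx_w + as.integer((unit - 2L * tx_w) / 2) + 1L
  gr <- GenomicRanges::GRanges(
    "chrS1",
    IRanges::IRanges(start = c(plus_start, minus_start), width = tx_w),
    strand = rep(c("+", "-"), each = length(starts0)))
  gr <- sort(gr, ignore.strand = TRUE)
  names(gr) <- paste0("tx", seq_along(gr))

  strand_at <- rep(0L, L)  # 0 none, 1 plus, 2 minus
  st <- as.character(GenomicRanges::strand(gr))
  for (i in seq_along(gr)) {
    strand_at[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <-
      if (st[i] == "+") 1L else 2L
  }

  tri32 <- pyrimidine_trinucleotides()
  pos <- 2:(L - 1L)
  tri_fwd <- paste0(s[pos - 1L], s[pos], s[pos + 1L])
  center_pyr <- s[pos] %in% c("C", "T")
  tri_pyr <- tri_fwd
  tri_pyr[!center_pyr] <- revcomp3(tri_fwd[!center_pyr])
  tri_id <- match(tri_pyr, tri32)
  str_code <- strand_at[pos]

  pools <- vector("list", 32)
  for (t in 1:32) {
    sel <- which(tri_id == t)
    p <- pos[sel]; cp <- center_pyr[sel]; sc <- str_code[sel]
    pools[[t]] <- list(
      all = p,
      all_pyr = cp,
      # A:T>T:A placement pools: adenine on non-transcribed vs transcribed
      at_non = list(pos = p[(!cp & sc == 1L) | (cp & sc == 2L)],
                    pyr = cp[(!cp & sc == 1L) | (cp & sc == 2L)]),
      at_tx = list(pos = p[(!cp & sc == 2L) | (cp & sc == 1L)],
                   pyr = cp[(!cp & sc == 2L) | (cp & sc == 1L)]))
  }
  names(pools) <- tri32

  structure(list(seq = dna, transcripts = gr,
                 opportunities = compute_opportunities(dna),
                 pools = pools, length = L),
            class = "aa_genome")
}

#' Configuration for the catalog simulator
#'
#' @param samples Sample names, or an integer count (names `S001`, ...).
#' @param burden Per-sample mutation count: a scalar, a vector (recycled),
#'   or `NULL` for the default log-uniform draw on \[100, 2000\] (the span
#'   of exome burdens the analysis is designed for).
#' @param exposures G x K matrix of mixture weights over `signatures`
#'   columns, rows summing to 1. Default: every sample pure `Sig5`.
#' @param signatures Column-stochastic 96 x K ground-truth matrix; default
#'   [bundled_signatures()].
#' @param strand_bias_q Probability that an A:T>T:A mutation is placed with
#'   its adenine on the non-transcribed strand; scalar or per-sample.
#'   0.5 means no bias.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @param genome An [synthetic_genome()] object to reuse, or `NULL` to
#'   generate one from the same seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(samples = 10, burden = NULL, exposures = NULL,
                             signatures = bundled_signatures(),
                             strand_bias_q = 0.5, seed = 1, genome = NULL) {
  if (is.numeric(samples) && length(samples) == 1) {
    samples <- sprintf("S%03d", seq_len(samples))
  }
  G <- length(samples)
  K <- ncol(signatures)
  if (is.null(exposures)) {
    exposures <- matrix(0, G, K, dimnames = list(samples,
                                                 colnames(signatures)))
    exposures[, "Sig5"] <- 1
  }
  exposures <- as.matrix(exposures)
  stopifnot(nrow(exposures) == G, ncol(exposures) == K,
            all(abs(rowSums(exposures) - 1) < 1e-8),
            all(exposures >= 0))
  q <- rep_len(strand_bias_q, G)
  stopifnot(all(q >= 0 & q <= 1))
  if (!is.null(burden)) {
    burden <- rep_len(as.integer(burden), G)
    stopifnot(all(burden >= 0))
  }
  structure(list(samples = samples, burden = burden, exposures = exposures,
                 signatures = signatures, strand_bias_q = q,
                 seed = as.integer(seed), genome = genome),
            class = "synthetic_config")
}

draw_sites <- function(pool_pos, pool_pyr, n) {
  if (n == 0) return(list(pos = integer(0), pyr = logical(0)))
  if (length(pool_pos) == 0) {
    stop("infeasible placement: no genomic site available for a required context")
  }
  i <- sample.int(length(pool_pos), n, replace = TRUE)
  list(pos = pool_pos[i], pyr = pool_pyr[i])
}

#' Simulate a mutation catalog from a signature mixture
#'
#' Per sample, `burden` mutations are drawn with channel probabilities
#' proportional to the opportunity-weighted mixed signature, then each
#' mutation is materialized at a genomic position whose reference context
#' matches its channel. A:T>T:A mutations are placed so the mutated adenine
#' falls on the non-transcribed strand with probability `strand_bias_q`
#' (realized mechanically through the strand of the covering fixture
#' transcript, so [annotate_tx_strand()] is exercised end-to-end);
#' all other mutations are placed uniformly over matching sites.
#'
#' @param config A [synthetic_config()].
#' @return List with `catalog` (contexts unattached, as a caller would
#'   receive real data), `truth` (per-mutation channel and strand label,
#'   per-sample exposure weights and `q`), and `genome`.
#' @export
simulate_catalog <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  local_seed(config$seed)
  genome <- if (is.null(config$genome)) synthetic_genome() else config$genome
  o96 <- as.numeric(expand_opportunities(genome$opportunities))
  ctx <- channel_contexts()
  tri32 <- pyrimidine_trinucleotides()
  tri_of_channel <- match(paste0(ctx$context5, ctx$ref, ctx$context3), tri32)
  is_at <- ctx$class == "T>A"
  G <- length(config$samples)
  burden <- config$burden
  if (is.null(burden)) {
    burden <- as.integer(round(exp(runif(G, log(100), log(2000)))))
  }
  S <- config$signatures

  recs <- vector("list", G)
  truth_recs <- vector("list", G)
  for (g in seq_len(G)) {
    w <- config$exposures[g, ]
    mix <- as.numeric(S %*% w) * o96
    mix <- mix / sum(mix)
    n_c <- as.integer(rmultinom(1, burden[g], mix))
    q <- config$strand_bias_q[g]
    out_pos <- integer(0); out_ref <- character(0); out_alt <- character(0)
    out_ch <- integer(0); out_lab <- character(0)
    for (ch in which(n_c > 0)) {
      n <- n_c[ch]
      pool <- genome$pools[[tri_of_channel[ch]]]
      if (is_at[ch]) {
        b <- rbinom(1, n, q)
        s_non <- draw_sites(pool$at_non$pos, pool$at_non$pyr, b)
        s_tx <- draw_sites(pool$at_tx$pos, pool$at_tx$pyr, n - b)
        pos <- c(s_non$pos, s_tx$pos)
        pyr <- c(s_non$pyr, s_tx$pyr)
        lab <- c(rep("nontranscribed", b), rep("transcribed", n - b))
      } else {
        sdr <- draw_sites(pool$all, pool$all_pyr, n)
        pos <- sdr$pos; pyr <- sdr$pyr
        lab <- rep(NA_character_, n)
      }
      ref <- ifelse(pyr, ctx$ref[ch], comp_base(ctx$ref[ch]))
      alt <- ifelse(pyr, ctx$alt[ch], comp_base(ctx$alt[ch]))
      out_pos <- c(out_pos, pos); out_ref <- c(out_ref, ref)
      out_alt <- c(out_alt, alt); out_ch <- c(out_ch, rep(ch, n))
      out_lab <- c(out_lab, lab)
    }
    recs[[g]] <- data.frame(
      sample = rep(config$samples[g], length(out_pos)),
      chrom = rep("chrS1", length(out_pos)),
      pos = out_pos, ref = out_ref, alt = out_alt, stringsAsFactors = FALSE)
    truth_recs[[g]] <- data.frame(
      sample = rep(config$samples[g], length(out_pos)), pos = out_pos,
      channel = out_ch, strand_label = out_lab, stringsAsFactors = FALSE)
  }
  catalog <- new_catalog(do.call(rbind, recs))
  list(catalog = catalog,
       truth = list(mutations = do.call(rbind, truth_recs),
                    exposures = config$exposures,
                    strand_bias_q = config$strand_bias_q,
                    burden = burden),
       genome = genome)
}

#' Simulate a cohort for detection-power assessment
#'
#' Exposed samples mix the AA-like signature at `aa_fraction` with a
#' Signature-5-like background and carry strand bias `q_exposed`; unexposed
#' samples are pure background with no strand bias. Truth labels allow
#' computing sensitivity and specificity of [classify_exposure()].
#'
#' @param n_exposed,n_unexposed Sample counts.
#' @param burden_exposed Mutation burden of exposed samples.
#' @param burden_unexposed Burden of unexposed samples; `NULL` for the
#'   default log-uniform draw on \[100, 2000\].
#' @param aa_fraction Mixture weight of the AA signature in exposed samples.
#' @param q_exposed Non-transcribed-strand probability for exposed samples.
#' @param seed Integer seed.
#' @param genome Optional [synthetic_genome()] to reuse across replicates.
#' @return As [simulate_catalog()], plus `labels` (logical vector,
#'   `TRUE` = exposed, named by sample).
#' @export
simulate_cohort_for_power <- function(n_exposed, n_unexposed,
                                      burden_exposed = 700,
                                      burden_unexposed = NULL,
                                      aa_fraction = 0.7, q_exposed = 0.75,
                                      seed = 1, genome = NULL) {
  G <- n_exposed + n_unexposed
  samples <- sprintf("S%03d", seq_len(G))
  exposed <- seq_len(G) <= n_exposed
  sig <- bundled_signatures()
  expo <- matrix(0, G, ncol(sig), dimnames = list(samples, colnames(sig)))
  expo[exposed, "AA"] <- aa_fraction
  expo[exposed, "Sig5"] <- 1 - aa_fraction
  expo[!exposed, "Sig5"] <- 1
  burden <- if (is.null(burden_unexposed)) NULL else
    ifelse(exposed, burden_exposed, burden_unexposed)
  cfg <- synthetic_config(
    samples = samples, burden = burden, exposures = expo, signatures = sig,
    strand_bias_q = ifelse(exposed, q_exposed, 0.5), seed = seed,
    genome = genome)
  if (is.null(burden)) {
    # exposed burdens fixed, unexposed drawn from the default distribution
    sim_seeded <- local({
      local_seed(seed)
      as.integer(round(exp(runif(G, log(100), log(2000)))))
    })
    sim_seeded[exposed] <- burden_exposed
    cfg$burden <- sim_seeded
  }
  sim <- simulate_catalog(cfg)
  sim$labels <- setNames(exposed, samples)
  sim
}

#' Write simulation fixtures to disk
#'
#' Emits the maf-lite catalog, fixture FASTA, transcript BED6, opportunity
#' TSV and ground-truth JSON for a simulation.
#'
#' @param sim Result of [simulate_catalog()].
#' @param dir Output directory (created if needed).
#' @return Named vector of the written paths, invisibly.
#' @export
write_fixtures <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(catalog = file.path(dir, "catalog.maf.tsv"),
             fasta = file.path(dir, "reference.fa"),
             bed = file.path(dir, "transcripts.bed"),
             opportunities = file.path(dir, "opportunities.tsv"),
             truth = file.path(dir, "truth.json"))
  write_catalog(sim$catalog, paths["catalog"])
  Biostrings::writeXStringSet(sim$genome$seq, paths["fasta"])
  rtracklayer::export(sim$genome$transcripts, paths["bed"], format = "BED")
  write_opportunities(sim$genome$opportunities, paths["opportunities"])
  jsonlite::write_json(
    list(exposures = sim$truth$exposures,
         strand_bias_q = sim$truth$strand_bias_q,
         burden = sim$truth$burden),
    paths["truth"], digits = NA, pretty = TRUE)
  invisible(paths)
}
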