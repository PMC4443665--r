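test_that("bundled signatures meet their design constraints", {
  S <- bundled_signatures()
  expect_equal(unname(colSums(S)), rep(1, 4))
  at <- aasig:::at_ta_channels()
  # the Signature-5-like background carries exactly 12.5% A:T>T:A mass
  expect_identical(sum(S[at, "Sig5"]), 0.125)
  expect_gte(sum(S[at, "AA"]), 0.85)
  expect_equal(names(which.max(S[, "AA"])), "C[T>A]G")  # CAG adenine context
  # CpG signature concentrates on C>T at NCG
  ctx <- aasig:::channel_contexts()
  ncg <- ctx$class == "C>T" & ctx$context3 == "G"
  expect_gte(sum(S[ncg, "CpG"]), 0.8)
  # APOBEC signature concentrates on TCW C>T / C>G
  tcw <- ctx$context5 == "T" & ctx$context3 %in% c("A", "T") &
    ctx$class %in% c("C>T", "C>G")
  expect_gte(sum(S[tcw, "APOBEC"]), 0.8)
})

test_that("simulation is deterministic given config and seed", {
  g <- shared_genome()
  cfg <- synthetic_config(samples = 3, burden = 150, seed = 77, genome = g,
                          strand_bias_q = 0.6)
  s1 <- simulate_catalog(cfg)
  s2 <- simulate_catalog(cfg)
  expect_identical(s1$catalog, s2$catalog)
  expect_identical(s1$truth$mutations, s2$truth$mutations)
  g2 <- synthetic_genome(length = 2e4, seed = 3141)
  g3 <- synthetic_genome(length = 2e4, seed = 3141)
  expect_identical(as.character(g2$seq), as.character(g3$seq))
})

test_that("every emitted mutation matches its assigned channel's context", {
  g <- shared_genome()
  cfg <- synthetic_config(samples = 2, burden = 400, seed = 12, genome = g,
                          exposures = matrix(c(0.4, 0.2, 0.2, 0.2), 2, 4,
                                             byrow = TRUE,
                                             dimnames = list(c("S001", "S002"),
                                               c("AA", "CpG", "APOBEC", "Sig5"))),
                          strand_bias_q = 0.75)
  sim <- simulate_catalog(cfg)
  cat_df <- attach_context(sim$catalog, g$seq)
  expect_true(all(cat_df$valid_context))
  got <- channel_index(cat_df$ref, cat_df$alt, cat_df$context5,
                       cat_df$context3)
  expect_equal(got, sim$truth$mutations$channel)

  # truth strand labels match the mechanical placement
  cat_df <- annotate_tx_strand(cat_df, g$transcripts)
  at <- !is.na(sim$truth$mutations$strand_label)
  adenine_fwd <- cat_df$ref[at] == "A"
  lab <- ifelse(adenine_fwd == (cat_df$tx_strand[at] == "plus"),
                "nontranscribed", "transcribed")
  expect_equal(lab, sim$truth$mutations$strand_label[at])
})

test_that("pure Signature-5 catalogs show the 12.5% A:T>T:A fraction", {
  g <- shared_genome()
  cfg <- synthetic_config(samples = 1, burden = 10000, seed = 88, genome = g)
  sim <- simulate_catalog(cfg)
  is_at <- (sim$catalog$ref == "A" & sim$catalog$alt == "T") |
    (sim$catalog$ref == "T" & sim$catalog$alt == "A")
  expect_equal(mean(is_at), 0.125, tolerance = 0.01 / 0.125)
})

test_that("configured strand bias is realized within binomial noise", {
  g <- shared_genome()
  expo <- matrix(c(1, 0, 0, 0), 1, 4,
                 dimnames = list("S001", c("AA", "CpG", "APOBEC", "Sig5")))
  cfg <- synthetic_config(samples = 1, burden = 2000, seed = 19, genome = g,
                          exposures = expo, strand_bias_q = 0.75)
  sim <- simulate_catalog(cfg)
  cat_df <- annotate_tx_strand(sim$catalog, g$transcripts)
  sc <- strand_counts(cat_df, "S001")
  frac <- sc$n_nontranscribed / (sc$n_nontranscribed + sc$n_transcribed)
  expect_equal(frac, 0.75, tolerance = 0.03 / 0.75)
})

test_that("zero burden yields an empty catalog but valid fixture files", {
  g <- synthetic_genome(length = 2e4, seed = 5)
  cfg <- synthetic_config(samples = 2, burden = 0, seed = 5, genome = g)
  sim <- simulate_catalog(cfg)
  expect_equal(nrow(sim$catalog), 0)
  dir <- withr::local_tempdir()
  paths <- write_fixtures(sim, dir)
  expect_true(all(file.exists(paths)))
  opp <- read_opportunities(paths["opportunities"])
  expect_equal(opp, g$opportunities)
  ref <- Biostrings::readDNAStringSet(paths["fasta"])
  expect_equal(as.character(ref[[1]]), as.character(g$seq[[1]]))
  tx <- read_transcripts(paths["bed"])
  expect_equal(GenomicRanges::start(tx), GenomicRanges::start(g$transcripts))
})

test_that("full-pipeline round trip recovers exposures and strand bias", {
  g <- shared_genome()
  expo <- matrix(c(0.6, 0.15, 0.1, 0.15), 1, 4,
                 dimnames = list("S001", c("AA", "CpG", "APOBEC", "Sig5")))
  cfg <- synthetic_config(samples = 1, burden = 2000, seed = 123, genome = g,
                          exposures = expo, strand_bias_q = 0.72)
  sim <- simulate_catalog(cfg)
  cat_df <- annotate_tx_strand(attach_context(sim$catalog, g$seq),
                               g$transcripts)
  att <- attribute_exposures(bundled_signatures(),
                             build_spectrum(cat_df, "S001"),
                             g$opportunities)
  expect_true(all(abs(att$proportions - expo[1, ]) < 0.05))
  sc <- strand_counts(cat_df, "S001")
  q_hat <- sc$n_nontranscribed / (sc$n_nontranscribed + sc$n_transcribed)
  expect_lt(abs(q_hat - 0.72), 0.03)
})

test_that("power-cohort construction labels and parameterizes correctly", {
  g <- shared_genome()
  sim <- simulate_cohort_for_power(n_exposed = 2, n_unexposed = 3,
                                   burden_exposed = 300, aa_fraction = 0.7,
                                   seed = 9, genome = g)
  expect_equal(sum(sim$labels), 2)
  expect_equal(unname(sim$truth$exposures[sim$labels, "AA"]), rep(0.7, 2))
  expect_equal(unname(sim$truth$exposures[!sim$labels, "Sig5"]), rep(1, 3))
  expect_equal(unname(sim$truth$burden[sim$labels]), rep(300, 2))
  expect_equal(unname(sim$truth$strand_bias_q), c(0.75, 0.75, 0.5, 0.5, 0.5))
  # aa_fraction 0: exposed are constructed identically to unexposed
  sim0 <- simulate_cohort_for_power(2, 3, burden_exposed = 300,
                                    aa_fraction = 0, seed = 9, genome = g)
  expect_equal(unname(sim0$truth$exposures[, "Sig5"]), rep(1, 5))
})
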