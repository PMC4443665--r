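test_that("channel_index folds all 192 representations onto 96 channels", {
  ctx <- aasig:::channel_contexts()
  # pyrimidine-centred representations map to their own position
  expect_equal(channel_index(ctx$ref, ctx$alt, ctx$context5, ctx$context3),
               1:96)
  # purine-centred reverse complements collide with them
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_equal(channel_index(unname(comp[ctx$ref]), unname(comp[ctx$alt]),
                             unname(comp[ctx$context3]),
                             unname(comp[ctx$context5])),
               1:96)
  expect_equal(channel_index("C", "A", "A", "A"), 1L)
  expect_equal(channel_index("G", "T", "T", "T"), 1L)
  # CAG>CTG in adenine-centric notation is T>A at CTG
  expect_equal(channel_names()[channel_index("A", "T", "C", "G")], "C[T>A]G")
  expect_error(channel_index("C", "C", "A", "A"), "differ")
  expect_error(channel_index("N", "A", "A", "A"), "invalid")
})

test_that("spectrum counts conserve the sample's valid SNVs", {
  g <- shared_genome()
  cfg <- synthetic_config(samples = 2, burden = c(200, 10), seed = 5,
                          genome = g)
  sim <- simulate_catalog(cfg)
  cat_df <- attach_context(sim$catalog, g$seq)
  s1 <- build_spectrum(cat_df, "S001")
  expect_equal(sum(s1), 200)
  expect_equal(attr(s1, "sample"), "S001")
  expect_error(build_spectrum(cat_df, "nope"), "unknown sample")

  m <- spectrum_matrix(cat_df)
  expect_equal(dim(m), c(96L, 2L))
  expect_equal(unname(colSums(m)), c(200, 10))
  expect_equal(m[, "S001"], unclass(s1)[1:96], ignore_attr = TRUE)
})

test_that("invalid-context records are excluded from spectra", {
  ref <- tiny_reference("AACAG")
  cat_df <- tiny_catalog(pos = c(3, 1), ref = c("C", "A"), alt = c("A", "G"))
  cat_df <- suppressMessages(attach_context(cat_df, ref))
  expect_message(s <- build_spectrum(cat_df, "S1"), "excluded")
  expect_equal(sum(s), 1)
})

test_that("opportunity adjustment applies the normalization formula", {
  counts <- setNames(integer(96), channel_names())
  counts[1] <- 2L; counts[2] <- 2L
  opp <- rep(100, 32)
  # uniform opportunities: adjustment cancels
  adj <- opportunity_adjust(counts, opp)
  expect_equal(sum(adj), 1)
  expect_equal(unname(adj[1:2]), c(0.5, 0.5))
  # opportunities (1, 2) on the two active contexts -> (2/3, 1/3)
  opp96 <- rep(1, 96); opp96[2] <- 2
  adj2 <- opportunity_adjust(counts, opp96)
  expect_equal(unname(adj2[1:2]), c(2 / 3, 1 / 3))
  # single nonzero channel
  counts2 <- counts; counts2[2] <- 0L
  expect_equal(unname(opportunity_adjust(counts2, opp)[1]), 1)
  # zero opportunity under observed mutations names the channel
  opp0 <- rep(1, 96); opp0[1] <- 0
  expect_error(opportunity_adjust(counts, opp0), "A\\[C>A\\]A")
})

test_that("A:T>T:A subvector uses adenine-centric order", {
  v <- setNames(numeric(96), channel_names())
  v["C[T>A]G"] <- 0.4  # CAG>CTG in adenine-centric terms
  sub <- at_ta_subvector(v)
  expect_equal(unname(sub["CAG"]), 1)
  expect_equal(sum(sub), 1)

  v2 <- v; v2["C[T>A]G"] <- 0
  sub2 <- at_ta_subvector(v2)
  expect_true(all(is.na(sub2)))
  expect_true(attr(sub2, "undefined"))

  v3 <- setNames(numeric(96), channel_names())
  v3[aasig:::at_ta_channels()] <- 0.2
  expect_equal(unname(at_ta_subvector(v3)), rep(1 / 16, 16))
})

test_that("strand counting follows the adenine-strand convention", {
  cat_df <- tiny_catalog(pos = c(10, 11, 12, 13, 14),
                         ref = c("A", "T", "A", "T", "A"),
                         alt = c("T", "A", "T", "A", "T"),
                         tx_strand = c("plus", "plus", "minus",
                                       "ambiguous", "none"))
  sc <- strand_counts(cat_df, "S1")
  # A on plus -> non-transcribed; T on plus -> transcribed;
  # A on minus -> transcribed; ambiguous/none skipped
  expect_equal(sc$n_nontranscribed, 1L)
  expect_equal(sc$n_transcribed, 2L)
  expect_equal(sc$n_skipped, 2L)
})

test_that("strand counts agree with a brute-force per-mutation oracle", {
  g <- shared_genome()
  cfg <- synthetic_config(samples = 1, burden = 1000, seed = 31, genome = g,
                          exposures = matrix(c(0.6, 0, 0, 0.4), 1, 4,
                                             dimnames = list("S001",
                                               c("AA", "CpG", "APOBEC", "Sig5"))),
                          strand_bias_q = 0.7)
  sim <- simulate_catalog(cfg)
  cat_df <- annotate_tx_strand(sim$catalog, g$transcripts)
  sc <- strand_counts(cat_df, "S001")

  # oracle: classify every record independently
  non <- tr <- skip <- 0L
  for (i in seq_len(nrow(cat_df))) {
    r <- cat_df[i, ]
    if (!((r$ref == "A" & r$alt == "T") | (r$ref == "T" & r$alt == "A"))) next
    if (!r$tx_strand %in% c("plus", "minus")) { skip <- skip + 1L; next }
    adenine_fwd <- r$ref == "A"
    tx_plus <- r$tx_strand == "plus"
    if (adenine_fwd == tx_plus) non <- non + 1L else tr <- tr + 1L
  }
  expect_equal(sc$n_nontranscribed, non)
  expect_equal(sc$n_transcribed, tr)
  expect_equal(sc$n_skipped, skip)
  # mechanically produced bias is near the configured q
  expect_gt(sc$n_nontranscribed / (sc$n_nontranscribed + sc$n_transcribed),
            0.6)
})

test_that("spectrum TSV writer emits 96 annotated rows", {
  counts <- setNames(integer(96), channel_names())
  counts[50] <- 3L
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(counts, path, opportunities = rep(1, 32))
  df <- read.delim(path)
  expect_equal(nrow(df), 96)
  expect_equal(sum(df$count), 3)
  expect_equal(sum(df$adjusted_proportion), 1)
})
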