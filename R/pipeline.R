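#' Run the end-to-end AA detection pipeline
#'
#' Catalog -> trinucleotide contexts -> transcription strands -> spectra and
#' strand tallies -> binomial tests -> FDR -> exposure classification ->
#' (optionally) de novo signature extraction. Results are returned and,
#' when `output_dir` is given, written as a Table-1-style TSV, a JSON
#' variant with log10 p-values, and a run manifest recording version,
#' seeds, parameters and input digests. On error, partial outputs in
#' `output_dir` are removed and the failing stage is named.
#'
#' @param catalog maf-lite path or a catalog `data.frame`.
#' @param reference FASTA path or `DNAStringSet`.
#' @param transcripts BED6 path or `GRanges` with strand.
#' @param opportunities Opportunity TSV path or named 32-vector; `NULL`
#'   computes it from the whole reference.
#' @param aa_reference Adenine-centric 16-vector, a TSV path (columns
#'   `context`, `weight`), or `NULL` for the bundled AA profile.
#' @param null A [null_spec()].
#' @param cosine_cutoff Passed to [classify_exposure()].
#' @param extract Also run [select_k()] signature extraction.
#' @param k_min,k_max,restarts,seed,tol Factorization options.
#' @param output_dir Directory for result files, or `NULL` to skip writing.
#' @return List with `results` (classified [test_exposure()] table), `fit`
#'   (an `aa_fit` or `NULL`) and `manifest`.
#' @export
run_pipeline <- function(catalog, reference, transcripts,
                         opportunities = NULL, aa_reference = NULL,
                         null = null_spec(), cosine_cutoff = 0.90,
                         extract = FALSE, k_min = 2, k_max = 8,
                         restarts = 10, seed = 1, tol = 1e-8,
                         output_dir = NULL) {
  inputs <- list(catalog = catalog, reference = reference,
                 transcripts = transcripts, opportunities = opportunities)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(output_dir)) {
        unlink(file.path(output_dir,
                         c("results.tsv", "results.json", "signatures.tsv",
                           "exposures.tsv", "fit.json", "manifest.json")))
      }
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cat_df <- stage("read_catalog", {
    if (is.character(catalog)) read_catalog(catalog, "maf-lite") else catalog
  })
  cat_df <- stage("attach_context", attach_context(cat_df, reference))
  cat_df <- stage("annotate_tx_strand", annotate_tx_strand(cat_df, transcripts))
  opp <- stage("opportunities", {
    if (is.null(opportunities)) compute_opportunities(reference)
    else if (is.character(opportunities)) read_opportunities(opportunities)
    else opportunities
  })
  aa_ref <- stage("aa_reference", {
    if (is.null(aa_reference)) aa_reference_profile()
    else if (is.character(aa_reference)) {
      df <- read.delim(aa_reference, stringsAsFactors = FALSE)
      setNames(df$weight, df$context)[names(adenine_context_channels())]
    } else aa_reference
  })
  results <- stage("exposure_test", {
    classify_exposure(test_exposure(cat_df, opp, aa_ref, null),
                      null, cosine_cutoff)
  })
  fit <- NULL
  if (extract) {
    fit <- stage("signature_extraction", {
      V <- spectrum_matrix(cat_df)
      if (k_min == k_max) {
        fit_poisson_factorization(V, opp, k_min, restarts, seed, tol)
      } else {
        select_k(V, opp, k_min, k_max, restarts, seed, tol)
      }
    })
  }
  manifest <- list(
    package = "aasig",
    version = as.character(packageVersion("aasig")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = list(p0_excess = null$p0_excess, p0_strand = null$p0_strand,
                      fdr_threshold = null$fdr_threshold,
                      cosine_cutoff = cosine_cutoff, extract = extract,
                      k_min = k_min, k_max = k_max, restarts = restarts,
                      seed = seed, tol = tol),
    inputs = lapply(inputs, function(x)
      if (is.character(x) && length(x) == 1 && file.exists(x))
        unname(tools::md5sum(x)) else class(x)[1]),
    n_samples = length(unique(cat_df$sample)),
    n_mutations = nrow(cat_df))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(results, file.path(output_dir, "results.tsv"))
    jsonlite::write_json(results, file.path(output_dir, "results.json"),
                         dataframe = "rows", digits = NA, na = "null",
                         pretty = TRUE)
    if (!is.null(fit)) {
      write.table(data.frame(channel = rownames(fit$S), fit$S),
                  file.path(output_dir, "signatures.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(data.frame(signature = rownames(fit$E), fit$E),
                  file.path(output_dir, "exposures.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      sel <- attr(fit, "selection")
      jsonlite::write_json(
        list(K = fit$K, loglik = fit$loglik, seed = fit$seed,
             iterations = fit$iterations, converged = fit$converged,
             selection = sel),
        file.path(output_dir, "fit.json"), digits = NA, pretty = TRUE)
    }
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(results = results, fit = fit, manifest = manifest)
}

#' Write a Table-1-style results TSV
#'
#' One row per sample with counts, proportions, formatted p-values and FDRs
#' (one significant figure, `0` below 1e-300), cosine similarity, call, and
#' the machine-precision log10 p-values.
#'
#' @param results A classified `aa_exposure_results` table.
#' @param path Output path.
#' @export
write_results <- function(results, path) {
  fmt <- function(lp) vapply(lp, format_pvalue, character(1))
  df <- data.frame(
    sample = results$sample,
    total = results$n_total,
    atta = results$n_atta,
    atta_proportion = round(results$prop_atta, 2),
    p_excess = fmt(results$log10_p_excess),
    fdr_excess = fmt(log10(results$fdr_excess)),
    nontranscribed = results$n_non,
    transcribed = results$n_tr,
    frac_nontranscribed = round(results$frac_non, 2),
    p_strand = fmt(results$log10_p_strand),
    fdr_strand = fmt(log10(results$fdr_strand)),
    cosine_aa = round(results$cosine_aa, 3),
    call = results$call,
    log10_p_excess = results$log10_p_excess,
    log10_p_strand = results$log10_p_strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
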