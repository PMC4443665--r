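# Opportunity-weighted Poisson matrix factorization of mutation spectra.
#
# Model: V_cg ~ Poisson(o_c * sum_k S_ck E_kg) with o_c the trinucleotide
# opportunity of channel c, S column-stochastic signatures, E nonnegative
# exposures (expected mutation counts). Fitted by multiplicative updates
# that monotonically non-increase the generalized KL divergence (weighted
# Lee-Seung), best of several seeded random restarts.

local_seed <- function(seed, env = parent.frame()) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  withr::defer({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, envir = env)
  set.seed(seed)
}

poisson_ll <- function(V, o, S, E) {
  mu <- o * (S %*% E)
  sum(ifelse(V > 0, V * log(mu), 0) - mu - lgamma(V + 1))
}

nmf_updates <- function(V, o, S, E, max_iter, tol, floor = 1e-12) {
  ll_prev <- -Inf
  trace <- numeric(0)
  it <- 0L
  converged <- FALSE
  esum <- NULL
  while (it < max_iter) {
    it <- it + 1L
    Lam <- pmax(S %*% E, floor)
    R <- V / Lam
    # S_ck <- S_ck * [sum_g R_cg E_kg] / [o_c * sum_g E_kg]
    S <- S * (R %*% t(E)) / pmax(outer(o, rowSums(E)), floor)
    Lam <- pmax(S %*% E, floor)
    R <- V / Lam
    # E_kg <- E_kg * [sum_c R_cg S_ck] / [sum_c o_c S_ck]
    E <- E * (t(S) %*% R) / pmax(colSums(o * S), floor)
    if (it %% 10L == 0L || it == max_iter) {
      ll <- poisson_ll(V, o, S, E)
      trace <- c(trace, ll)
      if (is.finite(ll_prev) &&
          abs(ll - ll_prev) < tol * (abs(ll_prev) + 1)) {
        converged <- TRUE
        break
      }
      ll_prev <- ll
    }
  }
  list(S = S, E = E, ll = poisson_ll(V, o, S, E), trace = trace,
       iterations = it, converged = converged)
}

finalize_fit <- function(fit, V, o, K, seed) {
  S <- fit$S
  E <- fit$E
  S[S < 1e-10] <- 0
  cs <- colSums(S)
  cs[cs == 0] <- 1
  S <- sweep(S, 2, cs, "/")
  E <- E * cs
  ord <- order(rowSums(E), decreasing = TRUE)
  S <- S[, ord, drop = FALSE]
  E <- E[ord, , drop = FALSE]
  colnames(S) <- rownames(E) <- paste0("S", seq_len(K))
  rownames(S) <- rownames(V)
  colnames(E) <- colnames(V)
  structure(list(S = S, E = E, loglik = poisson_ll(V, o, S, E),
                 trace = fit$trace, K = K, seed = seed,
                 iterations = fit$iterations, converged = fit$converged),
            class = "aa_fit")
}

#' Fit an opportunity-weighted Poisson factorization
#'
#' Decomposes a 96 x G matrix of per-sample channel counts into K
#' column-stochastic signatures `S` and nonnegative exposures `E` under the
#' model `V_cg ~ Poisson(o_c (S E)_cg)`, where `o` is the channel
#' opportunity. Multiplicative updates monotonically non-decrease the
#' Poisson log-likelihood; the best of `restarts` seeded random
#' initializations (entries uniform on (0.1, 1)) is returned. Signature
#' columns are ordered by total attributed mutations, descending.
#'
#' @param V 96 x G nonnegative integer matrix (channels x samples).
#' @param opportunities 32- or 96-long opportunity vector, positive on
#'   channels with data.
#' @param K Number of signatures (>= 1).
#' @param restarts Random initializations; the highest-likelihood fit wins.
#' @param seed Integer; restart r uses seed `seed + r - 1`. Identical seed
#'   and inputs give identical results.
#' @param tol Relative log-likelihood change below which a fit stops.
#' @param max_iter Update-iteration cap per restart; a fit still moving at
#'   the cap is returned with `converged = FALSE`.
#' @return An `aa_fit` list: `S`, `E`, `loglik`, `trace` (log-likelihood
#'   checkpoints), `K`, `seed`, `iterations`, `converged`.
#' @export
fit_poisson_factorization <- function(V, opportunities, K, restarts = 10,
                                      seed = 1, tol = 1e-8,
                                      max_iter = 5000) {
  V <- as.matrix(V)
  stopifnot(nrow(V) == 96, K >= 1, restarts >= 1, all(V >= 0))
  if (sum(V) == 0) stop("all-zero count matrix")
  o <- expand_opportunities(opportunities)
  if (any(rowSums(V) > 0 & o <= 0)) {
    stop("zero opportunity on a channel with observed mutations")
  }
  o <- as.numeric(o)
  o[o <= 0] <- min(o[o > 0]) * 1e-6  # inert channels
  if (is.null(rownames(V))) rownames(V) <- channel_names()
  G <- ncol(V)
  best <- NULL
  for (r in seq_len(restarts)) {
    local_seed(seed + r - 1L)
    S0 <- matrix(runif(96 * K, 0.1, 1), 96, K)
    # scale E so initial reconstruction has the data's magnitude
    E0 <- matrix(runif(K * G, 0.1, 1), K, G)
    E0 <- E0 * rep(colSums(V) / (colSums(o * (S0 %*% E0)) + 1e-12),
                   each = K)
    fit <- nmf_updates(V, o, S0, E0, max_iter, tol)
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }
  finalize_fit(best, V, o, K, seed)
}

#' Select the number of signatures by BIC
#'
#' Fits every K in `k_min:k_max` and returns the fit minimizing
#' `BIC(K) = -2 LL + (96 K + K G - K) log(sum(V))` — the Poisson
#' log-likelihood penalized by the free-parameter count (each
#' column-stochastic signature loses one degree of freedom).
#'
#' @inheritParams fit_poisson_factorization
#' @param k_min,k_max Range of signature numbers to consider.
#' @return The winning `aa_fit`, with a `selection` data.frame attribute
#'   (`K`, `loglik`, `bic`, `converged`) covering every K tried.
#' @export
select_k <- function(V, opportunities, k_min = 2, k_max = 8, restarts = 10,
                     seed = 1, tol = 1e-8, max_iter = 5000) {
  stopifnot(k_min <= k_max)
  fits <- lapply(k_min:k_max, function(K)
    fit_poisson_factorization(V, opportunities, K, restarts, seed, tol,
                              max_iter))
  n_obs <- sum(V)
  bic <- vapply(fits, function(f)
    -2 * f$loglik + (96 * f$K + f$K * ncol(as.matrix(V)) - f$K) * log(n_obs),
    numeric(1))
  sel <- data.frame(K = k_min:k_max,
                    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                    bic = bic,
                    converged = vapply(fits, `[[`, logical(1), "converged"))
  best <- fits[[which.min(bic)]]
  attr(best, "selection") <- sel
  best
}

#' Attribute a sample's mutations to fixed signatures
#'
#' Re-fits only the exposure column for one spectrum with the signature
#' matrix frozen (the same multiplicative update, S held fixed), and
#' returns the per-signature attribution as proportions of the sample's
#' mutations.
#'
#' @param S Column-stochastic 96 x K signature matrix.
#' @param spectrum Named 96-vector of counts for one sample.
#' @param opportunities 32- or 96-long opportunity vector.
#' @param tol,max_iter Convergence controls.
#' @return List with `proportions` (K-vector summing to 1), `counts`
#'   (expected mutations per signature) and `loglik`; `NULL` proportions
#'   for an all-zero spectrum.
#' @export
attribute_exposures <- function(S, spectrum, opportunities, tol = 1e-10,
                                max_iter = 10000) {
  S <- as.matrix(S)
  stopifnot(nrow(S) == 96, all(abs(colSums(S) - 1) < 1e-6))
  v <- as.numeric(spectrum)
  if (sum(v) == 0) {
    return(list(proportions = NULL, counts = NULL, loglik = NA_real_))
  }
  o <- as.numeric(expand_opportunities(opportunities))
  o[o <= 0] <- min(o[o > 0]) * 1e-6
  K <- ncol(S)
  e <- rep(sum(v) / K, K)
  denom <- colSums(o * S)
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    lam <- pmax(as.numeric(S %*% e), 1e-12)
    e <- e * as.numeric(t(S) %*% (v / lam)) / pmax(denom, 1e-12)
    if (it %% 10 == 0) {
      ll <- sum(ifelse(v > 0, v * log(o * pmax(as.numeric(S %*% e), 1e-300)), 0) -
                  o * as.numeric(S %*% e))
      if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (abs(ll_prev) + 1))
        break
      ll_prev <- ll
    }
  }
  counts <- e * denom  # expected observed mutations per signature
  props <- counts / sum(counts)
  names(props) <- names(counts) <- colnames(S)
  list(proportions = props, counts = counts, loglik = ll_prev)
}

#' Match two signature matrices by cosine similarity
#'
#' Greedy best-match pairing on the full 96-channel cosine, highest
#' similarity first; also reports the cosine restricted to the A:T>T:A
#' subvector of each matched pair.
#'
#' @param A,B Signature matrices with 96 rows (K may differ; pairs are
#'   formed up to `min(K_A, K_B)`).
#' @return `data.frame` with columns `a`, `b` (column names), `cosine`,
#'   `cosine_atta`.
#' @export
compare_signatures <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B)) stop("signature matrices differ in channel dimension")
  if (is.null(colnames(A))) colnames(A) <- paste0("A", seq_len(ncol(A)))
  if (is.null(colnames(B))) colnames(B) <- paste0("B", seq_len(ncol(B)))
  cm <- matrix(NA_real_, ncol(A), ncol(B),
               dimnames = list(colnames(A), colnames(B)))
  for (i in seq_len(ncol(A))) for (j in seq_len(ncol(B))) {
    cm[i, j] <- cosine_similarity(A[, i], B[, j])
  }
  ta <- at_ta_channels()
  pairs <- list()
  free_a <- rownames(cm); free_b <- colnames(cm)
  while (length(free_a) > 0 && length(free_b) > 0) {
    sub <- cm[free_a, free_b, drop = FALSE]
    ij <- arrayInd(which.max(sub), dim(sub))
    a <- free_a[ij[1]]; b <- free_b[ij[2]]
    ca <- cosine_similarity(A[ta, a], B[ta, b])
    pairs[[length(pairs) + 1]] <- data.frame(
      a = a, b = b, cosine = sub[ij], cosine_atta = ca,
      stringsAsFactors = FALSE)
    free_a <- setdiff(free_a, a); free_b <- setdiff(free_b, b)
  }
  do.call(rbind, pairs)
}

#' @export
#' @method print aa_fit
print.aa_fit <- function(x, ...) {
  cat("Opportunity-weighted Poisson factorization\n")
  cat("  K =", x$K, " samples =", ncol(x$E),
      " log-likelihood =", format(x$loglik, digits = 8), "\n")
  cat("  iterations =", x$iterations,
      " converged =", x$converged, " seed =", x$seed, "\n")
  sel <- attr(x, "selection")
  if (!is.null(sel)) {
    cat("  model selection (BIC):\n")
    print(sel, row.names = FALSE)
  }
  invisible(x)
}
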