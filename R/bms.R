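# Random-effects Bayesian model selection over a subjects x models matrix of
# log evidences: variational Dirichlet posterior over population model
# frequencies, exceedance probabilities, Bayes omnibus risk and protected
# exceedance probabilities.

check_evidence <- function(evidence) {
  evidence <- as.matrix(evidence)
  if (ncol(evidence) < 2L) stopf("need at least 2 models")
  if (!all(is.finite(evidence))) stopf("evidence matrix must be finite")
  evidence
}

#' Variational Dirichlet posterior over model frequencies
#'
#' Fixed-point iteration for the random-effects model in which each
#' subject's generating model is drawn from population frequencies with a
#' Dirichlet prior. Subject responsibilities are proportional to
#' `exp(log evidence + digamma(alpha_k) - digamma(sum alpha))`; the
#' concentration is `alpha = alpha0 + summed responsibilities`.
#'
#' @param evidence Numeric matrix, rows = subjects, columns = models,
#'   entries = log model evidence.
#' @param alpha0 Symmetric Dirichlet prior concentration (default 1).
#' @param tol Convergence tolerance on the concentration vector.
#' @param max_iter Maximum iterations.
#' @return List with `alpha` (posterior concentrations), `r` (expected model
#'   frequencies), `z` (subjects-by-models responsibility matrix) and
#'   `iterations`.
#' @export
vb_dirichlet <- function(evidence, alpha0 = 1, tol = 1e-8, max_iter = 500L) {
  evidence <- check_evidence(evidence)
  n <- nrow(evidence)
  K <- ncol(evidence)
  lev <- evidence - apply(evidence, 1L, max)  # row-normalize for stability
  alpha <- rep(alpha0, K)
  for (it in seq_len(max_iter)) {
    lg <- digamma(alpha) - digamma(sum(alpha))
    lu <- sweep(lev, 2L, lg, "+")
    rowmax <- apply(lu, 1L, max)
    lse <- rowmax + log(rowSums(exp(lu - rowmax)))
    z <- exp(lu - lse)
    alpha_new <- alpha0 + colSums(z)
    if (max(abs(alpha_new - alpha)) < tol) {
      return(list(alpha = alpha_new, r = alpha_new / sum(alpha_new), z = z,
                  iterations = it))
    }
    alpha <- alpha_new
  }
  stopf("vb_dirichlet did not converge in %d iterations (last delta %.3g)",
        max_iter, max(abs(alpha_new - alpha)))
}

#' Exceedance probabilities
#'
#' Monte-Carlo probability that each model's population frequency is the
#' largest, under the Dirichlet posterior. Ties among sampled maxima are
#' broken uniformly at random.
#'
#' @param alpha Dirichlet concentration vector (> 0).
#' @param n_samples Number of Dirichlet draws.
#' @param seed Seed for the draws.
#' @return Vector of exceedance probabilities summing to 1.
#' @export
exceedance_prob <- function(alpha, n_samples = 1e6, seed = NULL) {
  stopifnot(all(alpha > 0))
  K <- length(alpha)
  with_seed(seed, {
    counts <- numeric(K)
    remaining <- as.integer(n_samples)
    chunk <- 100000L
    while (remaining > 0L) {
      m <- min(chunk, remaining)
      g <- matrix(rgamma(m * K, shape = rep(alpha, each = m)), m, K)
      idx <- max.col(g, ties.method = "random")
      counts <- counts + tabulate(idx, K)
      remaining <- remaining - m
    }
    counts / n_samples
  })
}

#' Bayes omnibus risk
#'
#' Posterior probability that the observed evidences arose under the null
#' model in which all model frequencies are exactly equal, computed by
#' comparing the exact null log evidence `F0 = sum_n log mean_k p(y_n | m_k)`
#' with the variational free energy `F1` of the Dirichlet alternative:
#' `BOR = 1 / (1 + exp(F1 - F0))`.
#'
#' @inheritParams vb_dirichlet
#' @return The risk, a probability in \[0, 1\].
#' @export
bayes_omnibus_risk <- function(evidence, alpha0 = 1) {
  evidence <- check_evidence(evidence)
  K <- ncol(evidence)
  vb <- vb_dirichlet(evidence, alpha0 = alpha0)
  z <- vb$z
  # Free energy of the alternative: E_q[log p(y, r, m)] - E_q[log q], with
  # the Dirichlet expectation terms cancelling because alpha = alpha0 +
  # colSums(z). logC(a) is the log normalizer of a Dirichlet(a).
  logC <- function(a) lgamma(sum(a)) - sum(lgamma(a))
  zlogz <- z * log(z)
  zlogz[z == 0] <- 0
  F1 <- sum(z * evidence) - sum(zlogz) +
    logC(rep(alpha0, K)) - logC(vb$alpha)
  F0 <- sum(apply(evidence, 1L, logsumexp) - log(K))
  1 / (1 + exp(F1 - F0))
}

#' Protected exceedance probabilities
#'
#' Shrinks the exceedance probabilities toward uniform by the Bayes omnibus
#' risk: `PEP = EP * (1 - BOR) + BOR / K`.
#'
#' @param ep Exceedance probability vector (sums to 1).
#' @param bor Bayes omnibus risk in \[0, 1\].
#' @param K Number of models (default `length(ep)`).
#' @return Protected exceedance probability vector.
#' @export
protected_ep <- function(ep, bor, K = length(ep)) {
  stopifnot(abs(sum(ep) - 1) < 1e-6, bor >= 0, bor <= 1)
  ep * (1 - bor) + bor / K
}

#' Random-effects Bayesian model selection
#'
#' Full pipeline on a log evidence matrix: variational Dirichlet posterior,
#' Monte-Carlo exceedance probabilities, Bayes omnibus risk and protected
#' exceedance probabilities.
#'
#' @inheritParams vb_dirichlet
#' @inheritParams exceedance_prob
#' @return An object of class `cudn_bms`: `alpha`, `r`, `z`, `ep`, `bor`,
#'   `pep`, `best` (index of the maximum-PEP model), `n_samples`, `seed`.
#' @export
bms <- function(evidence, alpha0 = 1, n_samples = 1e6, seed = NULL) {
  evidence <- check_evidence(evidence)
  vb <- vb_dirichlet(evidence, alpha0 = alpha0)
  ep <- exceedance_prob(vb$alpha, n_samples = n_samples, seed = seed)
  bor <- bayes_omnibus_risk(evidence, alpha0 = alpha0)
  pep <- protected_ep(ep, bor)
  names(pep) <- names(ep) <- names(vb$r) <- colnames(evidence)
  structure(list(alpha = vb$alpha, r = vb$r, z = vb$z, ep = ep, bor = bor,
                 pep = pep, best = which.max(pep), n_samples = n_samples,
                 seed = seed),
            class = "cudn_bms")
}

#' @export
print.cudn_bms <- function(x, ...) {
  cat("Random-effects Bayesian model selection\n")
  cat(sprintf("  %d models, Bayes omnibus risk = %.3f\n", length(x$r), x$bor))
  top <- order(x$pep, decreasing = TRUE)[seq_len(min(5L, length(x$pep)))]
  for (i in top)
    cat(sprintf("  %-8s r = %.3f  EP = %.3f  PEP = %.3f\n",
                if (is.null(names(x$pep))) paste0("m", i) else names(x$pep)[i],
                x$r[i], x$ep[i], x$pep[i]))
  invisible(x)
}
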