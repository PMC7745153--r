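#' Prior specification for a candidate model
#'
#' Gaussian priors in a transformed space, one row per free parameter of the
#' model: `beta0` (identity, N(0, 2)), `zeta` (log, N(0, 2)), `nu` (identity,
#' N(`nu_mean`, `nu_var`); sign-free), `lambda` (identity, N(0, 2)), `alpha`
#' (logit, N(0, 1)), `omega` (identity, N(-3, 4)) and, for the 3-level
#' filter, `theta` (log, N(-6, 4)). The HGF coupling `kappa` and the initial
#' states are fixed (1 and `mu2_0 = 0`, `mu3_0 = 1`, `sigma2_0 = sigma3_0 =
#' 1`), the standard identifiability practice for a binary HGF at 240 trials.
#'
#' @param spec A [model_spec()].
#' @param nu_mean,nu_var Prior mean and variance of `nu` in identity space;
#'   the susceptibility analysis sweeps these.
#' @return A data frame of class `cudn_priors`: `param`, `transform`
#'   (`identity`/`log`/`logit`), `mean`, `var` (transformed space).
#' @export
default_priors <- function(spec, nu_mean = 0, nu_var = 2) {
  stopifnot(inherits(spec, "cudn_model_spec"), nu_var > 0)
  rows <- list(
    c("beta0", "identity", 0, 2),
    c("zeta", "log", 0, 2),
    c("omega", "identity", -3, 4))
  if (spec$hgf_levels == 3L) rows <- c(rows, list(c("theta", "log", -6, 4)))
  if (spec$blame_effect %in% c("noise_independent", "noise_interaction"))
    rows <- c(rows, list(c("nu", "identity", nu_mean, nu_var)))
  if (spec$blame_effect == "value")
    rows <- c(rows, list(c("lambda", "identity", 0, 2)))
  if (spec$blame_learning == "rw" && spec$blame_effect != "none")
    rows <- c(rows, list(c("alpha", "logit", 0, 1)))
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(param = r[1], transform = r[2], mean = as.numeric(r[3]),
               var = as.numeric(r[4]), stringsAsFactors = FALSE)))
  class(out) <- c("cudn_priors", "data.frame")
  out
}

#' Transform parameters between native and fitting space
#'
#' Applies each free parameter's transform (`identity`, `log` or `logit`) so
#' that optimization and priors live on an unconstrained scale.
#' `untransform_params` is the exact inverse.
#'
#' @param native Named numeric vector of native-space values.
#' @param priors A [default_priors()] table.
#' @return Named numeric vector in the other space.
#' @export
transform_params <- function(native, priors) {
  stopifnot(inherits(priors, "cudn_priors"))
  x <- native[priors$param]
  out <- numeric(nrow(priors))
  for (i in seq_len(nrow(priors))) {
    out[i] <- switch(priors$transform[i],
      identity = x[i],
      log = if (x[i] > 0) log(x[i]) else stopf("log transform of %s <= 0",
                                               priors$param[i]),
      logit = if (x[i] > 0 && x[i] < 1) qlogis(x[i]) else
        stopf("logit transform of %s outside (0, 1)", priors$param[i]))
  }
  names(out) <- priors$param
  out
}

#' @rdname transform_params
#' @param transformed Named numeric vector in transformed space.
#' @export
untransform_params <- function(transformed, priors) {
  stopifnot(inherits(priors, "cudn_priors"))
  x <- transformed[priors$param]
  out <- numeric(nrow(priors))
  for (i in seq_len(nrow(priors))) {
    out[i] <- switch(priors$transform[i],
      identity = x[i], log = exp(x[i]), logit = plogis(x[i]))
  }
  names(out) <- priors$param
  out
}

# Native parameter vector -> model components, with fixed values filled in
# for parameters the model structure does not free.
native_to_components <- function(native, spec) {
  get0 <- function(nm, default) if (nm %in% names(native)) native[[nm]] else default
  list(
    hgf = hgf_params(omega = get0("omega", -3),
                     theta = get0("theta", exp(-6)),
                     levels = spec$hgf_levels),
    rw = rw_params(alpha = get0("alpha", 0.2)),
    resp = response_params(beta0 = get0("beta0", 0),
                           zeta = get0("zeta", 0),
                           nu = get0("nu", 0),
                           lambda = get0("lambda", 0)))
}

# Negative log joint (likelihood + prior) in transformed space. Works on
# raw vectors and the compiled filter directly; this is the optimizer's hot
# path, evaluated thousands of times per fit.
make_neg_log_joint <- function(session, spec, priors) {
  prior_sd <- sqrt(priors$var)
  prior_mean <- priors$mean
  pnames <- priors$param
  transform <- priors$transform
  outcome <- as.integer(session_outcomes(session))
  wrong <- as.integer(session$correct_feedback == 0L)
  blame <- as.integer(session$blame_feedback)
  chose1 <- session$choice == 1L
  levels <- spec$hgf_levels
  blame_effect <- spec$blame_effect
  fixed_blame <- spec$blame_learning == "fixed"
  n <- length(outcome)
  function(theta) {
    val <- tryCatch({
      native <- ifelse(transform == "log", exp(theta),
                       ifelse(transform == "logit", plogis(theta), theta))
      g <- function(nm, default) {
        i <- match(nm, pnames)
        if (is.na(i)) default else native[i]
      }
      m <- cudn_filter_cpp(outcome, wrong, blame,
                           1, g("omega", -3), g("theta", exp(-6)),
                           0, 1, 1, 1, levels, g("alpha", 0.2), 0.5)
      muhat1 <- m[, 1L]
      sigmahat2 <- m[, 2L]
      pb <- if (fixed_blame) 0.5 else m[, 3L]
      beta0 <- g("beta0", 0); zeta <- g("zeta", 0)
      nu <- g("nu", 0); lambda <- g("lambda", 0)
      log_beta <- switch(blame_effect,
        noise_interaction = beta0 - (zeta - nu * pb) * sigmahat2,
        noise_independent = beta0 - zeta * sigmahat2 + nu * pb,
        beta0 - zeta * sigmahat2)
      beta <- exp(pmin(pmax(log_beta, -350), 350))
      u1 <- muhat1
      u2 <- 1 - muhat1
      if (blame_effect == "value") {
        u1 <- u1 + lambda * (1 - muhat1) * pb
        u2 <- u2 + lambda * muhat1 * pb
      }
      p1 <- plogis(beta * (u1 - u2))
      p_obs <- ifelse(chose1, p1, 1 - p1)
      ll <- sum(log(pmax(p_obs, 1e-12)))
      lp <- sum(dnorm(theta, prior_mean, prior_sd, log = TRUE))
      -(ll + lp)
    }, error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }
}

# Symmetric Hessian by central finite differences, step `h` per coordinate.
fd_hessian <- function(f, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(NA_real_, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h)
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i < d) for (j in (i + 1):d) {
      ej <- replace(numeric(d), j, h)
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

#' Laplace-approximate log model evidence
#'
#' `log p(y | model) ~ log joint at the mode + (d/2) log(2 pi) - (1/2) log
#' det(negative Hessian)`. When the negative Hessian at the mode is not
#' positive definite the function falls back to a BIC-based evidence,
#' `loglik - (d/2) log(n)`, with a warning.
#'
#' @param log_joint Log joint density (likelihood + prior) at the mode.
#' @param neg_hessian Negative Hessian of the log joint at the mode
#'   (`d x d`); ignored when `d = 0`.
#' @param loglik Log-likelihood at the mode (used by the fallback).
#' @param n_obs Number of observations (used by the fallback).
#' @return Log evidence (finite scalar).
#' @export
laplace_log_evidence <- function(log_joint, neg_hessian, loglik = log_joint,
                                 n_obs = NULL) {
  d <- if (is.null(neg_hessian)) 0L else nrow(neg_hessian)
  if (d == 0L) return(log_joint)
  ch <- tryCatch(chol(neg_hessian), error = function(e) NULL)
  if (is.null(ch) || any(!is.finite(diag(ch)))) {
    warning("negative Hessian not positive definite; using BIC evidence",
            call. = FALSE)
    if (is.null(n_obs)) stopf("n_obs needed for the BIC fallback")
    return(loglik - d / 2 * log(n_obs))
  }
  log_joint + d / 2 * log(2 * pi) - sum(log(diag(ch)))
}

#' Fit one model to one session by MAP
#'
#' Multi-start quasi-Newton (BFGS, numerical gradients, relative tolerance
#' 1e-10, at most 500 iterations per start) maximization of the log joint in
#' transformed space. The first start is the prior mean; the remaining
#' `n_restarts - 1` are prior draws. The best converged start is returned
#' with a Laplace-approximate log evidence (Hessian by central differences,
#' step 1e-4).
#'
#' @param session A session data frame.
#' @param spec A [model_spec()].
#' @param priors A [default_priors()] table for `spec`.
#' @param n_restarts Number of optimizer starts (>= 1).
#' @param seed Seed controlling the restart draws.
#' @return An object of class `cudn_fit`: `subject_id`, `model_id`,
#'   `estimate` (native space), `estimate_transformed`, `log_joint`,
#'   `loglik`, `log_evidence`, `neg_hessian`, `n_trials`, `convergence`
#'   (per-start optim codes), `n_restarts`.
#' @export
fit_map <- function(session, spec, priors = default_priors(spec),
                    n_restarts = 8L, seed = NULL) {
  stopifnot(inherits(spec, "cudn_model_spec"), n_restarts >= 1L)
  nlj <- make_neg_log_joint(session, spec, priors)
  d <- nrow(priors)
  starts <- with_seed(seed, {
    s <- matrix(rnorm((n_restarts - 1L) * d, rep(priors$mean, each = n_restarts - 1L),
                      rep(sqrt(priors$var), each = n_restarts - 1L)),
                nrow = max(n_restarts - 1L, 0L), ncol = d)
    rbind(priors$mean, s)
  })
  best <- NULL
  codes <- integer(0)
  for (r in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[r, ], nlj, method = "BFGS",
            control = list(maxit = 500L, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) { codes <- c(codes, NA_integer_); next }
    codes <- c(codes, fit$convergence)
    ok <- fit$convergence == 0L && is.finite(fit$value) && fit$value < 1e9
    if (ok && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stopf("all %d optimizer starts failed (codes: %s)", n_restarts,
          paste(codes, collapse = ","))
  theta <- best$par
  names(theta) <- priors$param
  native <- untransform_params(theta, priors)
  H <- fd_hessian(nlj, theta)
  cmp <- native_to_components(as.list(native), spec)
  traj <- run_perceptual(session, cmp$hgf, cmp$rw)
  ll <- session_loglik(session, traj, cmp$resp, spec)
  ev <- laplace_log_evidence(-best$value, H, loglik = ll,
                             n_obs = nrow(session))
  structure(list(subject_id = session$subject_id[1], model_id = spec$id,
                 spec = spec, priors = priors,
                 estimate = native, estimate_transformed = theta,
                 log_joint = -best$value, loglik = ll, log_evidence = ev,
                 neg_hessian = H, n_trials = nrow(session),
                 convergence = codes, n_restarts = n_restarts),
            class = "cudn_fit")
}

#' @describeIn fit_map Recompute the Laplace evidence of an existing fit.
#' @param fit A `cudn_fit`.
#' @export
laplace_evidence <- function(fit) {
  stopifnot(inherits(fit, "cudn_fit"))
  laplace_log_evidence(fit$log_joint, fit$neg_hessian, loglik = fit$loglik,
                       n_obs = fit$n_trials)
}

#' Fit the model space to a cohort
#'
#' Fits every candidate model to every session and assembles the
#' subjects-by-models log evidence matrix consumed by [bms()].
#'
#' @param sessions List of session data frames.
#' @param specs List of [model_spec()]s (default: the 16-model space).
#' @param n_restarts Optimizer starts per fit.
#' @param seed Root seed; each subject-model pair gets a derived child seed.
#' @param nu_mean,nu_var Prior setting for `nu`, passed to
#'   [default_priors()].
#' @param progress Print one line per subject.
#' @return A list of class `cudn_cohort_fit`: `evidence` (matrix, rows =
#'   subjects, columns = model ids) and `fits` (list of lists of
#'   `cudn_fit`).
#' @export
fit_cohort <- function(sessions, specs = enumerate_model_space(),
                       n_restarts = 4L, seed = NULL, nu_mean = 0, nu_var = 2,
                       progress = FALSE) {
  n <- length(sessions)
  K <- length(specs)
  seeds <- matrix(child_seeds(seed, n * K), n, K)
  ev <- matrix(NA_real_, n, K,
               dimnames = list(names(sessions),
                               vapply(specs, function(s) paste0("m", s$id),
                                      character(1))))
  fits <- vector("list", n)
  for (i in seq_len(n)) {
    fits[[i]] <- vector("list", K)
    for (j in seq_len(K)) {
      pri <- default_priors(specs[[j]], nu_mean = nu_mean, nu_var = nu_var)
      f <- fit_map(sessions[[i]], specs[[j]], pri,
                   n_restarts = n_restarts, seed = seeds[i, j])
      fits[[i]][[j]] <- f
      ev[i, j] <- f$log_evidence
    }
    if (progress) message(sprintf("fitted subject %d/%d", i, n))
  }
  names(fits) <- names(sessions)
  structure(list(evidence = ev, fits = fits, specs = specs),
            class = "cudn_cohort_fit")
}

#' Susceptibility of model selection to the nu prior
#'
#' Refits the models that contain the suppression parameter `nu` under each
#' prior setting, reruns the random-effects model comparison with the other
#' models' evidences unchanged, and tabulates the protected exceedance
#' probabilities per setting.
#'
#' @param sessions List of session data frames.
#' @param nu_settings List of `c(mean, variance)` pairs for the `nu` prior.
#' @param specs Model space.
#' @param n_restarts,seed Passed to the fitting routines.
#' @param base_fit Optional `cudn_cohort_fit` under the default prior, reused
#'   for the models without `nu`.
#' @return A list of class `cudn_susceptibility`: `pep` (matrix, rows =
#'   settings, columns = models), `settings`, `bms` (list of [bms()]
#'   results).
#' @export
prior_susceptibility <- function(sessions, nu_settings = list(c(0, 1), c(0, 2)),
                                 specs = enumerate_model_space(),
                                 n_restarts = 4L, seed = NULL,
                                 base_fit = NULL) {
  stopifnot(length(nu_settings) >= 1L)
  has_nu <- vapply(specs, function(s)
    s$blame_effect %in% c("noise_independent", "noise_interaction"), logical(1))
  if (is.null(base_fit))
    base_fit <- fit_cohort(sessions, specs[!has_nu], n_restarts = n_restarts,
                           seed = seed)
  base_ev <- base_fit$evidence[, vapply(specs[!has_nu], function(s)
    paste0("m", s$id), character(1)), drop = FALSE]
  seeds <- child_seeds(seed, 2L)
  K <- length(specs)
  results <- vector("list", length(nu_settings))
  pep <- matrix(NA_real_, length(nu_settings), K,
                dimnames = list(NULL, vapply(specs, function(s)
                  paste0("m", s$id), character(1))))
  for (s in seq_along(nu_settings)) {
    set <- nu_settings[[s]]
    nu_fit <- fit_cohort(sessions, specs[has_nu], n_restarts = n_restarts,
                         seed = seeds[1L], nu_mean = set[1], nu_var = set[2])
    ev <- matrix(NA_real_, length(sessions), K,
                 dimnames = list(names(sessions), colnames(pep)))
    ev[, colnames(base_ev)] <- base_ev
    ev[, colnames(nu_fit$evidence)] <- nu_fit$evidence
    res <- bms(ev, seed = seeds[2L])
    results[[s]] <- res
    pep[s, ] <- res$pep
  }
  structure(list(pep = pep, settings = nu_settings, bms = results),
            class = "cudn_susceptibility")
}
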