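#' Hierarchical Gaussian filter parameters
#'
#' Parameters of the binary hierarchical Gaussian filter (HGF) that tracks
#' the latent cue--outcome contingency. Level 1 is the binary outcome ("cue 1
#' was correct"), level 2 its logit-scale tendency, level 3 the log-volatility
#' of level 2. With `levels = 2` the third level is frozen at its initial
#' mean, i.e. the environment's volatility is treated as constant at
#' `exp(kappa * mu3_0 + omega)`.
#'
#' @param kappa Coupling strength from level 3 to level 2 (> 0).
#' @param omega Tonic log-volatility of level 2.
#' @param theta Volatility of level 3 (> 0; ignored when `levels = 2`).
#' @param mu2_0,mu3_0 Initial posterior means of levels 2 and 3.
#' @param sigma2_0,sigma3_0 Initial posterior variances (> 0).
#' @param levels 2 or 3.
#' @return An object of class `cudn_hgf_params`.
#' @export
hgf_params <- function(kappa = 1, omega = -3, theta = exp(-6),
                       mu2_0 = 0, mu3_0 = 1, sigma2_0 = 1, sigma3_0 = 1,
                       levels = 3L) {
  levels <- as.integer(levels)
  if (!levels %in% c(2L, 3L)) stopf("levels must be 2 or 3")
  if (!is.finite(kappa) || kappa <= 0) stopf("kappa must be > 0")
  if (!is.finite(omega)) stopf("omega must be finite")
  if (levels == 3L && (!is.finite(theta) || theta <= 0))
    stopf("theta must be > 0 for the 3-level filter")
  if (sigma2_0 <= 0 || sigma3_0 <= 0) stopf("initial variances must be > 0")
  structure(list(kappa = kappa, omega = omega, theta = theta,
                 mu2_0 = mu2_0, mu3_0 = mu3_0,
                 sigma2_0 = sigma2_0, sigma3_0 = sigma3_0,
                 levels = levels),
            class = "cudn_hgf_params")
}

#' Initial HGF state
#'
#' @param params A [hgf_params()] object.
#' @return A list with posterior means and variances (`mu2`, `sigma2`, `mu3`,
#'   `sigma3`) at their initial values.
#' @export
hgf_init <- function(params) {
  stopifnot(inherits(params, "cudn_hgf_params"))
  list(mu2 = params$mu2_0, sigma2 = params$sigma2_0,
       mu3 = params$mu3_0, sigma3 = params$sigma3_0)
}

# exp() with a clipped argument; keeps the volatility increment finite for
# extreme level-3 excursions during optimization.
exp_clip <- function(x) exp(pmin(pmax(x, -36), 36))

#' HGF prediction step
#'
#' Pre-outcome predictions for the current trial: the predicted probability
#' that cue 1 is correct and the level-2 prediction variance, which is the
#' trial's estimation uncertainty. The prediction variance is the posterior
#' variance carried over from the previous trial plus the volatility
#' increment `exp(kappa * mu3 + omega)`; it is computed before the trial's
#' outcome is seen, because the decision precedes the feedback.
#'
#' @param state An HGF state as returned by [hgf_init()] or [hgf_update()].
#' @param params A [hgf_params()] object.
#' @return List with `muhat1` (predicted p(correct | cue 1)) and `sigmahat2`
#'   (estimation uncertainty).
#' @export
hgf_predict <- function(state, params) {
  stopifnot(inherits(params, "cudn_hgf_params"))
  if (!is.finite(state$mu2) || state$sigma2 <= 0)
    stopf("invalid HGF state")
  list(muhat1 = logistic(state$mu2),
       sigmahat2 = state$sigma2 + exp_clip(params$kappa * state$mu3 + params$omega))
}

#' HGF update step
#'
#' Standard variational update of the binary HGF after observing whether
#' cue 1 was correct on the trial. Level 2 is updated with the outcome
#' prediction error scaled by the posterior precision; level 3 (when present)
#' is updated with the level-2 volatility prediction error.
#'
#' @param state Current HGF state.
#' @param params A [hgf_params()] object.
#' @param outcome 0/1, whether cue 1 was the correct cue this trial. Both
#'   cues' outcomes are knowable because the task's correct probabilities are
#'   reciprocal.
#' @return The updated state (list with `mu2`, `sigma2`, `mu3`, `sigma3`).
#' @export
hgf_update <- function(state, params, outcome) {
  stopifnot(inherits(params, "cudn_hgf_params"))
  if (!(length(outcome) == 1L && outcome %in% c(0, 1)))
    stopf("outcome must be binary (cue 1 correct yes/no)")
  pred <- hgf_predict(state, params)
  muhat1 <- pred$muhat1
  sigmahat2 <- pred$sigmahat2

  da1 <- outcome - muhat1
  pihat2 <- 1 / sigmahat2
  pi2 <- pihat2 + muhat1 * (1 - muhat1)
  if (!is.finite(pi2) || pi2 <= 0)
    stopf("non-positive level-2 precision: parameter pathology")
  mu2_new <- state$mu2 + da1 / pi2
  sigma2_new <- 1 / pi2

  if (params$levels == 2L)
    return(list(mu2 = mu2_new, sigma2 = sigma2_new,
                mu3 = state$mu3, sigma3 = state$sigma3))

  # level-3 update from the level-2 volatility prediction error
  pihat3 <- 1 / (state$sigma3 + params$theta)
  w2 <- exp_clip(params$kappa * state$mu3 + params$omega) * pihat2
  da2 <- (sigma2_new + (mu2_new - state$mu2)^2) * pihat2 - 1
  pi3 <- pihat3 + 0.5 * params$kappa^2 * w2 * (w2 + (2 * w2 - 1) * da2)
  if (!is.finite(pi3) || pi3 <= 0)
    stopf("non-positive level-3 precision: parameter pathology")
  mu3_new <- state$mu3 + 0.5 * params$kappa * w2 * da2 / pi3
  list(mu2 = mu2_new, sigma2 = sigma2_new,
       mu3 = mu3_new, sigma3 = 1 / pi3)
}

#' Rescorla--Wagner parameters for the blame belief
#'
#' @param alpha Learning rate in \[0, 1\].
#' @param p0 Initial belief p(blame | wrong) in \[0, 1\].
#' @return An object of class `cudn_rw_params`.
#' @export
rw_params <- function(alpha = 0.2, p0 = 0.5) {
  if (!is_prob(alpha) || length(alpha) != 1L)
    stopf("alpha must be a probability in [0, 1]")
  if (!is_prob(p0) || length(p0) != 1L) stopf("p0 must be in [0, 1]")
  structure(list(alpha = alpha, p0 = p0), class = "cudn_rw_params")
}

#' Rescorla--Wagner update of the blame belief
#'
#' Delta-rule update of the subjective conditional blame probability,
#' `p' = p + alpha * (blame - p)`. It is only meaningful on trials where the
#' choice was wrong, because blame is unobservable otherwise; callers are
#' responsible for invoking it on wrong-choice trials only. The prediction
#' error `blame - p` is the blame prediction error (BPE).
#'
#' @param p Current belief in \[0, 1\].
#' @param alpha Learning rate in \[0, 1\].
#' @param blame_observed 0/1 blame feedback.
#' @return The updated belief, with the prediction error attached as
#'   attribute `"delta"`.
#' @export
rw_update <- function(p, alpha, blame_observed) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stopf("alpha must be in [0, 1]")
  if (!is_prob(p)) stopf("p must be in [0, 1]")
  if (!all(blame_observed %in% c(0, 1))) stopf("blame_observed must be binary")
  delta <- blame_observed - p
  structure(p + alpha * delta, delta = delta)
}

# Derive the per-trial binary series "cue 1 was correct" from choices and
# correct feedback; valid because feedback is reciprocal across cues.
session_outcomes <- function(session) {
  ifelse(session$choice == 1L, session$correct_feedback,
         1L - session$correct_feedback)
}

#' Run the perceptual model over a session
#'
#' Applies the HGF prediction/update loop and the Rescorla--Wagner blame
#' learner to a completed session, returning per-trial beliefs aligned so
#' that `muhat1`, `sigmahat2` and `pblame` at trial k are the pre-outcome
#' predictions available when the choice was made (no look-ahead). The blame
#' belief is updated only on wrong-choice trials.
#'
#' @param session A session data frame (see [simulate_session()]) with
#'   columns `choice`, `correct_feedback` and `blame_feedback`.
#' @param hgf A [hgf_params()] object.
#' @param rw A [rw_params()] object.
#' @return A data frame of class `cudn_trajectory`, one row per trial:
#'   `muhat1`, `sigmahat2`, `pblame`, `delta_b` (blame prediction error, `NA`
#'   on correct trials), `outcome`, and the post-update HGF states `mu2`,
#'   `sigma2`, `mu3`, `sigma3`.
#' @export
run_perceptual <- function(session, hgf = hgf_params(), rw = rw_params()) {
  stopifnot(inherits(hgf, "cudn_hgf_params"), inherits(rw, "cudn_rw_params"))
  need <- c("choice", "correct_feedback", "blame_feedback")
  if (!all(need %in% names(session)))
    stopf("session must contain columns %s", paste(need, collapse = ", "))
  if (anyNA(session[need])) stopf("missing feedback rows in session")
  outcome <- as.integer(session_outcomes(session))
  wrong <- as.integer(session$correct_feedback == 0L)
  m <- cudn_filter_cpp(outcome, wrong, as.integer(session$blame_feedback),
                       hgf$kappa, hgf$omega, hgf$theta,
                       hgf$mu2_0, hgf$mu3_0, hgf$sigma2_0, hgf$sigma3_0,
                       hgf$levels, rw$alpha, rw$p0)
  out <- as.data.frame(m)
  names(out) <- c("muhat1", "sigmahat2", "pblame", "delta_b",
                  "mu2", "sigma2", "mu3", "sigma3")
  out$delta_b[wrong == 0L] <- NA_real_
  out <- cbind(trial = seq_len(nrow(out)), out, outcome = outcome)
  class(out) <- c("cudn_trajectory", "data.frame")
  out
}

# Reference R implementation of the same filter, built from the exported
# step functions; used to validate the compiled path.
run_perceptual_r <- function(session, hgf = hgf_params(), rw = rw_params()) {
  outcome <- as.integer(session_outcomes(session))
  wrong <- session$correct_feedback == 0L
  n <- length(outcome)
  st <- hgf_init(hgf)
  p <- rw$p0
  out <- data.frame(trial = seq_len(n), muhat1 = NA_real_, sigmahat2 = NA_real_,
                    pblame = NA_real_, delta_b = NA_real_, mu2 = NA_real_,
                    sigma2 = NA_real_, mu3 = NA_real_, sigma3 = NA_real_,
                    outcome = outcome)
  for (k in seq_len(n)) {
    pr <- hgf_predict(st, hgf)
    out$muhat1[k] <- pr$muhat1
    out$sigmahat2[k] <- pr$sigmahat2
    out$pblame[k] <- p
    st <- hgf_update(st, hgf, outcome[k])
    out[k, c("mu2", "sigma2", "mu3", "sigma3")] <-
      unlist(st[c("mu2", "sigma2", "mu3", "sigma3")])
    if (wrong[k]) {
      pnew <- rw_update(p, rw$alpha, session$blame_feedback[k])
      out$delta_b[k] <- attr(pnew, "delta")
      p <- as.numeric(pnew)
    }
  }
  class(out) <- c("cudn_trajectory", "data.frame")
  out
}
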