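#' Response model parameters
#'
#' Parameters of the softmax response stage. `beta0` is the baseline log
#' inverse temperature; `zeta` scales how much estimation uncertainty lowers
#' the inverse temperature (the degree of uncertainty-induced decision noise,
#' UDN); `nu` scales how much the blame belief suppresses that uncertainty
#' effect (it may be negative); `lambda` weights the blame belief as a
#' (typically negative) value component and is used only by the value-family
#' models.
#'
#' @param beta0,zeta,nu,lambda Finite reals; `zeta >= 0`.
#' @return An object of class `cudn_response_params`.
#' @export
response_params <- function(beta0 = 0, zeta = 0, nu = 0, lambda = 0) {
  vals <- c(beta0 = beta0, zeta = zeta, nu = nu, lambda = lambda)
  if (!all(is.finite(vals))) stopf("response parameters must be finite")
  if (zeta < 0) stopf("zeta must be >= 0")
  structure(as.list(vals), class = "cudn_response_params")
}

#' Candidate model structure
#'
#' One cell of the factorial model space: how the blame belief enters the
#' response model (`none`, `value`, `noise_independent`,
#' `noise_interaction`), the depth of the perceptual filter (2- or 3-level
#' HGF) and whether the blame belief is learned by the Rescorla--Wagner rule
#' or held fixed at 0.5.
#'
#' @param blame_effect One of `"none"`, `"value"`, `"noise_independent"`,
#'   `"noise_interaction"`.
#' @param hgf_levels 2 or 3.
#' @param blame_learning `"rw"` or `"fixed"`.
#' @param id Optional integer id (assigned by [enumerate_model_space()]).
#' @return An object of class `cudn_model_spec`.
#' @export
model_spec <- function(blame_effect = c("noise_interaction", "none", "value",
                                        "noise_independent"),
                       hgf_levels = 3L, blame_learning = c("rw", "fixed"),
                       id = NULL) {
  blame_effect <- match.arg(blame_effect)
  blame_learning <- match.arg(blame_learning)
  hgf_levels <- as.integer(hgf_levels)
  if (!hgf_levels %in% c(2L, 3L)) stopf("hgf_levels must be 2 or 3")
  structure(list(blame_effect = blame_effect, hgf_levels = hgf_levels,
                 blame_learning = blame_learning, id = id),
            class = "cudn_model_spec")
}

#' Enumerate the 16-model candidate space
#'
#' The full factorial crossing of blame effect (4 levels), HGF depth (2) and
#' blame learning (2), in a fixed deterministic order. The CUDN model
#' (`noise_interaction`, 3-level HGF, RW blame learning) is the final id.
#'
#' @return A list of 16 [model_spec()] objects with ids 1 to 16.
#' @export
enumerate_model_space <- function() {
  grid <- expand.grid(
    blame_learning = c("fixed", "rw"),
    hgf_levels = c(2L, 3L),
    blame_effect = c("none", "value", "noise_independent", "noise_interaction"),
    stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    model_spec(blame_effect = grid$blame_effect[i],
               hgf_levels = grid$hgf_levels[i],
               blame_learning = grid$blame_learning[i], id = i))
}

#' The CUDN model specification
#'
#' Convenience accessor for the winning model structure: blame belief
#' suppresses uncertainty-induced decision noise in interaction with the
#' current uncertainty, beliefs tracked by the 3-level HGF, blame belief
#' learned by the Rescorla--Wagner rule.
#'
#' @return A [model_spec()] (id 16 in [enumerate_model_space()]).
#' @export
cudn_spec <- function() {
  space <- enumerate_model_space()
  hit <- vapply(space, function(s)
    s$blame_effect == "noise_interaction" && s$hgf_levels == 3L &&
      s$blame_learning == "rw", logical(1))
  space[[which(hit)]]
}

#' Softmax inverse temperature
#'
#' The trial-wise inverse temperature as a function of estimation uncertainty
#' and blame belief. For the interaction (CUDN) family,
#' `beta = exp(beta0 - (zeta - nu * pblame) * sigmahat2)`: uncertainty lowers
#' the inverse temperature (inducing decision noise) and the blame belief
#' counteracts that effect in proportion to the current uncertainty. For the
#' noise-independent family the blame effect is additive on the log scale,
#' `beta = exp(beta0 - zeta * sigmahat2 + nu * pblame)`. The value and
#' no-effect families use `beta = exp(beta0 - zeta * sigmahat2)`.
#'
#' @param sigmahat2 Estimation uncertainty (> 0); vectorized.
#' @param pblame Blame belief in \[0, 1\]; vectorized.
#' @param params A [response_params()] object.
#' @param spec A [model_spec()] object.
#' @return Positive finite inverse temperature(s).
#' @export
inverse_temperature <- function(sigmahat2, pblame, params, spec) {
  stopifnot(inherits(params, "cudn_response_params"),
            inherits(spec, "cudn_model_spec"))
  if (!all(is.finite(sigmahat2)) || any(sigmahat2 <= 0))
    stopf("sigmahat2 must be finite and > 0")
  if (!is_prob(pblame)) stopf("pblame must be in [0, 1]")
  log_beta <- switch(spec$blame_effect,
    noise_interaction = params$beta0 -
      (params$zeta - params$nu * pblame) * sigmahat2,
    noise_independent = params$beta0 - params$zeta * sigmahat2 +
      params$nu * pblame,
    params$beta0 - params$zeta * sigmahat2)
  exp(pmin(pmax(log_beta, -350), 350))
}

#' Softmax choice probabilities
#'
#' Probability of choosing each of the two cues given their predicted
#' correct probabilities, an inverse temperature, and an optional additive
#' bias on each cue's utility (used by the value-family models).
#'
#' @param values Length-2 vector, the predicted p(correct) of cues 1 and 2.
#' @param beta Inverse temperature (>= 0).
#' @param value_bias Length-2 additive utility bias (default none).
#' @return Length-2 vector of choice probabilities summing to 1.
#' @export
choice_probability <- function(values, beta, value_bias = c(0, 0)) {
  stopifnot(length(values) == 2L, length(value_bias) == 2L,
            is.finite(beta), beta >= 0)
  u <- values + value_bias
  d <- beta * (u[1] - u[2])
  p1 <- plogis(d)
  c(p1, 1 - p1)
}

# Per-trial probability of the observed choices, vectorized over a session;
# shared by session_loglik and the simulator-facing code.
choice_prob_series <- function(trajectory, params, spec) {
  pb <- if (spec$blame_learning == "fixed")
    rep(0.5, nrow(trajectory)) else trajectory$pblame
  u1 <- trajectory$muhat1
  u2 <- 1 - u1
  if (spec$blame_effect == "value") {
    # blame belief enters as a (negative-lambda) cost on each cue's failure
    # probability rather than through the decision temperature
    u1 <- u1 + params$lambda * (1 - trajectory$muhat1) * pb
    u2 <- u2 + params$lambda * trajectory$muhat1 * pb
  }
  beta <- inverse_temperature(trajectory$sigmahat2, pb, params, spec)
  p1 <- plogis(beta * (u1 - u2))
  cbind(p1, 1 - p1)
}

#' Session log-likelihood
#'
#' Sum over trials of the log probability of the observed choice under the
#' response model, given the belief trajectory. Probabilities are floored at
#' 1e-12 so the result is always finite.
#'
#' @param session Session data frame with a `choice` column.
#' @param trajectory Belief trajectory from [run_perceptual()], aligned to
#'   the session.
#' @param params A [response_params()] object.
#' @param spec A [model_spec()] object.
#' @return The log-likelihood (finite scalar).
#' @export
session_loglik <- function(session, trajectory, params, spec) {
  if (nrow(session) != nrow(trajectory))
    stopf("session (%d trials) and trajectory (%d) are misaligned",
          nrow(session), nrow(trajectory))
  pr <- choice_prob_series(trajectory, params, spec)
  p_obs <- ifelse(session$choice == 1L, pr[, 1], pr[, 2])
  sum(log(pmax(p_obs, 1e-12)))
}
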