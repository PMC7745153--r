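#' Agent parameters for simulation
#'
#' Bundles the perceptual, blame-learning and response parameters that govern
#' a simulated agent, plus the generative models for response time and mood,
#' which are observables of the task but not part of the choice model.
#'
#' The RT generator is log-normal with a location that increases with the
#' trial's deliberation index `D = pblame * sigmahat2`:
#' `rt = exp(mu_rt + kappa_rt * D + eps)`, `eps ~ N(0, sigma_rt)`. Agents
#' therefore slow down when blame is expected and the situation is uncertain,
#' mirroring the deliberation account of the high-blame RT effect.
#'
#' The mood generator emits, on probe trials,
#' `round(clip(m0 - w_blame * pblame + w_outcome * recent + noise, -3, 3))`
#' where `recent` is the correct rate over the last 8 trials: expecting blame
#' lowers mood, recent success raises it.
#'
#' @param hgf A [hgf_params()] object.
#' @param rw A [rw_params()] object.
#' @param resp A [response_params()] object.
#' @param rt_mu,rt_kappa,rt_sigma Log-normal RT model: baseline log-seconds,
#'   deliberation slope, residual SD.
#' @param mood_m0,mood_w_blame,mood_w_outcome,mood_sd Mood model: baseline,
#'   blame-belief weight, recent-outcome weight, noise SD.
#' @return An object of class `cudn_agent_params`.
#' @export
agent_params <- function(hgf = hgf_params(), rw = rw_params(),
                         resp = response_params(beta0 = 1.5, zeta = 1, nu = 1),
                         rt_mu = log(0.55), rt_kappa = 0.12, rt_sigma = 0.25,
                         mood_m0 = 1.5, mood_w_blame = 2, mood_w_outcome = 1,
                         mood_sd = 0.5) {
  stopifnot(inherits(hgf, "cudn_hgf_params"), inherits(rw, "cudn_rw_params"),
            inherits(resp, "cudn_response_params"))
  structure(list(hgf = hgf, rw = rw, resp = resp,
                 rt_mu = rt_mu, rt_kappa = rt_kappa, rt_sigma = rt_sigma,
                 mood_m0 = mood_m0, mood_w_blame = mood_w_blame,
                 mood_w_outcome = mood_w_outcome, mood_sd = mood_sd),
            class = "cudn_agent_params")
}

#' Simulate one session
#'
#' Forward run of the generative model on a schedule: at each trial the agent
#' forms its pre-outcome beliefs, chooses by the response model of `spec`,
#' receives correct and (on wrong choices) blame feedback sampled from the
#' schedule, and updates its beliefs. RT is sampled from the log-normal
#' deliberation model and mood from the probe-trial mood model (see
#' [agent_params()]).
#'
#' @param schedule A [generate_schedule()] result.
#' @param params An [agent_params()] object.
#' @param spec A [model_spec()]; defaults to the CUDN model.
#' @param seed Seed for reproducibility.
#' @param subject_id Identifier stored in the session.
#' @return A data frame of class `cudn_session`, one row per trial: `trial`,
#'   `choice`, `correct_feedback`, `blame_feedback`, `rt` (seconds), `mood`
#'   (integer in -3..3 on probe trials, `NA` otherwise), `subject_id`. The
#'   schedule is attached as attribute `"schedule"`.
#' @export
simulate_session <- function(schedule, params = agent_params(),
                             spec = cudn_spec(), seed = NULL,
                             subject_id = "s1") {
  stopifnot(inherits(schedule, "cudn_schedule"),
            inherits(params, "cudn_agent_params"),
            inherits(spec, "cudn_model_spec"))
  with_seed(seed, {
    n <- nrow(schedule)
    hgf <- params$hgf
    rw <- params$rw
    resp <- params$resp
    st <- hgf_init(hgf)
    pb <- rw$p0
    choice <- integer(n)
    correct <- integer(n)
    blame <- integer(n)
    rt <- numeric(n)
    mood <- rep(NA_integer_, n)
    for (k in seq_len(n)) {
      pred <- hgf_predict(st, hgf)
      pb_eff <- if (spec$blame_learning == "fixed") 0.5 else pb
      u <- c(pred$muhat1, 1 - pred$muhat1)
      bias <- if (spec$blame_effect == "value")
        resp$lambda * (1 - u) * pb_eff else c(0, 0)
      beta <- inverse_temperature(pred$sigmahat2, pb_eff, resp, spec)
      p_choice <- choice_probability(u, beta, bias)
      choice[k] <- if (runif(1) < p_choice[1]) 1L else 2L
      fb <- sample_feedback(schedule, k, choice[k])
      correct[k] <- fb["correct"]
      blame[k] <- fb["blame"]
      # deliberation index: blame expectation times current uncertainty
      D <- pb_eff * pred$sigmahat2
      rt[k] <- exp(params$rt_mu + params$rt_kappa * D +
                     rnorm(1, 0, params$rt_sigma))
      if (schedule$mood_probe[k]) {
        recent <- mean(correct[max(1L, k - 7L):k])
        raw <- params$mood_m0 - params$mood_w_blame * pb_eff +
          params$mood_w_outcome * recent + rnorm(1, 0, params$mood_sd)
        mood[k] <- as.integer(round(pmin(pmax(raw, -3), 3)))
      }
      outcome <- if (choice[k] == 1L) correct[k] else 1L - correct[k]
      st <- hgf_update(st, hgf, outcome)
      if (correct[k] == 0L) pb <- as.numeric(rw_update(pb, rw$alpha, blame[k]))
    }
    out <- data.frame(trial = seq_len(n), choice = choice,
                      correct_feedback = correct, blame_feedback = blame,
                      rt = rt, mood = mood, subject_id = subject_id,
                      stringsAsFactors = FALSE)
    attr(out, "schedule") <- schedule
    attr(out, "spec") <- spec
    class(out) <- c("cudn_session", "data.frame")
    out
  })
}

#' Default cohort parameter sampler
#'
#' Draws agent parameters for a simulated cohort. The response parameters are
#' centred on a regime in which agents perform in the human range of the task
#' (good-choice proportion around 0.7): `beta0 ~ N(1.5, 0.5^2)`,
#' `log zeta ~ N(0, 0.4^2)`, `nu ~ N(1, 0.25)` (the effect-present regime
#' used by the recovery studies), `logit alpha ~ N(-1.4, 0.5^2)`,
#' `omega ~ N(-3, 0.5^2)`, `log theta ~ N(-6, 0.5^2)`.
#'
#' @param n Number of subjects.
#' @param nu_mean,nu_sd Mean and SD of the suppression parameter `nu`.
#' @return A data frame with one row per subject and columns `beta0`, `zeta`,
#'   `nu`, `lambda`, `alpha`, `omega`, `theta`.
#' @export
default_param_sampler <- function(n, nu_mean = 1, nu_sd = 0.5) {
  data.frame(
    beta0 = rnorm(n, 1.5, 0.5),
    zeta = exp(rnorm(n, 0, 0.4)),
    nu = rnorm(n, nu_mean, nu_sd),
    lambda = rep(0, n),
    alpha = plogis(rnorm(n, -1.4, 0.5)),
    omega = rnorm(n, -3, 0.5),
    theta = exp(rnorm(n, -6, 0.5)))
}

# Build an agent_params object from one row of a parameter table.
params_from_row <- function(row, levels = 3L) {
  agent_params(
    hgf = hgf_params(omega = row$omega, theta = row$theta, levels = levels),
    rw = rw_params(alpha = row$alpha),
    resp = response_params(beta0 = row$beta0, zeta = row$zeta,
                           nu = row$nu, lambda = row$lambda))
}

#' Simulate a cohort
#'
#' Generates independent schedules and sessions for `n_subjects` agents whose
#' parameters are drawn from `param_sampler`, recording the true parameters
#' for recovery studies. Each subject gets child seeds derived from the root
#' seed by a fixed rule, so the cohort is bit-reproducible.
#'
#' @param n_subjects Number of agents (>= 1).
#' @param param_sampler Function `n -> data.frame` of true parameters per
#'   subject (see [default_param_sampler()]).
#' @param config A [schedule_config()].
#' @param spec A [model_spec()] governing the agents' choices.
#' @param seed Root seed.
#' @return A list of class `cudn_cohort` with elements `sessions` (list of
#'   `cudn_session`), `schedules`, and `params` (true-parameter data frame
#'   with `subject_id`).
#' @export
simulate_cohort <- function(n_subjects, param_sampler = default_param_sampler,
                            config = schedule_config(), spec = cudn_spec(),
                            seed = NULL) {
  stopifnot(n_subjects >= 1)
  seeds <- child_seeds(seed, 2L * n_subjects + 1L)
  truth <- with_seed(seeds[1L], param_sampler(n_subjects))
  truth$subject_id <- sprintf("s%02d", seq_len(n_subjects))
  sessions <- vector("list", n_subjects)
  schedules <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    schedules[[i]] <- generate_schedule(config, seed = seeds[2L * i])
    sessions[[i]] <- simulate_session(
      schedules[[i]], params_from_row(truth[i, ], levels = spec$hgf_levels),
      spec = spec, seed = seeds[2L * i + 1L], subject_id = truth$subject_id[i])
  }
  names(sessions) <- names(schedules) <- truth$subject_id
  structure(list(sessions = sessions, schedules = schedules, params = truth),
            class = "cudn_cohort")
}

#' Write or read a session as tab-separated text
#'
#' Sessions travel as tidy TSV, one row per trial, with the schedule columns
#' joined in so a file is self-contained.
#'
#' @param session A `cudn_session`.
#' @param path File path.
#' @return `write_session_tsv` returns `path` invisibly; `read_session_tsv`
#'   returns a `cudn_session` with its schedule attribute rebuilt.
#' @export
write_session_tsv <- function(session, path) {
  sch <- attr(session, "schedule")
  out <- cbind(session, sch[, setdiff(names(sch), "trial")])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_tsv
#' @export
read_session_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  sch_cols <- c("p_correct_cue1", "p_blame_given_wrong", "good_cue",
                "blame_block_label", "is_reversal_start", "mood_probe")
  ses_cols <- c("trial", "choice", "correct_feedback", "blame_feedback",
                "rt", "mood", "subject_id")
  if (!all(c(sch_cols, ses_cols) %in% names(d)))
    stopf("session file lacks required columns")
  sch <- d[, c("trial", sch_cols)]
  class(sch) <- c("cudn_schedule", "data.frame")
  out <- d[, ses_cols]
  attr(out, "schedule") <- sch
  class(out) <- c("cudn_session", "data.frame")
  out
}
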