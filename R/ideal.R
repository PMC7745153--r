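# Ideal Bayesian observer: a hidden-Markov filter over the task's generative
# probability levels with a constant reversal hazard, used as a performance
# benchmark for the simulated cohorts.

#' Ideal observer belief
#'
#' Posterior over the latent per-block probability that cue 1 is correct,
#' starting uniform. The latent state jumps, with probability `hazard` per
#' trial, uniformly to one of the states on the opposite side of 0.5
#' (encoding the task's alternating-reversal design) and otherwise stays.
#'
#' @param states Latent probability levels the observer entertains.
#' @param hazard Per-trial reversal probability. The default, 1/30, is the
#'   reciprocal of the mean block length under the 10--50 uniform range.
#' @return An object of class `cudn_ideal_belief` with fields `b`
#'   (posterior, sums to 1), `states`, `hazard`.
#' @export
ideal_belief <- function(states = c(0.2, 0.3, 0.7, 0.8), hazard = 1 / 30) {
  stopifnot(is_prob(states), length(states) >= 2L,
            is_prob(hazard), length(hazard) == 1L)
  structure(list(b = rep(1 / length(states), length(states)),
                 states = states, hazard = hazard),
            class = "cudn_ideal_belief")
}

# One transition step of the change-point process.
ideal_transition <- function(belief) {
  b <- belief$b
  lo <- belief$states < 0.5
  h <- belief$hazard
  bt <- (1 - h) * b
  for (i in seq_along(b)) {
    opp <- which(lo != lo[i])
    bt[opp] <- bt[opp] + h * b[i] / length(opp)
  }
  belief$b <- bt
  belief
}

# Predictive probability that cue 1 is correct on the upcoming trial
# (transition applied, outcome not yet seen).
ideal_predictive <- function(belief) {
  bt <- ideal_transition(belief)
  sum(bt$b * bt$states)
}

#' Ideal observer update
#'
#' Advances the belief by one trial: transition step (hazard-weighted jump to
#' the opposite side) followed by a Bayes update with the realized outcome.
#'
#' @param belief A [ideal_belief()] object.
#' @param observation 0/1, whether cue 1 was the correct cue this trial. The
#'   observer sees the realized correct cue regardless of its own choice,
#'   which is legitimate because the task's feedback is reciprocal.
#' @return The updated belief.
#' @export
ideal_update <- function(belief, observation) {
  stopifnot(inherits(belief, "cudn_ideal_belief"),
            length(observation) == 1L, observation %in% c(0, 1))
  belief <- ideal_transition(belief)
  lik <- if (observation == 1) belief$states else 1 - belief$states
  b <- belief$b * lik
  belief$b <- b / sum(b)
  belief
}

#' Ideal observer policy
#'
#' Maps a belief to a choice. The default greedy policy chooses cue 1 iff
#' the predictive probability that cue 1 is correct exceeds 0.5, with ties
#' broken uniformly at random. The stochastic alternatives are provided for
#' benchmarking: `"thompson"` samples a latent state from the (transitioned)
#' posterior and acts greedily on it; `"matching"` chooses cue 1 with the
#' predictive probability itself.
#'
#' @param belief A [ideal_belief()] object (pre-transition; the policy
#'   applies the upcoming trial's transition internally, consistent with
#'   [ideal_update()]).
#' @param policy `"greedy"`, `"thompson"` or `"matching"`.
#' @return Chosen cue, 1 or 2.
#' @export
ideal_policy <- function(belief, policy = c("greedy", "thompson", "matching")) {
  policy <- match.arg(policy)
  stopifnot(inherits(belief, "cudn_ideal_belief"))
  if (policy == "thompson") {
    bt <- ideal_transition(belief)
    s <- sample(bt$states, 1L, prob = bt$b)
    if (s > 0.5) return(1L)
    if (s < 0.5) return(2L)
    return(sample(1:2, 1L))
  }
  p <- ideal_predictive(belief)
  if (policy == "matching") return(if (runif(1) < p) 1L else 2L)
  if (p > 0.5) 1L else if (p < 0.5) 2L else sample(1:2, 1L)
}

#' Run the ideal observer over one schedule
#'
#' @param schedule A [generate_schedule()] result.
#' @param hazard,states Passed to [ideal_belief()].
#' @param policy Passed to [ideal_policy()].
#' @param seed Seed for outcome sampling (and stochastic policies).
#' @return A data frame with per-trial `choice`, `good_choice` (logical) and
#'   the predictive probability `p_cue1`.
#' @export
run_ideal_session <- function(schedule, hazard = 1 / 30,
                              states = c(0.2, 0.3, 0.7, 0.8),
                              policy = "greedy", seed = NULL) {
  stopifnot(inherits(schedule, "cudn_schedule"))
  with_seed(seed, {
    bel <- ideal_belief(states = states, hazard = hazard)
    n <- nrow(schedule)
    choice <- integer(n)
    p_cue1 <- numeric(n)
    for (k in seq_len(n)) {
      p_cue1[k] <- ideal_predictive(bel)
      choice[k] <- ideal_policy(bel, policy)
      obs <- rbinom(1L, 1L, schedule$p_correct_cue1[k])
      bel <- ideal_update(bel, obs)
    }
    data.frame(trial = seq_len(n), choice = choice,
               good_choice = choice == schedule$good_cue, p_cue1 = p_cue1)
  })
}

#' Ideal observer good-choice benchmark
#'
#' Mean proportion of trials on which the ideal observer chooses the
#' designed good cue, over freshly generated schedules.
#'
#' @param config A [schedule_config()].
#' @param n_sessions Number of schedules to average over.
#' @param hazard,states,policy Observer construction (see [ideal_belief()],
#'   [ideal_policy()]).
#' @param seed Root seed.
#' @return A list of class `cudn_benchmark`: `proportion`, `se` (Monte-Carlo
#'   standard error), `per_session`, `n_sessions`, `hazard`, `policy`.
#' @export
benchmark_good_choice <- function(config = schedule_config(),
                                  n_sessions = 200L, hazard = 1 / 30,
                                  states = c(0.2, 0.3, 0.7, 0.8),
                                  policy = "greedy", seed = NULL) {
  stopifnot(n_sessions >= 1L)
  seeds <- matrix(child_seeds(seed, 2L * n_sessions), ncol = 2L)
  per <- vapply(seq_len(n_sessions), function(i) {
    sch <- generate_schedule(config, seed = seeds[i, 1L])
    mean(run_ideal_session(sch, hazard = hazard, states = states,
                           policy = policy, seed = seeds[i, 2L])$good_choice)
  }, numeric(1))
  structure(list(proportion = mean(per),
                 se = sd(per) / sqrt(n_sessions),
                 per_session = per, n_sessions = n_sessions,
                 hazard = hazard, policy = policy),
            class = "cudn_benchmark")
}

#' @export
print.cudn_benchmark <- function(x, ...) {
  cat(sprintf("Ideal observer (%s policy, hazard %.4f): good choice %.3f +/- %.3f (%d sessions)\n",
              x$policy, x$hazard, x$proportion, x$se, x$n_sessions))
  invisible(x)
}

#' Benchmark sensitivity to observer construction
#'
#' Tabulates the good-choice benchmark across hazard rates and policies,
#' documenting how strongly the benchmark depends on the observer's
#' construction.
#'
#' @param config A [schedule_config()].
#' @param hazards Hazard rates to sweep.
#' @param policies Policies to sweep.
#' @param n_sessions Sessions per cell.
#' @param seed Root seed (shared across cells so schedules match).
#' @return Data frame with `hazard`, `policy`, `proportion`, `se`.
#' @export
benchmark_sensitivity <- function(config = schedule_config(),
                                  hazards = c(1 / 50, 1 / 30, 1 / 15),
                                  policies = c("greedy", "thompson", "matching"),
                                  n_sessions = 100L, seed = NULL) {
  grid <- expand.grid(hazard = hazards, policy = policies,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    b <- benchmark_good_choice(config, n_sessions = n_sessions,
                               hazard = grid$hazard[i],
                               policy = grid$policy[i], seed = seed)
    data.frame(hazard = grid$hazard[i], policy = grid$policy[i],
               proportion = b$proportion, se = b$se)
  })
  do.call(rbind, res)
}
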