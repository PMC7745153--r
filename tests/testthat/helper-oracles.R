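# Independent oracles used by the tests. These deliberately re-derive the
# quantities from first principles, without calling the package's own
# implementations.

# Step-by-step binary HGF recomputation with plain arithmetic.
oracle_hgf_trajectory <- function(outcomes, kappa, omega, theta,
                                  mu2_0 = 0, mu3_0 = 1,
                                  sigma2_0 = 1, sigma3_0 = 1, levels = 3L) {
  n <- length(outcomes)
  mu2 <- mu2_0; sigma2 <- sigma2_0; mu3 <- mu3_0; sigma3 <- sigma3_0
  out <- matrix(NA_real_, n, 4,
                dimnames = list(NULL, c("muhat1", "sigmahat2", "mu2", "mu3")))
  for (k in seq_len(n)) {
    muhat1 <- 1 / (1 + exp(-mu2))
    sigmahat2 <- sigma2 + exp(kappa * mu3 + omega)
    out[k, "muhat1"] <- muhat1
    out[k, "sigmahat2"] <- sigmahat2
    pihat2 <- 1 / sigmahat2
    pi2 <- pihat2 + muhat1 * (1 - muhat1)
    mu2_new <- mu2 + (outcomes[k] - muhat1) / pi2
    sigma2_new <- 1 / pi2
    if (levels == 3L) {
      pihat3 <- 1 / (sigma3 + theta)
      w2 <- exp(kappa * mu3 + omega) * pihat2
      da2 <- (sigma2_new + (mu2_new - mu2)^2) * pihat2 - 1
      pi3 <- pihat3 + 0.5 * kappa^2 * w2 * (w2 + (2 * w2 - 1) * da2)
      mu3 <- mu3 + 0.5 * kappa * w2 * da2 / pi3
      sigma3 <- 1 / pi3
    }
    mu2 <- mu2_new; sigma2 <- sigma2_new
    out[k, "mu2"] <- mu2
    out[k, "mu3"] <- mu3
  }
  out
}

# Exact posterior of the change-point observer by brute-force enumeration of
# all latent state paths (feasible for <= 8 trials). Transition: stay with
# probability 1 - h, jump uniformly to one of the opposite-side states with
# probability h. Returns the posterior over states after all observations.
oracle_ideal_posterior <- function(observations, states = c(0.2, 0.3, 0.7, 0.8),
                                   h = 1 / 30) {
  K <- length(states)
  lo <- states < 0.5
  n <- length(observations)
  trans <- function(i, j) {
    if (i == j) return(1 - h)
    if (lo[i] != lo[j]) return(h / sum(lo != lo[i]))
    0
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  post <- numeric(K)
  for (r in seq_len(nrow(paths))) {
    path <- paths[r, ]
    # prior over the state at trial 1: uniform then one transition step
    w <- sum(vapply(seq_len(K), function(i) (1 / K) * trans(i, path[1]),
                    numeric(1)))
    if (n > 1) for (t in 2:n) w <- w * trans(path[t - 1], path[t])
    for (t in seq_len(n)) {
      s <- states[path[t]]
      w <- w * if (observations[t] == 1) s else 1 - s
    }
    post[path[n]] <- post[path[n]] + w
  }
  post / sum(post)
}

# Gibbs sampler for the random-effects model selection mixture: alternates
# subject-level model assignments and the Dirichlet frequency vector.
oracle_bms_gibbs <- function(evidence, alpha0 = 1, n_iter = 4000L,
                             burn = 500L) {
  n <- nrow(evidence); K <- ncol(evidence)
  lev <- evidence - apply(evidence, 1, max)
  r <- rep(1 / K, K)
  acc <- numeric(K)
  kept <- 0L
  for (it in seq_len(n_iter)) {
    lw <- sweep(lev, 2, log(r), "+")
    z <- apply(lw, 1, function(x) {
      p <- exp(x - max(x)); sample.int(K, 1L, prob = p)
    })
    counts <- tabulate(z, K)
    g <- rgamma(K, alpha0 + counts)
    r <- g / sum(g)
    if (it > burn) { acc <- acc + r; kept <- kept + 1L }
  }
  acc / kept
}

# Tiny deterministic session for likelihood fixtures.
fixture_session <- function(n = 20L, seed = 1L) {
  sch <- suppressWarnings(generate_schedule(
    schedule_config(n_trials = n, correct_block_len_range = c(5L, 8L),
                    mood_probe_period = 8L), seed = seed))
  simulate_session(sch, agent_params(), seed = seed + 1L)
}

# Standard 240-trial session used across tests.
std_session <- function(seed = 1L, ...) {
  sch <- generate_schedule(schedule_config(seed = seed))
  simulate_session(sch, agent_params(...), seed = seed + 1000L)
}
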