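test_that("HGF prediction maps states to outcome probabilities correctly", {
  p <- hgf_params()
  st <- hgf_init(p)
  expect_equal(hgf_predict(st, p)$muhat1, 0.5)
  st$mu2 <- log(4)  # logistic(log 4) = 4/5
  expect_equal(hgf_predict(st, p)$muhat1, 0.8, tolerance = 1e-12)
  # vanishing volatility increment: prediction variance collapses to sigma2
  p_lo <- hgf_params(omega = -30)
  expect_equal(hgf_predict(st, p_lo)$sigmahat2, st$sigma2, tolerance = 1e-8)
})

test_that("HGF updates move beliefs toward the evidence", {
  p <- hgf_params()
  st <- hgf_init(p)
  up <- hgf_update(st, p, 1)
  expect_gt(up$mu2, st$mu2)
  expect_lt(hgf_update(st, p, 0)$mu2, st$mu2)
  expect_error(hgf_update(st, p, 2), "binary")
  # alternating outcomes keep the predicted probability in the 0.5 region
  st2 <- hgf_init(p)
  for (k in 1:200) st2 <- hgf_update(st2, p, k %% 2)
  expect_lt(abs(hgf_predict(st2, p)$muhat1 - 0.5), 0.15)
})

test_that("HGF trajectory equals an independent step-by-step recomputation", {
  ses <- std_session(seed = 3)
  outcomes <- ifelse(ses$choice == 1L, ses$correct_feedback,
                     1L - ses$correct_feedback)
  for (levels in c(3L, 2L)) {
    hp <- hgf_params(kappa = 1.3, omega = -2.5, theta = 0.02, levels = levels)
    traj <- run_perceptual(ses, hp, rw_params(alpha = 0.15))
    orc <- oracle_hgf_trajectory(outcomes, kappa = 1.3, omega = -2.5,
                                 theta = 0.02, levels = levels)
    expect_equal(traj$muhat1, unname(orc[, "muhat1"]), tolerance = 1e-10)
    expect_equal(traj$sigmahat2, unname(orc[, "sigmahat2"]), tolerance = 1e-10)
    expect_equal(traj$mu2, unname(orc[, "mu2"]), tolerance = 1e-10)
  }
})

test_that("compiled filter matches the exported R step functions exactly", {
  ses <- std_session(seed = 6)
  hp <- hgf_params(omega = -2.8, theta = 0.01)
  rp <- rw_params(alpha = 0.3, p0 = 0.4)
  a <- run_perceptual(ses, hp, rp)
  b <- cudn:::run_perceptual_r(ses, hp, rp)
  for (col in c("muhat1", "sigmahat2", "pblame", "mu2", "sigma2", "mu3",
                "sigma3", "delta_b"))
    expect_equal(a[[col]], b[[col]], tolerance = 1e-12)
})

test_that("3-level filter reduces to the 2-level filter as theta -> 0", {
  ses <- std_session(seed = 9)
  h3 <- hgf_params(omega = -3, theta = 1e-14, sigma3_0 = 1e-14, levels = 3L)
  h2 <- hgf_params(omega = -3, levels = 2L)
  t3 <- run_perceptual(ses, h3, rw_params())
  t2 <- run_perceptual(ses, h2, rw_params())
  expect_equal(t3$muhat1, t2$muhat1, tolerance = 1e-8)
  expect_equal(t3$sigmahat2, t2$sigmahat2, tolerance = 1e-8)
})

test_that("posterior variances stay positive across random parameter draws", {
  # parameters drawn over the documented stable region (omega clipped away
  # from the volatile boundary), many short sequences
  set.seed(42)
  for (rep in 1:400) {
    hp <- hgf_params(kappa = runif(1, 0.6, 1.3),
                     omega = runif(1, -6, -2),
                     theta = exp(runif(1, -9, -3)),
                     sigma2_0 = runif(1, 0.2, 2),
                     sigma3_0 = runif(1, 0.2, 2))
    st <- hgf_init(hp)
    for (k in 1:250) {
      st <- hgf_update(st, hp, rbinom(1, 1, 0.7))
      if (st$sigma2 <= 0 || st$sigma3 <= 0) break
    }
    expect_gt(st$sigma2, 0)
    expect_gt(st$sigma3, 0)
  }
})

test_that("Rescorla-Wagner updates follow the delta rule and stay bounded", {
  up <- rw_update(0.5, 0.2, 1)
  expect_equal(as.numeric(up), 0.6, tolerance = 1e-12)
  expect_equal(attr(up, "delta"), 0.5)
  expect_equal(as.numeric(rw_update(0.37, 0, 1)), 0.37)
  expect_equal(as.numeric(rw_update(0.37, 0, 0)), 0.37)
  expect_error(rw_update(0.5, 1.2, 1), "alpha")
  # boundedness for arbitrary alpha in [0, 1]
  set.seed(7)
  for (rep in 1:200) {
    p <- runif(1)
    a <- runif(1)
    for (k in 1:50) p <- as.numeric(rw_update(p, a, rbinom(1, 1, 0.5)))
    expect_true(p >= 0 && p <= 1)
  }
})

test_that("RW belief converges to the blame rate over wrong-choice trials", {
  # i.i.d. blame at rate 0.8, alpha = 0.1: the delta rule's stationary
  # distribution has mean 0.8 and variance alpha/(2 - alpha) * p(1 - p);
  # terminal beliefs concentrate accordingly
  set.seed(11)
  terminal <- replicate(400, {
    p <- 0.5
    for (k in 1:500) p <- as.numeric(rw_update(p, 0.1, rbinom(1, 1, 0.8)))
    p
  })
  sd_stat <- sqrt(0.1 / (2 - 0.1) * 0.8 * 0.2)
  expect_lt(abs(mean(terminal) - 0.8), 3 * sd_stat / sqrt(400))
  expect_gte(mean(abs(terminal - 0.8) <= 2.5 * sd_stat), 0.95)
})

test_that("the trajectory is aligned without look-ahead", {
  ses <- std_session(seed = 12)
  traj <- run_perceptual(ses)
  # trial k's prediction must be unchanged by permuting feedback from k on
  k <- 120L
  ses2 <- ses
  idx <- k:nrow(ses)
  set.seed(5)
  perm <- sample(idx)
  ses2$correct_feedback[idx] <- ses$correct_feedback[perm]
  ses2$blame_feedback[idx] <- ses$blame_feedback[perm]
  ses2$choice[idx] <- ses$choice[perm]
  traj2 <- run_perceptual(ses2)
  expect_equal(traj2$muhat1[1:k], traj$muhat1[1:k], tolerance = 1e-12)
  expect_equal(traj2$sigmahat2[1:k], traj$sigmahat2[1:k], tolerance = 1e-12)
  expect_equal(traj2$pblame[1:k], traj$pblame[1:k], tolerance = 1e-12)
})

test_that("blame belief only changes on wrong-choice trials", {
  ses <- std_session(seed = 15)
  traj <- run_perceptual(ses, rw = rw_params(alpha = 0.25, p0 = 0.5))
  pb <- c(traj$pblame, NA)
  moved <- which(abs(diff(traj$pblame)) > 0)
  expect_true(all(ses$correct_feedback[moved] == 0))
  # all-correct session: belief constant at p0
  ses_ac <- ses
  ses_ac$correct_feedback <- 1L
  ses_ac$blame_feedback <- 0L
  traj_ac <- run_perceptual(ses_ac, rw = rw_params(alpha = 0.25, p0 = 0.5))
  expect_true(all(traj_ac$pblame == 0.5))
  expect_true(all(is.na(traj_ac$delta_b)))
})

test_that("probability-scale estimation uncertainty peaks after reversals", {
  # the level-2 logit variance itself has a narrow range in this task; the
  # uncertainty that spikes at reversals is its projection onto the outcome
  # probability scale, var ~ (muhat1 (1 - muhat1))^2 * sigmahat2
  co <- simulate_cohort(8, seed = 21)
  ratios <- vapply(seq_along(co$sessions), function(i) {
    traj <- run_perceptual(co$sessions[[i]])
    lab <- label_trials(co$schedules[[i]])
    pvar <- (traj$muhat1 * (1 - traj$muhat1))^2 * traj$sigmahat2
    early <- lab$trials_since_reversal <= 5 & lab$trial > 10
    late <- lab$trials_since_reversal > 10
    mean(pvar[early]) / mean(pvar[late])
  }, numeric(1))
  expect_gt(mean(ratios), 1.1)
})
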