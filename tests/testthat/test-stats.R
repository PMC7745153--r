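test_that("trial labels partition the session and reset at reversals", {
  sch <- generate_schedule(schedule_config(seed = 61))
  lab <- label_trials(sch)
  expect_equal(nrow(lab), 240L)
  expect_true(all(lab$blame_label %in% c("high", "low")))
  expect_equal(which(lab$trials_since_reversal == 1L),
               which(sch$is_reversal_start))
  # single-block schedule: one label run and a 1..240 counter
  sch1 <- generate_schedule(
    schedule_config(correct_block_len_range = c(240, 240),
                    blame_block_len_range = c(240, 240), seed = 3))
  lab1 <- label_trials(sch1)
  expect_equal(lab1$trials_since_reversal, 1:240)
  expect_equal(length(unique(lab1$blame_label)), 1L)
})

test_that("per-subject metrics equal brute-force recomputation", {
  sch <- generate_schedule(schedule_config(seed = 62))
  ses <- simulate_session(sch, seed = 63)
  lab <- label_trials(sch)
  m <- good_choice_metrics(ses)
  for (cond in c("high", "low")) {
    sel <- sch$blame_block_label == cond
    row <- m[m$condition == cond, ]
    expect_equal(row$good_choice, mean((ses$choice == sch$good_cue)[sel]))
    expect_equal(row$accuracy, mean(ses$correct_feedback[sel]))
    expect_equal(row$rt, mean(ses$rt[sel]))
    early <- sel & lab$trials_since_reversal <= 10
    expect_equal(row$good_choice_early,
                 mean((ses$choice == sch$good_cue)[early]))
  }
  # an always-good agent scores 1 in both conditions
  ses1 <- ses
  ses1$choice <- sch$good_cue
  m1 <- good_choice_metrics(ses1)
  expect_equal(m1$good_choice, c(1, 1))
})

test_that("the early window counts trials as designed", {
  sch <- generate_schedule(
    schedule_config(correct_block_len_range = c(20, 20), seed = 64))
  lab <- label_trials(sch)
  # with exact 20-trial blocks, half of all trials fall in the first 10
  expect_equal(sum(lab$trials_since_reversal <= 10), 120L)
})

test_that("paired contrasts handle null, shifted and degenerate cohorts", {
  mk <- function(hi, lo) {
    n <- length(hi)
    data.frame(subject_id = rep(sprintf("s%d", 1:n), each = 2),
               condition = rep(c("high", "low"), n),
               n_trials = 120, good_choice = as.vector(rbind(hi, lo)),
               accuracy = as.vector(rbind(hi, lo)),
               rt = as.vector(rbind(hi, lo)),
               good_choice_early = as.vector(rbind(hi, lo)), n_early = 40)
  }
  x <- c(0.7, 0.6, 0.65, 0.72, 0.58)
  ct0 <- contrast_high_low(mk(x, x), "good_choice")
  expect_equal(ct0$statistic, 0)
  expect_equal(ct0$p_value, 1)
  ct1 <- contrast_high_low(mk(x + 0.05, x), "accuracy")
  expect_lt(ct1$p_value, 0.001)
  expect_gt(ct1$effect_size, 1)
  ctw <- contrast_high_low(mk(x + 0.05, x), "rt", test = "wilcoxon")
  expect_lt(ctw$p_value, 0.05)
  expect_error(contrast_high_low(mk(0.7, 0.6), "good_choice"), "2 subjects")
})

test_that("reversal curves rise for learners and stay flat for random play", {
  co <- simulate_cohort(10, seed = 71)
  rc <- reversal_curve(co, horizon = 15, n_boot = 200, seed = 1)
  expect_equal(nrow(rc), 30L)
  expect_true(all(rc$n_subjects <= 10))
  for (cond in c("high", "low")) {
    tr <- rc[rc$condition == cond, ]
    expect_gt(mean(tr$good_choice[tr$trials_since_reversal %in% 11:15]),
              mean(tr$good_choice[tr$trials_since_reversal %in% 1:3]))
  }
  # uniform-random agents: flat around one half
  rnd <- lapply(1:20, function(i) {
    sch <- generate_schedule(schedule_config(), seed = 100 + i)
    simulate_session(sch, agent_params(resp = response_params(beta0 = -30)),
                     seed = 200 + i)
  })
  rcr <- reversal_curve(rnd, horizon = 8, n_boot = 100, seed = 2)
  expect_lt(max(abs(rcr$good_choice - 0.5)), 0.15)
})

test_that("rank correlation of nu with enhancement behaves on toy tables", {
  mk <- function(diffs) {
    n <- length(diffs)
    data.frame(subject_id = rep(sprintf("s%d", 1:n), each = 2),
               condition = rep(c("high", "low"), n),
               n_trials = 120,
               good_choice = as.vector(rbind(0.6 + diffs, 0.6)),
               accuracy = as.vector(rbind(0.55 + diffs, 0.55)),
               rt = 0.6, good_choice_early = as.vector(rbind(0.6 + diffs, 0.6)),
               n_early = 40)
  }
  # anti-monotone: strictly decreasing differences against increasing nu
  res <- nu_performance_correlation(1:5, mk(c(0.5, 0.4, 0.3, 0.2, 0.1)))
  full <- res[res$outcome == "good_choice" & res$sample == "full", ]
  expect_equal(full$rho, -1, tolerance = 1e-12)
  # constant nu: undefined, flagged
  resc <- nu_performance_correlation(rep(1, 5), mk(c(0.5, 0.4, 0.3, 0.2, 0.1)))
  expect_true(all(resc$flagged))
  expect_true(all(is.na(resc$rho)))
  expect_error(nu_performance_correlation(1:3, mk(c(0.1, 0.2, 0.3))), "5 subjects")
})

test_that("the trimmed correlation drops far outliers only", {
  set.seed(81)
  nu <- c(rnorm(12, 1, 0.3), 6)  # one extreme point
  diffs <- 0.05 * nu + rnorm(13, 0, 0.01)
  mk <- data.frame(subject_id = rep(sprintf("s%02d", 1:13), each = 2),
                   condition = rep(c("high", "low"), 13),
                   n_trials = 120,
                   good_choice = as.vector(rbind(0.6 + diffs, 0.6)),
                   accuracy = as.vector(rbind(0.55 + diffs, 0.55)),
                   rt = 0.6, good_choice_early = as.vector(rbind(0.6 + diffs, 0.6)),
                   n_early = 40)
  res <- nu_performance_correlation(nu, mk)
  trimmed <- res[res$outcome == "good_choice" & res$sample == "trimmed", ]
  expect_equal(trimmed$n, 12L)
  expect_gt(trimmed$rho, 0.5)
})

test_that("mood analysis rejects degenerate inputs and excludes flat subjects", {
  co <- simulate_cohort(4, seed = 91)
  trajs <- lapply(seq_along(co$sessions), function(i)
    run_perceptual(co$sessions[[i]],
                   hgf_params(omega = co$params$omega[i],
                              theta = co$params$theta[i]),
                   rw_params(alpha = co$params$alpha[i])))
  # single probe per subject: per-subject fit impossible
  ses1 <- co$sessions[[1]]
  ses1$mood[which(!is.na(ses1$mood))[-1]] <- NA
  expect_error(mood_analysis(list(ses1), trajs[1]), "probes")
  # constant mood: excluded with a message, remaining subjects analysed
  ses2 <- co$sessions[[2]]
  ses2$mood[!is.na(ses2$mood)] <- 2L
  expect_message(
    res <- mood_analysis(c(list(ses2), co$sessions[3:4]),
                         c(trajs[2], trajs[3:4])),
    "constant")
  expect_equal(res$n, 2L)
  expect_length(res$excluded, 1L)
})
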