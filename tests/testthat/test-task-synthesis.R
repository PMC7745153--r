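test_that("generated schedules satisfy the task's structural invariants", {
  for (seed in c(1, 7, 31)) {
    sch <- generate_schedule(schedule_config(seed = seed))
    expect_equal(nrow(sch), 240L)
    expect_equal(sum(sch$mood_probe), 30L)
    expect_true(all(diff(which(sch$mood_probe)) == 8L))
    # reciprocity: cue 2's correct probability is 1 - cue 1's, so the good
    # cue is simply the one whose probability exceeds 0.5
    lev_dist <- vapply(sch$p_correct_cue1, function(p)
      min(abs(p - c(0.2, 0.3, 0.7, 0.8))), numeric(1))
    expect_lt(max(lev_dist), 1e-12)
    expect_identical(sch$good_cue, ifelse(sch$p_correct_cue1 > 0.5, 1L, 2L))
    expect_true(all(sch$p_blame_given_wrong %in% c(0.1, 0.2, 0.8, 0.9)))
    expect_identical(sch$blame_block_label,
                     ifelse(sch$p_blame_given_wrong >= 0.8, "high", "low"))
    # correct-probability blocks: lengths in range (final may truncate),
    # good cue alternating
    starts <- which(sch$is_reversal_start)
    lens <- diff(c(starts, 241L))
    expect_true(all(head(lens, -1) >= 10 & head(lens, -1) <= 50))
    expect_true(all(lens[length(lens)] <= 50))
    goods <- sch$good_cue[starts]
    expect_true(all(abs(diff(goods)) == 1L))
    # blame blocks: lengths in range except final, labels alternating
    bstart <- c(1L, which(diff(match(sch$blame_block_label,
                                     c("low", "high"))) != 0) + 1L)
    blens <- diff(c(bstart, 241L))
    expect_true(all(head(blens, -1) >= 20 & head(blens, -1) <= 40))
    labs <- sch$blame_block_label[bstart]
    expect_true(all(labs[-1] != head(labs, -1)))
  }
})

test_that("schedule generation is deterministic given the seed", {
  cfg <- schedule_config(seed = 99)
  expect_identical(generate_schedule(cfg), generate_schedule(cfg))
  expect_false(identical(generate_schedule(cfg, seed = 1),
                         generate_schedule(cfg, seed = 2)))
})

test_that("degenerate single-block schedule has no reversals after trial 1", {
  cfg <- schedule_config(correct_block_len_range = c(240, 240), seed = 4)
  sch <- generate_schedule(cfg)
  expect_equal(which(sch$is_reversal_start), 1L)
  expect_equal(length(unique(sch$p_correct_cue1)), 1L)
})

test_that("probe-period misalignment warns instead of failing", {
  expect_warning(generate_schedule(schedule_config(n_trials = 241, seed = 1)),
                 "divisible")
})

test_that("config validation rejects malformed inputs", {
  expect_error(schedule_config(n_trials = 0), "positive")
  expect_error(schedule_config(correct_block_len_range = c(50, 10)), "low <= high")
  expect_error(schedule_config(good_prob_levels = c(0.4, 0.8)), "exceed 0.5")
  expect_error(schedule_config(blame_high_levels = c(0, 0.9)), "inside")
})

test_that("feedback sampling respects the scheduled contingencies", {
  sch <- generate_schedule(schedule_config(seed = 11))
  expect_error(sample_feedback(sch, 1, 3), "cue")
  expect_error(sample_feedback(sch, 500, 1), "out of range")

  # degenerate probabilities pin the feedback exactly
  sch1 <- sch
  sch1$p_correct_cue1[1] <- 1
  fb <- replicate(20, sample_feedback(sch1, 1, 1L))
  expect_true(all(fb["correct", ] == 1) && all(fb["blame", ] == 0))
  sch1$p_correct_cue1[1] <- 0
  sch1$p_blame_given_wrong[1] <- 1
  fb <- replicate(20, sample_feedback(sch1, 1, 1L))
  expect_true(all(fb["correct", ] == 0) && all(fb["blame", ] == 1))

  # Monte-Carlo agreement with the Bernoulli parameters, 3 s.e. tolerance
  set.seed(21)
  k <- which(sch$p_correct_cue1 == 0.7)[1]
  draws <- replicate(20000, sample_feedback(sch, k, 1L))
  p_hat <- mean(draws["correct", ] == 1)
  expect_lt(abs(p_hat - 0.7), 3 * sqrt(0.7 * 0.3 / 20000))
  wrongs <- draws[, draws["correct", ] == 0]
  p_blame_hat <- mean(wrongs["blame", ] == 1)
  p_sched <- sch$p_blame_given_wrong[k]
  expect_lt(abs(p_blame_hat - p_sched),
            3 * sqrt(p_sched * (1 - p_sched) / ncol(wrongs)))
})

test_that("sessions respect the blame-feedback contingency and the seed", {
  sch <- generate_schedule(schedule_config(seed = 5))
  ses <- simulate_session(sch, seed = 9)
  expect_equal(nrow(ses), 240L)
  expect_true(all(ses$blame_feedback[ses$correct_feedback == 1] == 0))
  expect_identical(is.na(ses$mood), !sch$mood_probe)
  expect_true(all(ses$mood[!is.na(ses$mood)] %in% -3:3))
  expect_true(all(ses$rt > 0))
  expect_identical(ses, simulate_session(sch, seed = 9))
})

test_that("inverse temperature extremes pin choice behaviour", {
  sch <- generate_schedule(schedule_config(seed = 13))
  # near-deterministic agent: very high baseline inverse temperature
  hot <- agent_params(resp = response_params(beta0 = 12, zeta = 0, nu = 0))
  ses_hot <- simulate_session(sch, hot, seed = 2)
  lab <- label_trials(sch)
  late <- lab$trials_since_reversal > 10
  expect_gt(mean((ses_hot$choice == sch$good_cue)[late]), 0.85)
  # zero inverse temperature: uniform random choice
  cold <- agent_params(resp = response_params(beta0 = -30, zeta = 0, nu = 0))
  gc <- vapply(1:20, function(s)
    mean(simulate_session(sch, cold, seed = s)$choice == sch$good_cue),
    numeric(1))
  expect_lt(abs(mean(gc) - 0.5), 3 * sqrt(0.25 / (20 * 240)))
})

test_that("cohorts record true parameters and are seed-reproducible", {
  co <- simulate_cohort(4, config = schedule_config(), seed = 3)
  expect_length(co$sessions, 4L)
  expect_equal(nrow(co$params), 4L)
  expect_identical(names(co$sessions), co$params$subject_id)
  co2 <- simulate_cohort(4, config = schedule_config(), seed = 3)
  expect_identical(co$sessions, co2$sessions)
  expect_identical(co$params, co2$params)
  # degenerate sampler: all true-parameter rows identical
  pt <- function(n, ...) default_param_sampler(n, nu_mean = 1, nu_sd = 0)[
    rep(1, n), , drop = FALSE]
  cod <- simulate_cohort(3, pt, seed = 8)
  expect_equal(nrow(unique(cod$params[, 1:7])), 1L)
})

test_that("sessions survive a TSV round trip", {
  sch <- generate_schedule(schedule_config(seed = 17))
  ses <- simulate_session(sch, seed = 4)
  path <- tempfile(fileext = ".tsv")
  write_session_tsv(ses, path)
  back <- read_session_tsv(path)
  expect_equal(back$choice, ses$choice)
  expect_equal(back$rt, ses$rt, tolerance = 1e-12)
  expect_equal(attr(back, "schedule")$p_correct_cue1, sch$p_correct_cue1)
  unlink(path)
})
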