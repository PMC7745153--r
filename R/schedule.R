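#' Task schedule configuration
#'
#' Bundles the generative parameters of the probabilistic reversal learning
#' task with blame feedback: 240 trials in which the correct probability of
#' cue 1 (reciprocal to cue 2) reverses between the 0.2/0.3 and 0.7/0.8 ranges
#' every 10--50 trials, while an independent block structure (20--40 trials)
#' sets the conditional probability of blame feedback after a wrong choice to
#' a high (0.8/0.9) or low (0.1/0.2) level, alternating. Mood is probed every
#' `mood_probe_period` trials.
#'
#' @param n_trials Number of trials per session.
#' @param correct_block_len_range Integer pair, min/max length of a
#'   correct-probability block.
#' @param good_prob_levels Correct probabilities the designed good cue can
#'   take within a block.
#' @param blame_block_len_range Integer pair, min/max length of a blame block.
#' @param blame_high_levels,blame_low_levels Conditional blame probabilities
#'   available in high- and low-blame blocks.
#' @param mood_probe_period Mood is rated every this many trials.
#' @param seed Optional default seed used by [generate_schedule()].
#' @return An object of class `cudn_schedule_config`.
#' @seealso [generate_schedule()]
#' @export
schedule_config <- function(n_trials = 240L,
                            correct_block_len_range = c(10L, 50L),
                            good_prob_levels = c(0.7, 0.8),
                            blame_block_len_range = c(20L, 40L),
                            blame_high_levels = c(0.8, 0.9),
                            blame_low_levels = c(0.1, 0.2),
                            mood_probe_period = 8L,
                            seed = NULL) {
  n_trials <- as.integer(n_trials)
  if (length(n_trials) != 1L || is.na(n_trials) || n_trials <= 0L)
    stopf("n_trials must be a positive integer")
  check_range <- function(r, nm) {
    r <- as.integer(r)
    if (length(r) != 2L || any(is.na(r)) || r[1] < 1L || r[1] > r[2])
      stopf("%s must be an integer pair with 1 <= low <= high", nm)
    r
  }
  correct_block_len_range <- check_range(correct_block_len_range,
                                         "correct_block_len_range")
  blame_block_len_range <- check_range(blame_block_len_range,
                                       "blame_block_len_range")
  for (nm in c("good_prob_levels", "blame_high_levels", "blame_low_levels")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) < 1L || any(v <= 0 | v >= 1))
      stopf("%s must be probabilities strictly inside (0, 1)", nm)
  }
  if (any(good_prob_levels <= 0.5))
    stopf("good_prob_levels must exceed 0.5 (they belong to the good cue)")
  mood_probe_period <- as.integer(mood_probe_period)
  if (mood_probe_period < 1L) stopf("mood_probe_period must be >= 1")
  structure(
    list(n_trials = n_trials,
         correct_block_len_range = correct_block_len_range,
         good_prob_levels = good_prob_levels,
         blame_block_len_range = blame_block_len_range,
         blame_high_levels = blame_high_levels,
         blame_low_levels = blame_low_levels,
         mood_probe_period = mood_probe_period,
         seed = seed),
    class = "cudn_schedule_config")
}

# Draw consecutive block lengths until `n_trials` is covered (last block
# truncated), returning per-trial block index.
draw_blocks <- function(n_trials, len_range) {
  lens <- integer(0)
  while (sum(lens) < n_trials) {
    lens <- c(lens, if (len_range[1] == len_range[2]) len_range[1]
              else sample(len_range[1]:len_range[2], 1L))
  }
  rep(seq_along(lens), lens)[seq_len(n_trials)]
}

#' Generate a task schedule
#'
#' Draws one realization of the task's generative structure. Correct
#' probability blocks flip the designed good cue at every block boundary (a
#' reversal), with the good cue's probability re-drawn uniformly from
#' `good_prob_levels` each block. Blame blocks are drawn independently and
#' alternate high/low, with the level re-drawn uniformly within the label's
#' set each block.
#'
#' @param config A [schedule_config()].
#' @param seed Seed for reproducibility; defaults to `config$seed`.
#' @return A data frame of class `cudn_schedule` with one row per trial:
#'   `trial`, `p_correct_cue1`, `p_blame_given_wrong`, `good_cue`,
#'   `blame_block_label`, `is_reversal_start` (`TRUE` at the first trial of
#'   every correct-probability block, including trial 1), and `mood_probe`.
#' @examples
#' sch <- generate_schedule(schedule_config(seed = 1))
#' sum(sch$mood_probe)        # 30 mood probes
#' range(sch$p_correct_cue1)  # reciprocal probability levels
#' @export
generate_schedule <- function(config = schedule_config(), seed = config$seed) {
  stopifnot(inherits(config, "cudn_schedule_config"))
  if (config$n_trials %% config$mood_probe_period != 0L)
    warning("n_trials is not divisible by mood_probe_period; ",
            "the probe count will not match the usual 30", call. = FALSE)
  with_seed(seed, {
    n <- config$n_trials
    cblock <- draw_blocks(n, config$correct_block_len_range)
    n_cblocks <- max(cblock)
    first_good <- sample(1:2, 1L)
    good_by_block <- rep_len(c(first_good, 3L - first_good), n_cblocks)
    level_by_block <- sample(config$good_prob_levels, n_cblocks, replace = TRUE)
    good_cue <- good_by_block[cblock]
    good_level <- level_by_block[cblock]
    p1 <- ifelse(good_cue == 1L, good_level, 1 - good_level)

    bblock <- draw_blocks(n, config$blame_block_len_range)
    n_bblocks <- max(bblock)
    first_lab <- sample(c("high", "low"), 1L)
    lab_by_block <- rep_len(if (first_lab == "high") c("high", "low")
                            else c("low", "high"), n_bblocks)
    blev_by_block <- vapply(lab_by_block, function(l) {
      pool <- if (l == "high") config$blame_high_levels else config$blame_low_levels
      if (length(pool) == 1L) pool else sample(pool, 1L)
    }, numeric(1))
    out <- data.frame(
      trial = seq_len(n),
      p_correct_cue1 = p1,
      p_blame_given_wrong = blev_by_block[bblock],
      good_cue = good_cue,
      blame_block_label = lab_by_block[bblock],
      is_reversal_start = c(TRUE, diff(cblock) != 0L),
      mood_probe = seq_len(n) %% config$mood_probe_period == 0L,
      stringsAsFactors = FALSE)
    attr(out, "config") <- config
    class(out) <- c("cudn_schedule", "data.frame")
    out
  })
}

#' Sample trial feedback
#'
#' Samples the correct/wrong outcome of a choice and, conditionally on a
#' wrong choice, the blame feedback, using the current RNG stream.
#'
#' @param schedule A `cudn_schedule`.
#' @param k Trial index.
#' @param choice Chosen cue, 1 or 2.
#' @return Named integer vector `c(correct = 0/1, blame = 0/1)`; `blame` can
#'   only be 1 when `correct` is 0.
#' @export
sample_feedback <- function(schedule, k, choice) {
  stopifnot(inherits(schedule, "cudn_schedule"))
  if (!(k %in% seq_len(nrow(schedule)))) stopf("trial index %s out of range", k)
  if (!(length(choice) == 1L && choice %in% c(1L, 2L)))
    stopf("choice must be cue 1 or 2")
  p_corr <- if (choice == 1L) schedule$p_correct_cue1[k]
            else 1 - schedule$p_correct_cue1[k]
  correct <- rbinom(1L, 1L, p_corr)
  blame <- if (correct == 0L)
    rbinom(1L, 1L, schedule$p_blame_given_wrong[k]) else 0L
  c(correct = correct, blame = blame)
}
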