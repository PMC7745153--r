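# Behavioural statistics pipeline: block labels, per-subject metrics,
# high- vs low-blame contrasts, reversal-locked learning curves, the
# suppression-parameter/performance correlation, and the mood analysis.

#' Label trials by blame condition and time since reversal
#'
#' @param schedule A [generate_schedule()] result.
#' @return Data frame with `trial`, `blame_label` (`"high"`/`"low"`) and
#'   `trials_since_reversal` (1 at each correct-probability block start).
#' @export
label_trials <- function(schedule) {
  stopifnot(inherits(schedule, "cudn_schedule"))
  n <- nrow(schedule)
  tsr <- integer(n)
  for (k in seq_len(n))
    tsr[k] <- if (schedule$is_reversal_start[k] || k == 1L) 1L else tsr[k - 1L] + 1L
  data.frame(trial = seq_len(n), blame_label = schedule$blame_block_label,
             trials_since_reversal = tsr, stringsAsFactors = FALSE)
}

#' Per-subject behavioural metrics by blame condition
#'
#' Good-choice proportion (choosing the cue designed to have the higher
#' correct probability), accuracy (trials whose realized feedback was
#' "correct"), mean RT, and the early-window good-choice proportion
#' restricted to the first `window` trials after each reversal, separately
#' for high- and low-blame trials.
#'
#' @param session A session data frame.
#' @param labels Trial labels; defaults to [label_trials()] of the session's
#'   attached schedule.
#' @param window Early-window width in trials after a reversal (default 10).
#' @return Data frame with one row per blame condition: `subject_id`,
#'   `condition`, `n_trials`, `good_choice`, `accuracy`, `rt`,
#'   `good_choice_early`, `n_early`. Conditions with no trials are flagged
#'   with `NA` metrics.
#' @export
good_choice_metrics <- function(session, labels = NULL, window = 10L) {
  if (is.null(labels)) {
    sch <- attr(session, "schedule")
    if (is.null(sch)) stopf("no labels given and session carries no schedule")
    labels <- label_trials(sch)
  }
  if (nrow(labels) != nrow(session)) stopf("labels misaligned with session")
  sch <- attr(session, "schedule")
  good <- session$choice == sch$good_cue
  out <- lapply(c("high", "low"), function(cond) {
    sel <- labels$blame_label == cond
    early <- sel & labels$trials_since_reversal <= window
    data.frame(
      subject_id = session$subject_id[1], condition = cond,
      n_trials = sum(sel),
      good_choice = if (any(sel)) mean(good[sel]) else NA_real_,
      accuracy = if (any(sel)) mean(session$correct_feedback[sel]) else NA_real_,
      rt = if (any(sel)) mean(session$rt[sel]) else NA_real_,
      good_choice_early = if (any(early)) mean(good[early]) else NA_real_,
      n_early = sum(early), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Metrics for every subject of a cohort
#'
#' @param cohort A [simulate_cohort()] result or plain list of sessions.
#' @param window Early-window width, see [good_choice_metrics()].
#' @return Row-bound per-subject metric table.
#' @export
cohort_metrics <- function(cohort, window = 10L) {
  sessions <- if (inherits(cohort, "cudn_cohort")) cohort$sessions else cohort
  do.call(rbind, lapply(sessions, good_choice_metrics, window = window))
}

# Reshape a metric to paired per-subject high/low columns.
paired_metric <- function(metrics, metric) {
  hi <- metrics[metrics$condition == "high", c("subject_id", metric)]
  lo <- metrics[metrics$condition == "low", c("subject_id", metric)]
  m <- merge(hi, lo, by = "subject_id", suffixes = c("_high", "_low"))
  m <- m[complete.cases(m), ]
  m
}

#' High- vs low-blame contrast
#'
#' Two-tailed paired comparison of a per-subject metric between blame
#' conditions: paired t-test with Cohen's d (mean difference over SD of
#' differences) and a 95% CI for the mean difference, or a Wilcoxon
#' signed-rank test with the matched-pairs effect size Z / sqrt(n).
#'
#' @param metrics A [cohort_metrics()] table.
#' @param metric One of `"good_choice"`, `"accuracy"`, `"rt"`,
#'   `"good_choice_early"`.
#' @param test `"paired_t"` or `"wilcoxon"`.
#' @return An object of class `cudn_contrast`: `metric`, `test`, `n`,
#'   `mean_high`, `mean_low`, `mean_diff`, `statistic`, `p_value`,
#'   `effect_size`, `conf_int`.
#' @export
contrast_high_low <- function(metrics,
                              metric = c("good_choice", "accuracy", "rt",
                                         "good_choice_early"),
                              test = c("paired_t", "wilcoxon")) {
  metric <- match.arg(metric)
  test <- match.arg(test)
  m <- paired_metric(metrics, metric)
  if (nrow(m) < 2L) stopf("need at least 2 subjects with complete pairs")
  hi <- m[[paste0(metric, "_high")]]
  lo <- m[[paste0(metric, "_low")]]
  d <- hi - lo
  n <- length(d)
  if (test == "paired_t") {
    if (sd(d) == 0) {
      # zero-variance differences: exact null if all zero, otherwise a
      # degenerate certain alternative
      if (mean(d) == 0) {
        res <- list(statistic = 0, p.value = 1,
                    conf.int = c(0, 0))
        es <- 0
      } else {
        res <- list(statistic = sign(mean(d)) * Inf, p.value = 0,
                    conf.int = c(mean(d), mean(d)))
        es <- sign(mean(d)) * Inf
      }
    } else {
      tt <- t.test(hi, lo, paired = TRUE)
      res <- list(statistic = unname(tt$statistic), p.value = tt$p.value,
                  conf.int = as.numeric(tt$conf.int))
      es <- mean(d) / sd(d)
    }
  } else {
    wt <- suppressWarnings(wilcox.test(hi, lo, paired = TRUE, exact = FALSE,
                                       correct = TRUE))
    # matched-pairs effect size from the normal approximation of V
    mu_v <- n * (n + 1) / 4
    sd_v <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    z <- (unname(wt$statistic) - mu_v) / sd_v
    ci <- mean(d) + qt(c(0.025, 0.975), n - 1L) * sd(d) / sqrt(n)
    res <- list(statistic = z, p.value = wt$p.value, conf.int = ci)
    es <- z / sqrt(n)
  }
  structure(list(metric = metric, test = test, n = n,
                 mean_high = mean(hi), mean_low = mean(lo),
                 mean_diff = mean(d), statistic = res$statistic,
                 p_value = res$p.value, effect_size = es,
                 conf_int = res$conf.int),
            class = "cudn_contrast")
}

#' @export
print.cudn_contrast <- function(x, ...) {
  cat(sprintf("%s, high vs low blame (%s, n = %d)\n", x$metric, x$test, x$n))
  cat(sprintf("  %.3f vs %.3f (diff %.3f, 95%% CI %.3f..%.3f)\n",
              x$mean_high, x$mean_low, x$mean_diff,
              x$conf_int[1], x$conf_int[2]))
  cat(sprintf("  statistic = %.3f, p = %.4g, effect size = %.2f\n",
              x$statistic, x$p_value, x$effect_size))
  invisible(x)
}

#' Reversal-locked good-choice curve
#'
#' Mean good-choice proportion as a function of trials since the last
#' reversal, per blame condition, with subject-level bootstrap confidence
#' bands. Later positions of the horizon may draw on fewer trials (blocks
#' shorter than the horizon); the per-position subject counts are reported.
#'
#' @param cohort A [simulate_cohort()] result or list of sessions.
#' @param horizon Number of post-reversal positions (default 20).
#' @param n_boot Bootstrap replicates over subjects.
#' @param seed Bootstrap seed.
#' @return Data frame with `condition`, `trials_since_reversal`,
#'   `good_choice`, `lower`, `upper`, `n_subjects`.
#' @export
reversal_curve <- function(cohort, horizon = 20L, n_boot = 1000L,
                           seed = NULL) {
  stopifnot(horizon >= 1L)
  sessions <- if (inherits(cohort, "cudn_cohort")) cohort$sessions else cohort
  per_subj <- lapply(sessions, function(ses) {
    sch <- attr(ses, "schedule")
    lab <- label_trials(sch)
    good <- ses$choice == sch$good_cue
    out <- expand.grid(condition = c("high", "low"),
                       trials_since_reversal = seq_len(horizon),
                       stringsAsFactors = FALSE)
    out$good_choice <- mapply(function(cond, t) {
      sel <- lab$blame_label == cond & lab$trials_since_reversal == t
      if (any(sel)) mean(good[sel]) else NA_real_
    }, out$condition, out$trials_since_reversal)
    out
  })
  arr <- array(unlist(lapply(per_subj, `[[`, "good_choice")),
               dim = c(nrow(per_subj[[1]]), length(per_subj)))
  base <- per_subj[[1]][c("condition", "trials_since_reversal")]
  base$good_choice <- rowMeans(arr, na.rm = TRUE)
  base$n_subjects <- rowSums(!is.na(arr))
  bands <- with_seed(seed, {
    ns <- length(per_subj)
    boot <- replicate(n_boot, {
      idx <- sample.int(ns, ns, replace = TRUE)
      rowMeans(arr[, idx, drop = FALSE], na.rm = TRUE)
    })
    t(apply(boot, 1L, quantile, probs = c(0.025, 0.975), na.rm = TRUE))
  })
  base$lower <- bands[, 1L]
  base$upper <- bands[, 2L]
  base
}

#' Correlation between the suppression parameter and performance enhancement
#'
#' Spearman rank correlation between per-subject `nu` (the degree of
#' suppression of uncertainty-induced decision noise by the blame belief)
#' and the high-minus-low blame difference in good choice and accuracy, with
#' a sensitivity rerun excluding subjects whose value on either variable
#' lies more than 2 SD from its mean.
#'
#' @param nu Named (by subject id) or ordered numeric vector of per-subject
#'   `nu` estimates.
#' @param metrics A [cohort_metrics()] table for the same subjects.
#' @param window_metric Metric used for the good-choice difference
#'   (`"good_choice"` or `"good_choice_early"`).
#' @return An object of class `cudn_nu_correlation`: one row per outcome
#'   (`good_choice`, `accuracy`) and sample (`full`, `trimmed`) with
#'   Spearman's rho, p-value and n. Zero-variance inputs are flagged with
#'   `NA` rho.
#' @export
nu_performance_correlation <- function(nu, metrics,
                                       window_metric = "good_choice") {
  hi <- metrics[metrics$condition == "high", ]
  lo <- metrics[metrics$condition == "low", ]
  stopifnot(all(hi$subject_id == lo$subject_id))
  if (length(nu) != nrow(hi)) stopf("nu length does not match cohort size")
  if (!is.null(names(nu))) nu <- nu[hi$subject_id]
  if (length(nu) < 5L) stopf("need at least 5 subjects")
  diffs <- list(good_choice = hi[[window_metric]] - lo[[window_metric]],
                accuracy = hi$accuracy - lo$accuracy)
  one <- function(x, y, sample) {
    keep <- is.finite(x) & is.finite(y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 5L || sd(x) == 0 || sd(y) == 0)
      return(data.frame(sample = sample, rho = NA_real_, p_value = NA_real_,
                        n = length(x), flagged = TRUE))
    ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
    data.frame(sample = sample, rho = unname(ct$estimate),
               p_value = ct$p.value, n = length(x), flagged = FALSE)
  }
  out <- lapply(names(diffs), function(nm) {
    y <- diffs[[nm]]
    full <- one(nu, y, "full")
    keep <- abs(nu - mean(nu)) <= 2 * sd(nu) &
      abs(y - mean(y, na.rm = TRUE)) <= 2 * sd(y, na.rm = TRUE)
    trimmed <- one(nu[keep], y[keep], "trimmed")
    cbind(outcome = nm, rbind(full, trimmed))
  })
  structure(do.call(rbind, out), class = c("cudn_nu_correlation",
                                           "data.frame"))
}

#' Effect of the blame belief on mood
#'
#' Per-subject linear regression of probe-trial mood ratings on the
#' concurrent blame belief `p(blame|w)` with the recent correct rate (last 8
#' trials) as covariate, followed by a group-level two-tailed one-sample
#' t-test on the per-subject blame-belief coefficients.
#'
#' @param sessions List of session data frames with mood probes.
#' @param trajectories List of matching [run_perceptual()] trajectories.
#' @return An object of class `cudn_mood_analysis`: `coefficients`
#'   (per-subject blame-belief slopes), `excluded` (subject ids with
#'   degenerate mood data), `t`, `p_value`, `mean_coef`, `n`.
#' @export
mood_analysis <- function(sessions, trajectories) {
  stopifnot(length(sessions) == length(trajectories))
  coefs <- numeric(0)
  excluded <- character(0)
  for (i in seq_along(sessions)) {
    ses <- sessions[[i]]
    traj <- trajectories[[i]]
    probe <- which(!is.na(ses$mood))
    sid <- as.character(ses$subject_id[1])
    if (length(probe) < 3L)
      stopf("subject %s has %d mood probes; need >= 3 for a per-subject fit",
            sid, length(probe))
    recent <- vapply(probe, function(k)
      mean(ses$correct_feedback[max(1L, k - 7L):k]), numeric(1))
    d <- data.frame(mood = ses$mood[probe], pblame = traj$pblame[probe],
                    recent = recent)
    if (sd(d$mood) == 0 || sd(d$pblame) == 0) {
      excluded <- c(excluded, sid)
      message(sprintf("excluding subject %s: constant mood or blame belief", sid))
      next
    }
    fit <- lm(mood ~ pblame + recent, data = d)
    coefs <- c(coefs, stats::setNames(coef(fit)["pblame"], sid))
  }
  if (length(coefs) < 2L) stopf("fewer than 2 usable subjects")
  tt <- t.test(coefs)
  structure(list(coefficients = coefs, excluded = excluded,
                 t = unname(tt$statistic), p_value = tt$p.value,
                 mean_coef = mean(coefs), n = length(coefs)),
            class = "cudn_mood_analysis")
}

#' @export
print.cudn_mood_analysis <- function(x, ...) {
  cat(sprintf("Mood ~ p(blame|w): mean coefficient %.3f over %d subjects, t = %.2f, p = %.4g\n",
              x$mean_coef, x$n, x$t, x$p_value))
  if (length(x$excluded)) cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}
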