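#' Configuration for the amplitude-envelope freeze labeler
#'
#' The labeler marks a sample as frozen when the local oscillation
#' amplitude of the force trace — measured as the peak-to-peak range over a
#' centred rolling window — falls below a fraction of the trace's normal
#' stepping amplitude, and the low-amplitude run lasts at least
#' `min_freeze_duration`. The baseline stepping amplitude is estimated as
#' an upper quantile of the rolling ranges computed with a
#' `baseline_window`-wide window, which is robust to the trace containing
#' long frozen stretches (freezes occupy the low end of the range
#' distribution).
#'
#' @param baseline_window Window (centiseconds) for the rolling range used
#'   to estimate the normal stepping amplitude. Default 113, one average
#'   stepping cycle, so the window spans a full loading/unloading cycle.
#' @param amplitude_threshold Fraction of the baseline amplitude below
#'   which a sample is a freeze candidate (strictly between 0 and 1).
#' @param min_freeze_duration Minimum duration (centiseconds) of a maximal
#'   low-amplitude run for it to be labeled a freeze. Default 100 (1 s).
#' @param smoothing_window Window (centiseconds) of the rolling
#'   peak-to-peak range used for the per-sample envelope. Default 113.
#' @param baseline_quantile Quantile of rolling ranges taken as the
#'   baseline amplitude.
#' @return A list of class `labeler_config`.
#' @export
labeler_config <- function(baseline_window = 113,
                           amplitude_threshold = 0.4,
                           min_freeze_duration = 100,
                           smoothing_window = 113,
                           baseline_quantile = 0.9) {
  stopifnot(
    baseline_window > 0, smoothing_window > 0, min_freeze_duration > 0,
    amplitude_threshold > 0, amplitude_threshold < 1,
    baseline_quantile > 0, baseline_quantile <= 1
  )
  structure(
    list(
      baseline_window = as.integer(baseline_window),
      amplitude_threshold = amplitude_threshold,
      min_freeze_duration = as.integer(min_freeze_duration),
      smoothing_window = as.integer(smoothing_window),
      baseline_quantile = baseline_quantile
    ),
    class = "labeler_config"
  )
}

# Centred rolling peak-to-peak range with partial windows at the edges.
rolling_range <- function(x, window) {
  rmax <- zoo::rollapply(x, window, max, partial = TRUE, align = "center")
  rmin <- zoo::rollapply(x, window, min, partial = TRUE, align = "center")
  rmax - rmin
}

#' Label freeze samples in a force trace
#'
#' Assigns a 0/1 freeze label to every sample of a vertical force trace by
#' amplitude-envelope thresholding (see [labeler_config()]). Candidate
#' samples are those whose rolling peak-to-peak range falls below
#' `amplitude_threshold` times the baseline stepping amplitude; maximal
#' candidate runs shorter than `min_freeze_duration` are discarded, so no
#' labeled freeze is ever shorter than the minimum duration.
#'
#' @param trace A tibble with a `force` column (and optionally `t_cs`), as
#'   produced by [simulate_cohort()] or [read_trace()].
#' @param config A [labeler_config()].
#' @return The trace tibble with an integer `label_auto` column appended.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 1, trial_length = 3000))
#' labeled <- label_trace(cohort, labeler_config())
#' mean(labeled$label_auto == labeled$label)
label_trace <- function(trace, config = labeler_config()) {
  stopifnot("force" %in% names(trace))
  n <- nrow(trace)
  if (n < config$baseline_window) {
    abort(paste0("Trace of ", n, " samples is shorter than the baseline ",
                 "window (", config$baseline_window, " samples)."),
          class = "fogcast_invalid_input")
  }
  env <- rolling_range(trace$force, config$smoothing_window)
  baseline <- quantile(rolling_range(trace$force, config$baseline_window),
                       config$baseline_quantile, names = FALSE)
  candidate <- env < config$amplitude_threshold * baseline
  lab <- integer(n)
  runs <- episode_runs(as.integer(candidate))
  keep <- runs$length >= config$min_freeze_duration
  for (i in which(keep)) {
    lab[seq.int(runs$start[i] + 1L, runs$start[i] + runs$length[i])] <- 1L
  }
  dplyr::mutate(trace, label_auto = lab)
}

#' Label every subject of a cohort
#'
#' Applies [label_trace()] independently per subject.
#'
#' @param cohort A cohort tibble with `subject` and `force` columns.
#' @param config A [labeler_config()].
#' @return The cohort with a `label_auto` column appended.
#' @export
label_cohort <- function(cohort, config = labeler_config()) {
  cohort %>%
    group_by(.data$subject) %>%
    dplyr::group_modify(~ label_trace(.x, config)) %>%
    ungroup()
}

#' Agreement between predicted and ground-truth label sequences
#'
#' Per-sample accuracy plus episode-level recall and precision under a
#' 50%-overlap rule: a true episode counts as recalled when at least half
#' of its samples are predicted 1; a predicted episode counts as a true
#' positive when at least half of its samples overlap truth.
#'
#' @param predicted,truth Equal-length 0/1 vectors.
#' @return A one-row tibble: `accuracy`, `episode_recall`,
#'   `episode_precision`, `n_true_episodes`, `n_predicted_episodes`.
#'   Episode-level statistics are `NA` when the respective side has no
#'   episodes.
#' @export
label_agreement <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    abort("`predicted` and `truth` must have the same length.",
          class = "fogcast_invalid_input")
  }
  predicted <- as.integer(predicted)
  truth <- as.integer(truth)
  overlap_frac <- function(runs, other) {
    purrr::map_dbl(seq_along(runs$start), function(i) {
      idx <- seq.int(runs$start[i] + 1L, runs$start[i] + runs$length[i])
      mean(other[idx] == 1L)
    })
  }
  tr <- episode_runs(truth)
  pr <- episode_runs(predicted)
  recall <- if (length(tr$start)) mean(overlap_frac(tr, predicted) >= 0.5) else NA_real_
  precision <- if (length(pr$start)) mean(overlap_frac(pr, truth) >= 0.5) else NA_real_
  tibble(
    accuracy = mean(predicted == truth),
    episode_recall = recall,
    episode_precision = precision,
    n_true_episodes = length(tr$start),
    n_predicted_episodes = length(pr$start)
  )
}
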