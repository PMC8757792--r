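#' Simulation configuration for a stepping-in-place cohort
#'
#' Parameters for the synthetic vertical ground-reaction-force (GRF)
#' generator. A stepping-in-place trial produces a force trace that
#' oscillates quasi-periodically about body weight; freezing-of-gait (FoG)
#' episodes replace the stepping oscillation with low-amplitude output
#' around body weight, optionally with a higher-frequency trembling
#' component. Each freeze onset is preceded by a degradation interval over
#' which step amplitude decays and cadence slows, which is what makes
#' forecasting (rather than mere detection) possible.
#'
#' Time is expressed in centiseconds (cs); at the default 100 Hz sampling
#' rate one sample spans exactly one centisecond, so sample counts and
#' elapsed centiseconds coincide.
#'
#' Episode count and duration are controlled directly
#' (`episodes_per_trial_*`, `episode_duration_*`); the pooled freeze
#' fraction of the cohort is an emergent quantity that
#' [cohort_stats()] reports against `target_freeze_fraction`.
#'
#' @param n_subjects Number of subjects (one trial each).
#' @param trial_length Trial length in centiseconds. Trials in the stepping
#'   protocol last at least 90 s (recording continues until a freeze has
#'   occurred); the default 10700 cs is the mean length the cohort
#'   statistics jointly imply (3 episodes x 12.08 s at a 34% freeze
#'   fraction).
#' @param sampling_rate Sampling rate in Hz (default 100).
#' @param body_weight Baseline vertical force (arbitrary units, lbs-scale).
#' @param cycle_length_mean,cycle_length_sd Stepping cycle length mean/SD in
#'   centiseconds. Defaults 113 and 30 (four times a quarter-cycle of
#'   28.4 cs, SD 7.6 cs).
#' @param step_amplitude Oscillation amplitude as a fraction of body weight.
#' @param noise_sd Additive Gaussian measurement noise SD (force units).
#' @param episodes_per_trial_mean,episodes_per_trial_sd Mean/SD of the
#'   number of freeze episodes per trial (defaults 3 and 1.6; at least one
#'   episode is always scheduled).
#' @param episode_duration_mean,episode_duration_sd Mean/SD of episode
#'   duration in seconds (defaults 12.08 and 13.5); drawn from a
#'   moment-matched log-normal truncated below at `episode_duration_min`.
#' @param episode_duration_min Minimum episode duration in seconds.
#' @param target_freeze_fraction Intended pooled fraction of frozen samples;
#'   used as the calibration target reported by [cohort_stats()].
#' @param degradation_lead Pre-freeze degradation interval in centiseconds
#'   over which amplitude decays linearly toward the freeze regime and
#'   cadence slows.
#' @param cadence_drift Fractional slow-down of stepping frequency reached
#'   at freeze onset (0 = no drift).
#' @param tremble_freq_range Two-element Hz range for the trembling
#'   component during freezes.
#' @param tremble_amplitude Trembling amplitude as a fraction of
#'   `step_amplitude` (0 gives akinetic, flat freezes).
#' @param seed Integer seed making the cohort reproducible.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_cohort()], [episode_schedule()], [cohort_stats()]
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 2, trial_length = 3000, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' dplyr::count(cohort, subject)
sim_config <- function(n_subjects = 9,
                       trial_length = 10700,
                       sampling_rate = 100,
                       body_weight = 150,
                       cycle_length_mean = 113,
                       cycle_length_sd = 30,
                       step_amplitude = 0.4,
                       noise_sd = 3,
                       episodes_per_trial_mean = 3,
                       episodes_per_trial_sd = 1.6,
                       episode_duration_mean = 12.08,
                       episode_duration_sd = 13.5,
                       episode_duration_min = 1,
                       target_freeze_fraction = 0.34,
                       degradation_lead = 150,
                       cadence_drift = 0.3,
                       tremble_freq_range = c(3, 8),
                       tremble_amplitude = 0.1,
                       seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    trial_length = as.integer(trial_length),
    sampling_rate = sampling_rate,
    body_weight = body_weight,
    cycle_length_mean = cycle_length_mean,
    cycle_length_sd = cycle_length_sd,
    step_amplitude = step_amplitude,
    noise_sd = noise_sd,
    episodes_per_trial_mean = episodes_per_trial_mean,
    episodes_per_trial_sd = episodes_per_trial_sd,
    episode_duration_mean = episode_duration_mean,
    episode_duration_sd = episode_duration_sd,
    episode_duration_min = episode_duration_min,
    target_freeze_fraction = target_freeze_fraction,
    degradation_lead = degradation_lead,
    cadence_drift = cadence_drift,
    tremble_freq_range = tremble_freq_range,
    tremble_amplitude = tremble_amplitude,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_subjects >= 1,
    cfg$trial_length >= 1,
    cfg$sampling_rate > 0,
    cfg$body_weight > 0,
    cfg$cycle_length_mean > 0,
    cfg$cycle_length_sd >= 0,
    cfg$step_amplitude > 0,
    cfg$noise_sd >= 0,
    cfg$episodes_per_trial_mean > 0,
    cfg$episode_duration_mean > 0,
    cfg$episode_duration_min > 0,
    cfg$degradation_lead >= 0,
    cfg$cadence_drift >= 0, cfg$cadence_drift < 1,
    length(cfg$tremble_freq_range) == 2,
    all(cfg$tremble_freq_range > 0),
    cfg$tremble_amplitude >= 0
  )
  if (cfg$target_freeze_fraction <= 0 || cfg$target_freeze_fraction >= 1) {
    abort("`target_freeze_fraction` must lie strictly between 0 and 1.")
  }
  invisible(cfg)
}

# Episode counts are max(1, round(N(mu, sd))): every trial carries at least
# one episode. Clamping at 1 shifts the mean upward, so the latent mu is
# moment-matched (solved once per call) to make the clamped mean equal the
# configured mean.
draw_episode_count <- function(mean, sd) {
  clamped_mean <- function(mu) {
    k <- 1:200
    p <- stats::pnorm(k + 0.5, mu, sd) - stats::pnorm(k - 0.5, mu, sd)
    sum(k * p) + stats::pnorm(0.5, mu, sd) # mass below 0.5 maps to 1
  }
  mu <- if (sd > 0 && clamped_mean(mean) - mean > 1e-8) {
    stats::uniroot(function(m) clamped_mean(m) - mean,
                   c(mean - 3 * sd, mean))$root
  } else {
    mean
  }
  max(1L, as.integer(round(rnorm(1, mu, sd))))
}

# Log-normal (mu, sigma) matching a target mean and SD on the natural scale.
lnorm_params <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Schedule freeze episodes within one trial
#'
#' Draws the number of episodes and their durations, then places them in the
#' trial so that episodes do not overlap, are separated by at least one full
#' step cycle plus the degradation lead, and the first onset leaves room for
#' one cycle of normal stepping plus the degradation interval. Durations are
#' drawn from a log-normal moment-matched to the configured mean/SD and
#' truncated below at the minimum duration. Infeasible draws (episodes that
#' cannot fit the trial) are rejected and redrawn a bounded number of times,
#' with the episode count reduced as a last resort; a configuration that
#' cannot fit even one episode is an error.
#'
#' Uses the current RNG state; call inside a seeded context (as
#' [simulate_cohort()] does) for reproducibility.
#'
#' @param config A [sim_config()].
#' @param max_attempts Rejection-sampling budget before the episode count is
#'   reduced.
#' @return A tibble with integer columns `onset` (0-based sample index) and
#'   `duration` (samples), ordered by onset.
#' @export
episode_schedule <- function(config, max_attempts = 200L) {
  validate_sim_config(config)
  n <- config$trial_length
  rate <- config$sampling_rate
  sep <- ceiling(config$cycle_length_mean + config$degradation_lead)
  dur_par <- lnorm_params(config$episode_duration_mean * rate,
                          config$episode_duration_sd * rate)
  min_dur <- ceiling(config$episode_duration_min * rate)

  k <- draw_episode_count(config$episodes_per_trial_mean,
                          config$episodes_per_trial_sd)
  draw_durations <- function(k) {
    d <- numeric(k)
    for (i in seq_len(k)) {
      # truncated log-normal: redraw until above the minimum duration
      repeat {
        x <- stats::rlnorm(1, dur_par["meanlog"], dur_par["sdlog"])
        if (x >= min_dur) break
      }
      d[i] <- round(x)
    }
    d
  }

  durations <- draw_durations(k)
  # A trial cannot hold more freezing than its length: when the drawn
  # episodes do not fit, drop the shortest episode rather than redrawing
  # durations (redraws condition the kept durations on being short and
  # bias the realised mean down; the trial's dominant freezes are the
  # defining events and are preserved). Only the single-episode case
  # falls back to rejection sampling, so a configuration whose episodes
  # can never fit still errors out.
  while (sum(durations) + (k + 1) * sep > n && k > 1L) {
    durations <- durations[-which.min(durations)]
    k <- k - 1L
  }
  if (sum(durations) + 2 * sep > n) {
    feasible <- FALSE
    for (attempt in seq_len(max_attempts)) {
      durations <- draw_durations(1L)
      if (durations + 2 * sep <= n) {
        feasible <- TRUE
        break
      }
    }
    if (!feasible) {
      abort(paste0(
        "Infeasible simulation config: cannot fit one freeze episode ",
        "(minimum ", min_dur, " samples plus ", 2 * sep,
        " samples of separation) into a trial of ", n, " samples."
      ), class = "fogcast_infeasible_config")
    }
  }

  # distribute the leftover slack uniformly across the k + 1 inter-episode gaps
  slack <- n - sum(durations) - (k + 1) * sep
  cuts <- sort(runif(k, 0, slack))
  extra <- diff(c(0, cuts))
  onsets <- integer(k)
  pos <- 0
  for (i in seq_len(k)) {
    pos <- pos + sep + floor(extra[i])
    onsets[i] <- pos
    pos <- pos + durations[i]
  }
  tibble(onset = as.integer(onsets), duration = as.integer(durations))
}

# One stepping cycle of the loading waveform: a half-sine loading bump
# above body weight (weight acceptance on one side), a quarter-cycle dwell
# at body weight, a half-sine unloading trough (push-off on the other
# side), and a second dwell. Half-rectified alternating loading rather
# than a pure sinusoid: the dwells give normal stepping brief flat
# stretches at body weight, so distinguishing stepping from freezing
# genuinely requires seeing about one full cycle of data.
step_waveform <- function(phase) {
  p <- phase %% (2 * pi)
  out <- numeric(length(p))
  up <- p < pi / 2
  down <- p >= pi & p < 3 * pi / 2
  out[up] <- sin(2 * p[up])
  out[down] <- -sin(2 * (p[down] - pi))
  out
}

# Piecewise-constant stepping frequency (cycles per sample) from per-cycle
# lengths drawn around the configured mean.
stepping_frequency <- function(n, config) {
  f <- numeric(n)
  pos <- 0L
  lo <- max(20, config$cycle_length_mean - 3 * config$cycle_length_sd)
  while (pos < n) {
    len <- max(lo, round(rnorm(1, config$cycle_length_mean,
                               config$cycle_length_sd)))
    idx <- seq.int(pos + 1L, min(n, pos + len))
    f[idx] <- 1 / len
    pos <- pos + as.integer(len)
  }
  f
}

# One subject-trial: returns tibble(t_cs, force, label).
simulate_trace <- function(config, schedule = NULL) {
  n <- config$trial_length
  if (is.null(schedule)) schedule <- episode_schedule(config)
  lead <- config$degradation_lead

  label <- integer(n)
  for (i in seq_len(nrow(schedule))) {
    idx <- seq.int(schedule$onset[i] + 1L,
                   min(n, schedule$onset[i] + schedule$duration[i]))
    label[idx] <- 1L
  }

  # amplitude envelope (fraction of body weight) and cadence multiplier
  amp <- rep(config$step_amplitude, n)
  cad <- rep(1, n)
  floor_amp <- config$tremble_amplitude * config$step_amplitude
  for (i in seq_len(nrow(schedule))) {
    on <- schedule$onset[i]
    if (lead > 0) {
      idx <- seq.int(max(1L, on - lead + 1L), on)
      prog <- seq_along(idx) / length(idx)
      amp[idx] <- config$step_amplitude +
        (floor_amp - config$step_amplitude) * prog
      cad[idx] <- 1 - config$cadence_drift * prog
    }
  }

  freq <- stepping_frequency(n, config) * cad
  phase <- cumsum(2 * pi * freq) + runif(1, 0, 2 * pi)
  stepping <- config$body_weight * amp * step_waveform(phase)

  # freeze regime: flat about body weight plus optional trembling
  frozen <- label == 1L
  if (any(frozen)) {
    t_idx <- seq_len(n)
    for (i in seq_len(nrow(schedule))) {
      idx <- seq.int(schedule$onset[i] + 1L,
                     min(n, schedule$onset[i] + schedule$duration[i]))
      f_tr <- runif(1, config$tremble_freq_range[1],
                    config$tremble_freq_range[2])
      tremble <- config$body_weight * floor_amp *
        sin(2 * pi * f_tr * (t_idx[idx] - idx[1]) / config$sampling_rate)
      stepping[idx] <- tremble
    }
  }

  force <- config$body_weight + stepping
  if (config$noise_sd > 0) force <- force + rnorm(n, 0, config$noise_sd)

  tibble(t_cs = seq.int(0L, n - 1L), force = force, label = label)
}

#' Simulate a stepping-in-place cohort with freeze episodes
#'
#' Generates one vertical-force trial per subject. During normal stepping
#' the force oscillates quasi-periodically about body weight with the
#' configured cycle length; over the `degradation_lead` before each freeze
#' onset the oscillation amplitude decays linearly toward the freeze regime
#' and cadence slows; during a freeze the stepping oscillation is replaced
#' by low-amplitude output around body weight plus an optional trembling
#' component. Ground-truth labels mark frozen samples with 1.
#'
#' The cohort is bit-reproducible given the same configuration (including
#' its `seed`). Every trace contains at least one freeze episode.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `subject` (character), `t_cs` (integer
#'   centiseconds from 0), `force` (double) and `label` (integer 0/1
#'   ground truth).
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 1, trial_length = 2000))
#' mean(cohort$label)
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  purrr::map_dfr(seq_len(config$n_subjects), function(i) {
    tr <- simulate_trace(config)
    dplyr::mutate(tr, subject = sprintf("S%02d", i), .before = 1)
  })
}

#' Cohort descriptive statistics from ground-truth labels
#'
#' Computes, by run-length encoding of the per-sample labels, the pooled
#' freeze fraction, episode count per trial and episode durations. This is
#' the routine used to validate the simulator against its calibration
#' targets (freeze fraction near `target_freeze_fraction`, episode count
#' and duration near their configured means).
#'
#' @param cohort A cohort tibble with `subject` and a 0/1 label column.
#' @param label_col Name of the label column (default `"label"`).
#' @param sampling_rate Samples per second, to express durations in seconds.
#' @return A one-row tibble: `n_subjects`, `freeze_fraction`, `n_episodes`,
#'   `mean_episodes_per_trial`, `sd_episodes_per_trial`,
#'   `mean_episode_duration_s`, `sd_episode_duration_s`.
#' @export
cohort_stats <- function(cohort, label_col = "label", sampling_rate = 100) {
  stopifnot(label_col %in% names(cohort))
  per_subj <- cohort %>%
    group_by(.data$subject) %>%
    summarise(
      frozen = sum(.data[[label_col]]),
      total = dplyr::n(),
      runs = list(episode_runs(.data[[label_col]])),
      .groups = "drop"
    )
  durations <- unlist(purrr::map(per_subj$runs, "length"))
  counts <- purrr::map_int(per_subj$runs, ~ length(.x$length))
  tibble(
    n_subjects = nrow(per_subj),
    freeze_fraction = sum(per_subj$frozen) / sum(per_subj$total),
    n_episodes = sum(counts),
    mean_episodes_per_trial = mean(counts),
    sd_episodes_per_trial = sd(counts),
    mean_episode_duration_s = mean(durations) / sampling_rate,
    sd_episode_duration_s = sd(durations) / sampling_rate
  )
}

# Maximal runs of 1s in a binary vector: tibble(start [0-based], length).
episode_runs <- function(x) {
  r <- rle(as.integer(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values == 1L
  list(start = starts[keep], length = r$lengths[keep])
}
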