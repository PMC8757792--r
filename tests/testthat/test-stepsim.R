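test_that("simulated traces honour length, episode and determinism contracts", {
  cfg <- sim_config(n_subjects = 9, trial_length = 9000, seed = 4)
  cohort <- simulate_cohort(cfg)
  lens <- dplyr::count(cohort, subject)
  expect_equal(nrow(lens), 9)
  expect_true(all(lens$n == 9000))
  episodes <- cohort %>%
    dplyr::group_by(subject) %>%
    dplyr::summarise(n_ep = oracle_count_episodes(label)$n)
  expect_true(all(episodes$n_ep >= 1))
  expect_true(all(is.finite(cohort$force)))
  # bit-identical reproduction from the same (config, seed)
  expect_identical(cohort, simulate_cohort(cfg))
})

test_that("freeze segments are flat at body weight when tremble and noise are off", {
  cfg <- sim_config(n_subjects = 2, trial_length = 6000, seed = 9,
                    tremble_amplitude = 0, noise_sd = 0)
  cohort <- simulate_cohort(cfg)
  frozen <- cohort$force[cohort$label == 1L]
  expect_true(all(abs(frozen - cfg$body_weight) < 1e-9))
})

test_that("episode schedules respect separation, onset margin and feasibility", {
  cfg <- sim_config(seed = 1)
  min_gap <- cfg$cycle_length_mean + cfg$degradation_lead
  for (s in 1:20) {
    set.seed(s)
    sched <- episode_schedule(cfg)
    expect_true(all(sched$onset >= min_gap))
    expect_true(all(sched$onset + sched$duration <= cfg$trial_length))
    if (nrow(sched) > 1) {
      gaps <- sched$onset[-1] - (sched$onset + sched$duration)[-nrow(sched)]
      expect_true(all(gaps >= min_gap))
    }
  }
  set.seed(3); a <- episode_schedule(cfg)
  set.seed(3); b <- episode_schedule(cfg)
  expect_identical(a, b)
  # episodes that can never fit the trial signal an infeasible config
  bad <- sim_config(trial_length = 2000, episodes_per_trial_mean = 1,
                    episodes_per_trial_sd = 0, episode_duration_mean = 600,
                    episode_duration_sd = 1, episode_duration_min = 500)
  set.seed(1)
  expect_error(episode_schedule(bad), class = "fogcast_infeasible_config")
})

test_that("pooled freeze fraction of a 50-subject cohort lands near its target", {
  cohort <- simulate_cohort(sim_config(n_subjects = 50, seed = 12))
  frac <- mean(cohort$label)
  expect_gt(frac, 0.29)
  expect_lt(frac, 0.39)
})

test_that("normal stepping has the configured dominant period", {
  # jitter-free, noise-free: the autocorrelation peak is the cycle length
  cfg <- sim_config(n_subjects = 1, trial_length = 9000, noise_sd = 0,
                    cycle_length_sd = 0, seed = 3)
  tr <- simulate_cohort(cfg)
  runs <- rle(tr$label)
  first_freeze <- cumsum(runs$lengths)[which(runs$values == 1)[1] - 1]
  seg <- tr$force[seq_len(min(first_freeze - cfg$degradation_lead - 50, 3000))]
  a <- stats::acf(seg - mean(seg), lag.max = 180, plot = FALSE)$acf[-1]
  lags <- 60:180
  peak <- lags[which.max(a[lags])]
  expect_lte(abs(peak - cfg$cycle_length_mean), 2)
  # with cadence jitter the finite-segment period wanders only a few cs
  cfgj <- sim_config(n_subjects = 1, trial_length = 9000, noise_sd = 0,
                     seed = 3)
  trj <- simulate_cohort(cfgj)
  runsj <- rle(trj$label)
  ffj <- cumsum(runsj$lengths)[which(runsj$values == 1)[1] - 1]
  segj <- trj$force[seq_len(min(ffj - cfgj$degradation_lead - 50, 3000))]
  aj <- stats::acf(segj - mean(segj), lag.max = 180, plot = FALSE)$acf[-1]
  peakj <- lags[which.max(aj[lags])]
  expect_lte(abs(peakj - cfgj$cycle_length_mean), 10)
})

test_that("pre-freeze degradation sits strictly between stepping and freezing", {
  cfg <- sim_config(n_subjects = 6, trial_length = 9000, seed = 8)
  cohort <- simulate_cohort(cfg)
  mads <- cohort %>%
    dplyr::group_by(subject) %>%
    dplyr::group_map(function(d, ...) {
      runs <- oracle_count_episodes(d$label)
      onsets <- which(diff(c(0L, d$label)) == 1L) - 1L
      lead_idx <- unlist(lapply(onsets, function(o) {
        seq.int(max(1, o - cfg$degradation_lead + 1), o)
      }))
      frozen_idx <- which(d$label == 1L)
      normal_idx <- setdiff(seq_len(nrow(d)), c(lead_idx, frozen_idx))
      dev <- abs(d$force - cfg$body_weight)
      c(normal = mean(dev[normal_idx]), lead = mean(dev[lead_idx]),
        frozen = mean(dev[frozen_idx]))
    })
  for (m in mads) {
    expect_lt(m["frozen"], m["lead"])
    expect_lt(m["lead"], m["normal"])
  }
})

test_that("cohort statistics match the independent episode counter", {
  cohort <- simulate_cohort(sim_config(n_subjects = 10, seed = 2))
  st <- cohort_stats(cohort)
  ref <- cohort %>%
    dplyr::group_by(subject) %>%
    dplyr::summarise(res = list(oracle_count_episodes(label)))
  counts <- vapply(ref$res, function(r) r$n, integer(1))
  durs <- unlist(lapply(ref$res, function(r) r$durations))
  expect_equal(st$n_episodes, sum(counts))
  expect_equal(st$mean_episodes_per_trial, mean(counts))
  expect_equal(st$mean_episode_duration_s, mean(durs) / 100)
  expect_equal(st$freeze_fraction, mean(cohort$label))
})
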