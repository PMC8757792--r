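# Shared fixtures. The heavier objects (forecast cohort, sweeps) are built
# once per test run and cached, so several test files can reuse them.

suppressMessages(library(dplyr))

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, builder(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# A small ensemble configuration: full RF depth/weighting but fewer trees
# and a compact network, sized for cross-validated sweeps.
test_ensemble_config <- function(seed = 1L) {
  ensemble_config(rf_trees = 50L, nn_hidden = c(32L, 32L), nn_maxit = 150L,
                  seed = seed)
}

# The 9-subject forecasting cohort: 90 s trials, default degradation lead
# of 150 cs, automatic labels attached.
forecast_cohort <- function() {
  fixture("forecast_cohort", function() {
    cohort <- simulate_cohort(sim_config(n_subjects = 9, trial_length = 9000,
                                         seed = 11))
    label_cohort(cohort)
  })
}

# GL sweep of the forecast cohort at IL = 226 (all members + vote rules).
forecast_gl_sweep <- function() {
  fixture("forecast_gl_sweep", function() {
    sweep_f1(forecast_cohort(), il_values = 226,
             gl_values = c(0, 28, 57, 113),
             config = test_ensemble_config(), label_col = "label_auto")
  })
}

# IL sweep of the forecast cohort at GL = 0 (NB and RF).
forecast_il_sweep <- function() {
  fixture("forecast_il_sweep", function() {
    sweep_f1(forecast_cohort(), il_values = c(28, 57, 113, 226, 339),
             gl_values = 0, config = test_ensemble_config(),
             label_col = "label_auto", members = c("nb", "rf"))
  })
}

# A tiny, fast, well-separated two-class dataset: class 0 oscillates,
# class 1 is flat with a small offset.
separable_windows <- function(n_per_class = 40, il = 10, seed = 5) {
  set.seed(seed)
  X0 <- t(replicate(n_per_class,
                    sin(seq_len(il) + runif(1, 0, 2 * pi)) * 50 + 150 +
                      rnorm(il, 0, 2)))
  X1 <- t(replicate(n_per_class, rep(150, il) + rnorm(il, 0, 2)))
  X <- rbind(X0, X1)
  colnames(X) <- sprintf("f_%03d", seq_len(il))
  w <- dplyr::bind_cols(
    tibble::tibble(subject = rep(c("A", "B"), n_per_class),
                   start_cs = seq_len(2 * n_per_class),
                   label = rep(c(0L, 1L), each = n_per_class)),
    tibble::as_tibble(X)
  )
  structure(w, params = windowing_params(il = il, ol = 1),
            class = c("fog_windows", class(tibble::tibble())))
}

# A short two-subject cohort (identical dynamics) for fast LOSO tests.
mini_cohort <- function(n_subjects = 2, trial_length = 4000, seed = 21) {
  simulate_cohort(sim_config(n_subjects = n_subjects,
                             trial_length = trial_length, seed = seed))
}
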