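# A quick model trained once on two synthetic subjects.
stream_model <- function(il = 113) {
  fixture(paste0("stream_model_", il), function() {
    cohort <- mini_cohort(n_subjects = 2, trial_length = 5000, seed = 31)
    w <- window_cohort(cohort, windowing_params(il = il, gl = 0))
    fit_ensemble(w, ensemble_config(rf_trees = 30, nn_hidden = c(16, 16),
                                    nn_maxit = 100, seed = 2))
  })
}

test_that("emission schedule matches the sliding-window arithmetic", {
  model <- stream_model(226)
  trace <- mini_cohort(n_subjects = 1, trial_length = 1000, seed = 33)
  tl <- stream_predict(trace, model,
                       windowing_params(il = 226, gl = 0, tl = 1, ol = 10))
  expect_equal(nrow(tl), 78) # floor((999 - 226) / 10) + 1
  expect_equal(tl$t_cs[1], 226)
  expect_true(all(diff(tl$t_cs) == 10))
  expect_true(all(tl$minority >= tl$majority))
})

test_that("streaming equals batch windowed prediction at OL 10 and 28", {
  model <- stream_model(113)
  trace <- mini_cohort(n_subjects = 1, trial_length = 3000, seed = 35)
  for (ol in c(10L, 28L)) {
    p <- windowing_params(il = 113, gl = 0, tl = 1, ol = ol)
    tl <- stream_predict(trace, model, p)
    w <- window_trace(trace, p)
    votes <- ensemble_votes(model, w)
    expect_equal(tl$t_cs, w$start_cs + p$il + p$gl)
    expect_equal(tl$vote_nb, votes$nb)
    expect_equal(tl$vote_rf, votes$rf)
    expect_equal(tl$vote_nn, votes$nn)
    expect_equal(tl$minority, combine_votes(votes, "minority"))
    expect_equal(tl$gt, w$label)
  }
})

test_that("emissions are causal: future samples cannot change them", {
  model <- stream_model(113)
  trace <- mini_cohort(n_subjects = 1, trial_length = 2000, seed = 37)
  p <- windowing_params(il = 113, gl = 28, tl = 1, ol = 28)
  base <- stream_predict(trace, model, p)
  cut <- 1000L
  perturbed <- trace
  perturbed$force[(cut + 1):2000] <- rev(perturbed$force[(cut + 1):2000]) + 40
  got <- stream_predict(perturbed, model, p)
  # every emission whose input window lies before the perturbation agrees
  safe <- base$t_cs - p$gl - 1L < cut # last input sample index < cut
  expect_true(any(safe))
  expect_equal(got$vote_nb[safe], base$vote_nb[safe])
  expect_equal(got$vote_rf[safe], base$vote_rf[safe])
  expect_equal(got$vote_nn[safe], base$vote_nn[safe])
})

test_that("model/stream IL mismatch and short traces are rejected", {
  model <- stream_model(113)
  trace <- mini_cohort(n_subjects = 1, trial_length = 1000, seed = 39)
  expect_error(stream_predict(trace, model, windowing_params(il = 57)),
               class = "fogcast_invalid_input")
  expect_error(stream_predict(trace[1:50, ], model,
                              windowing_params(il = 113)),
               class = "fogcast_invalid_input")
})

fake_timeline <- function(gt, nb, rf, nn) {
  votes <- tibble::tibble(nb = nb, rf = rf, nn = nn)
  structure(
    tibble::tibble(t_cs = seq_along(gt), vote_nb = nb, vote_rf = rf,
                   vote_nn = nn,
                   minority = combine_votes(votes, "minority"),
                   majority = combine_votes(votes, "majority"),
                   gt = gt),
    class = c("fog_timeline", class(tibble::tibble()))
  )
}

test_that("timeline error rates follow the hand-enumerated vote table", {
  gt <- rep(c(1L, 0L), each = 10)
  perfect <- fake_timeline(gt, gt, gt, gt)
  rates <- timeline_error_rates(perfect)
  expect_true(all(rates$fp_rate == 0) && all(rates$fn_rate == 0))

  # members: always 1, always 0, equal to truth
  mixed <- fake_timeline(gt, rep(1L, 20), rep(0L, 20), gt)
  r <- timeline_error_rates(mixed)
  minority <- dplyr::filter(r, rule == "minority")
  majority <- dplyr::filter(r, rule == "majority")
  expect_equal(minority$fn, 0)
  expect_equal(majority$fn, 0)
  expect_equal(minority$fp, sum(gt == 0)) # the always-1 member fires alone
  expect_equal(majority$fp, 0)
  # member-mean counts: FP only from the always-1 member, FN from always-0
  expect_equal(minority$mfp, sum(gt == 0) / 3)
  expect_equal(minority$mfn, sum(gt == 1) / 3)
})

test_that("minority dominates majority in FN and is dominated in FP", {
  set.seed(41)
  for (i in 1:25) {
    gt <- rbinom(60, 1, 0.4)
    tl <- fake_timeline(gt, rbinom(60, 1, 0.5), rbinom(60, 1, 0.5),
                        rbinom(60, 1, 0.5))
    r <- timeline_error_rates(tl)
    expect_lte(r$fn[r$rule == "minority"], r$fn[r$rule == "majority"])
    expect_gte(r$fp[r$rule == "minority"], r$fp[r$rule == "majority"])
  }
})

test_that("timelines without ground truth cannot be scored", {
  tl <- fake_timeline(rep(1L, 4), rep(1L, 4), rep(0L, 4), rep(1L, 4))
  tl$gt <- NA_integer_
  expect_error(timeline_error_rates(tl), class = "fogcast_invalid_input")
})
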