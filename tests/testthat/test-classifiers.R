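two_class_windows <- function(x0, x1) {
  tibble::tibble(subject = "A",
                 start_cs = seq_len(length(x0) + length(x1)),
                 label = rep(c(0L, 1L), c(length(x0), length(x1))),
                 f_001 = c(x0, x1))
}

test_that("naive Bayes recovers hand-worked parameters and predictions", {
  w <- two_class_windows(c(-1, -1.1, -0.9), c(0.9, 1.0, 1.1))
  m <- fit_gaussian_nb(w)
  expect_equal(unname(m$stats[["0"]]$mean), -1)
  expect_equal(unname(m$stats[["1"]]$mean), 1)
  expect_equal(m$stats[["0"]]$prior, 0.5)
  expect_equal(m$stats[["1"]]$prior, 0.5)
  expect_equal(predict(m, matrix(0.95)), 1L)
  expect_equal(predict(m, matrix(-0.95)), 0L)
  expect_equal(sum(vapply(m$stats, `[[`, numeric(1), "prior")), 1,
               tolerance = 1e-12)
})

test_that("constant features are floored and keep log-likelihoods finite", {
  w <- tibble::tibble(subject = "A", start_cs = 1:6,
                      label = rep(0:1, each = 3),
                      f_001 = c(5, 5, 5, 1, 2, 3))
  m <- fit_gaussian_nb(w)
  expect_equal(unname(m$stats[["0"]]$var), m$variance_floor)
  ll <- predict(m, matrix(c(5, 2), ncol = 1), type = "loglik")
  expect_true(all(is.finite(ll)))
})

test_that("naive Bayes parameters match an independent per-class computation", {
  set.seed(33)
  X <- matrix(rnorm(50 * 4, 100, 10), 50, 4,
              dimnames = list(NULL, sprintf("f_%03d", 1:4)))
  y <- rbinom(50, 1, 0.4)
  y[1:2] <- c(0L, 1L)
  w <- dplyr::bind_cols(tibble::tibble(subject = "A", start_cs = 1:50,
                                       label = as.integer(y)),
                        tibble::as_tibble(X))
  m <- fit_gaussian_nb(w)
  ref <- oracle_nb_fit(X, y, m$variance_floor)
  for (cl in c("0", "1")) {
    expect_equal(unname(m$stats[[cl]]$mean), ref[[cl]]$mean)
    expect_equal(unname(m$stats[[cl]]$var), ref[[cl]]$var)
    expect_equal(m$stats[[cl]]$prior, ref[[cl]]$prior)
  }
})

test_that("single-class training data raises an explicit error", {
  w <- tibble::tibble(subject = "A", start_cs = 1:4, label = rep(0L, 4),
                      f_001 = rnorm(4))
  expect_error(fit_gaussian_nb(w), class = "fogcast_single_class")
  expect_error(fit_mlp(w), class = "fogcast_single_class")
  expect_error(fit_rf(w), class = "fogcast_single_class")
})

test_that("naive Bayes is invariant to row order", {
  w <- separable_windows()
  m1 <- fit_gaussian_nb(w)
  set.seed(1)
  w2 <- w[sample(nrow(w)), ]
  attr(w2, "params") <- attr(w, "params")
  m2 <- fit_gaussian_nb(w2)
  expect_equal(m1$stats, m2$stats)
})

test_that("ensemble members separate an easy dataset and are reproducible", {
  w <- separable_windows()
  cfg <- ensemble_config(rf_trees = 30, nn_hidden = c(16, 16), nn_maxit = 100,
                         seed = 2)
  fit <- fit_ensemble(w, cfg)
  votes <- ensemble_votes(fit, w)
  for (m in c("nb", "rf", "nn")) {
    expect_gte(f1_macro(w$label, votes[[m]]), 0.95)
  }
  fit2 <- fit_ensemble(w, cfg)
  expect_identical(ensemble_votes(fit2, w), votes)
})

test_that("raising the freeze-class weight does not lower freeze recall", {
  set.seed(44)
  il <- 8
  n0 <- 180; n1 <- 12 # imbalanced, overlapping classes
  X0 <- matrix(rnorm(n0 * il, 0, 1.5), n0, il)
  X1 <- matrix(rnorm(n1 * il, 1, 1.5), n1, il)
  X <- rbind(X0, X1); colnames(X) <- sprintf("f_%03d", seq_len(il))
  w <- dplyr::bind_cols(
    tibble::tibble(subject = "A", start_cs = seq_len(n0 + n1),
                   label = rep(c(0L, 1L), c(n0, n1))),
    tibble::as_tibble(X)
  )
  recall <- function(weight) {
    m <- fit_rf(w, num_trees = 100, class_weight = weight, seed = 7)
    pred <- predict(m, w)
    sum(pred == 1L & w$label == 1L) / sum(w$label == 1L)
  }
  expect_gte(recall(100), recall(1))
})

test_that("vote rules implement minority/majority and their containment", {
  v <- tibble::tibble(nb = c(0L, 1L, 1L), rf = c(0L, 1L, 0L),
                      nn = c(1L, 0L, 0L))
  expect_equal(combine_votes(v, "minority"), c(1L, 1L, 1L))
  expect_equal(combine_votes(v, "majority"), c(0L, 1L, 0L))
  expect_equal(combine_votes(v, "nb_only"), v$nb)
  expect_error(combine_votes(v, "plurality"))
  set.seed(6)
  for (i in 1:20) {
    vv <- tibble::tibble(nb = rbinom(50, 1, 0.5), rf = rbinom(50, 1, 0.5),
                         nn = rbinom(50, 1, 0.5))
    expect_true(all(combine_votes(vv, "minority") >=
                      combine_votes(vv, "majority")))
  }
  expect_error(combine_votes(v[, 1:2], "minority"),
               class = "fogcast_invalid_input")
})

test_that("naive Bayes matches brute-force density products on random data", {
  set.seed(77)
  for (case in 1:40) {
    n <- sample(10:30, 1); p <- sample(1:4, 1)
    X <- matrix(rnorm(n * p, 0, sample(c(0.5, 1, 5), 1)), n, p,
                dimnames = list(NULL, sprintf("f_%03d", seq_len(p))))
    y <- rbinom(n, 1, 0.5)
    y[1:2] <- c(0L, 1L)
    w <- dplyr::bind_cols(tibble::tibble(subject = "A", start_cs = seq_len(n),
                                         label = as.integer(y)),
                          tibble::as_tibble(X))
    m <- fit_gaussian_nb(w)
    Xnew <- matrix(rnorm(20 * p), 20, p)
    ref <- oracle_nb_predict(oracle_nb_fit(X, y, m$variance_floor), Xnew)
    expect_equal(predict(m, Xnew), ref)
  }
})
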