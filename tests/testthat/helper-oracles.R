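# Independent reference implementations used as oracles. These are kept
# deliberately naive (double loops, direct density products) and separate
# from the package's vectorised code paths.

# Naive double-loop windowing: enumerate every candidate start, copy the
# input sample by sample, look up the target labels directly.
oracle_windows <- function(force, labels, il, gl, tl, ol) {
  n <- length(force)
  wl <- il + gl + tl
  out <- list()
  s <- 0L
  while (s + wl <= n) {
    input <- numeric(il)
    for (j in seq_len(il)) input[j] <- force[s + j]
    lab <- 0L
    for (j in seq_len(tl)) {
      if (labels[s + il + gl + j] == 1L) lab <- 1L
    }
    out[[length(out) + 1L]] <- list(start = s, input = input, label = lab)
    s <- s + ol
  }
  out
}

# Direct Gaussian density-product naive Bayes: per-class mean/variance by
# explicit loops, prediction by multiplying dnorm values on the log scale
# feature by feature.
oracle_nb_fit <- function(X, y, variance_floor) {
  out <- list()
  for (cl in c(0L, 1L)) {
    Xc <- X[y == cl, , drop = FALSE]
    mu <- sig2 <- numeric(ncol(X))
    for (j in seq_len(ncol(X))) {
      mu[j] <- sum(Xc[, j]) / nrow(Xc)
      sig2[j] <- max(sum((Xc[, j] - mu[j])^2) / nrow(Xc), variance_floor)
    }
    out[[as.character(cl)]] <- list(prior = nrow(Xc) / nrow(X),
                                    mean = mu, var = sig2)
  }
  out
}

oracle_nb_predict <- function(fit, X) {
  pred <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    score <- c("0" = 0, "1" = 0)
    for (cl in c("0", "1")) {
      s <- log(fit[[cl]]$prior)
      for (j in seq_len(ncol(X))) {
        s <- s + stats::dnorm(X[i, j], fit[[cl]]$mean[j],
                              sqrt(fit[[cl]]$var[j]), log = TRUE)
      }
      score[cl] <- s
    }
    pred[i] <- as.integer(score["1"] > score["0"])
  }
  pred
}

# Confusion-matrix macro F1, written against the textbook definitions.
oracle_f1 <- function(truth, pred) {
  f1s <- numeric(2)
  for (i in 1:2) {
    cl <- i - 1L
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1s[i] <- if (tp + fp + fn == 0) {
      1
    } else if (is.na(prec) || is.na(rec) || prec + rec == 0) {
      0
    } else {
      2 * prec * rec / (prec + rec)
    }
  }
  mean(f1s)
}

# Independent episode counter over a 0/1 vector.
oracle_count_episodes <- function(x) {
  d <- diff(c(0L, as.integer(x)))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  if (length(ends) < length(starts)) ends <- c(ends, length(x))
  list(n = length(starts), durations = ends - starts + 1L)
}
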