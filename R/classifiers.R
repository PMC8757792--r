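#' Fit a Gaussian naive Bayes classifier
#'
#' Implements the benchmark classifier directly: class priors are the
#' relative label frequencies and, feature by feature, each class gets a
#' Gaussian with maximum-likelihood (biased) sample mean and variance.
#' Prediction picks the class maximising
#' `log P(y) + sum_i log N(x_i; mu_yi, sigma2_yi)`. Variances are floored
#' at a small positive constant so constant features keep finite
#' log-likelihoods.
#'
#' @param windows A `fog_windows` tibble (or any tibble with an integer
#'   `label` column and `f_*` feature columns).
#' @param variance_floor Lower bound applied to every per-class feature
#'   variance. Default `1e-9` times the mean pooled feature variance (or
#'   `1e-12` if that is zero).
#' @return An object of class `fog_nb`.
#' @export
#' @examples
#' w <- tibble::tibble(label = rep(0:1, each = 3),
#'                     f_001 = c(-1, -1.1, -0.9, 0.9, 1, 1.1))
#' m <- fit_gaussian_nb(w)
#' predict(m, matrix(c(0.95, -0.95), ncol = 1))
fit_gaussian_nb <- function(windows, variance_floor = NULL) {
  X <- window_matrix(windows)
  y <- as.integer(windows$label)
  classes <- sort(unique(y))
  if (length(classes) < 2) {
    abort("Training data contains a single class; cannot fit naive Bayes.",
          class = "fogcast_single_class")
  }
  if (is.null(variance_floor)) {
    pooled <- mean(apply(X, 2, function(v) mean((v - mean(v))^2)))
    variance_floor <- if (pooled > 0) 1e-9 * pooled else 1e-12
  }
  stopifnot(variance_floor > 0)
  stats_by_class <- lapply(classes, function(cl) {
    Xc <- X[y == cl, , drop = FALSE]
    mu <- colMeans(Xc)
    v <- colMeans(sweep(Xc, 2, mu)^2) # MLE (biased) variance
    list(prior = nrow(Xc) / nrow(X), mean = mu,
         var = pmax(v, variance_floor))
  })
  names(stats_by_class) <- as.character(classes)
  structure(
    list(classes = classes, stats = stats_by_class,
         variance_floor = variance_floor, n_features = ncol(X),
         features = colnames(X), n = nrow(X)),
    class = "fog_nb"
  )
}

nb_loglik <- function(object, X) {
  sapply(object$stats, function(s) {
    const <- -0.5 * sum(log(2 * pi * s$var))
    quad <- rowSums(sweep(sweep(X, 2, s$mean)^2, 2, s$var, "/"))
    log(s$prior) + const - 0.5 * quad
  })
}

#' Predict with a Gaussian naive Bayes model
#'
#' @param object A `fog_nb` model.
#' @param newdata A numeric matrix (IL columns) or a `fog_windows` tibble.
#' @param type `"class"` for 0/1 labels (ties broken toward 0, the
#'   no-freeze class) or `"loglik"` for the per-class joint
#'   log-likelihoods.
#' @param ... Unused.
#' @return Integer labels, or a matrix of log-likelihoods.
#' @export
predict.fog_nb <- function(object, newdata, type = c("class", "loglik"), ...) {
  type <- match.arg(type)
  X <- if (is.matrix(newdata)) newdata else window_matrix(newdata)
  if (ncol(X) != object$n_features) {
    abort(sprintf("Model expects %d features, got %d.",
                  object$n_features, ncol(X)),
          class = "fogcast_invalid_input")
  }
  ll <- nb_loglik(object, X)
  if (!is.matrix(ll)) {
    ll <- matrix(ll, nrow = 1, dimnames = list(NULL, names(ll)))
  }
  if (type == "loglik") return(ll)
  as.integer(ll[, "1"] > ll[, "0"]) # strict: ties fall to class 0
}

#' @export
tidy.fog_nb <- function(x, ...) {
  purrr::map_dfr(names(x$stats), function(cl) {
    tibble(class = as.integer(cl), feature = x$features,
           mean = unname(x$stats[[cl]]$mean),
           variance = unname(x$stats[[cl]]$var))
  })
}

#' @export
glance.fog_nb <- function(x, ...) {
  tibble(n = x$n, n_features = x$n_features,
         prior_0 = x$stats[["0"]]$prior, prior_1 = x$stats[["1"]]$prior,
         variance_floor = x$variance_floor)
}

## ---- multilayer perceptron -------------------------------------------------

relu <- function(z) pmax(z, 0)

mlp_shapes <- function(p, hidden) {
  sizes <- c(p, hidden, 1L)
  purrr::map(seq_len(length(sizes) - 1L),
             ~ c(sizes[.x], sizes[.x + 1L]))
}

mlp_unpack <- function(theta, shapes) {
  out <- vector("list", length(shapes))
  pos <- 0L
  for (l in seq_along(shapes)) {
    nw <- shapes[[l]][1] * shapes[[l]][2]
    W <- matrix(theta[pos + seq_len(nw)], shapes[[l]][1], shapes[[l]][2])
    pos <- pos + nw
    b <- theta[pos + seq_len(shapes[[l]][2])]
    pos <- pos + shapes[[l]][2]
    out[[l]] <- list(W = W, b = b)
  }
  out
}

mlp_forward <- function(layers, X) {
  A <- X
  acts <- vector("list", length(layers))
  L <- length(layers)
  for (l in seq_len(L)) {
    Z <- sweep(A %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
    A <- if (l < L) relu(Z) else 1 / (1 + exp(-Z))
    acts[[l]] <- list(Z = Z, A = A)
  }
  list(prob = as.numeric(acts[[L]]$A), acts = acts)
}

#' Fit a multilayer perceptron for freeze forecasting
#'
#' A fully connected feed-forward network with rectified-linear hidden
#' layers and a logistic output, trained by minimising the L2-penalised
#' binary cross-entropy with the limited-memory BFGS optimiser
#' (`optim(method = "L-BFGS-B")`) using analytic backpropagation
#' gradients. The default architecture is 5 hidden layers of 100 units.
#' Inputs are standardised internally (centre/scale stored in the model);
#' this is a conditioning choice for the optimiser, invisible to callers.
#'
#' @param windows A `fog_windows` tibble with both classes present.
#' @param hidden Integer vector of hidden-layer widths.
#' @param decay L2 penalty weight (per-sample, applied to weights only).
#' @param maxit Optimiser iteration cap.
#' @param seed Seed for the weight initialisation.
#' @return An object of class `fog_mlp`.
#' @export
fit_mlp <- function(windows, hidden = rep(100L, 5), decay = 1e-4,
                    maxit = 500L, seed = 1L) {
  X <- window_matrix(windows)
  y <- as.numeric(windows$label)
  if (length(unique(y)) < 2) {
    abort("Training data contains a single class; cannot fit the network.",
          class = "fogcast_single_class")
  }
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  n <- nrow(Xs)
  shapes <- mlp_shapes(ncol(Xs), hidden)

  set.seed(seed)
  theta0 <- unlist(purrr::map(shapes, function(sh) {
    c(rnorm(sh[1] * sh[2], 0, sqrt(2 / sh[1])), numeric(sh[2])) # He init
  }))

  eps <- 1e-12
  obj <- function(theta) {
    layers <- mlp_unpack(theta, shapes)
    p <- pmin(pmax(mlp_forward(layers, Xs)$prob, eps), 1 - eps)
    bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
    l2 <- sum(purrr::map_dbl(layers, ~ sum(.x$W^2)))
    bce + decay * l2 / (2 * n)
  }
  grad <- function(theta) {
    layers <- mlp_unpack(theta, shapes)
    fw <- mlp_forward(layers, Xs)
    L <- length(layers)
    delta <- matrix((fw$prob - y) / n, ncol = 1)
    g <- vector("list", L)
    for (l in rev(seq_len(L))) {
      A_prev <- if (l == 1) Xs else fw$acts[[l - 1]]$A
      gW <- crossprod(A_prev, delta) + (decay / n) * layers[[l]]$W
      gb <- colSums(delta)
      g[[l]] <- c(as.numeric(gW), gb)
      if (l > 1) {
        delta <- (delta %*% t(layers[[l]]$W)) *
          (fw$acts[[l - 1]]$Z > 0)
      }
    }
    unlist(g)
  }

  fit <- optim(theta0, obj, grad, method = "L-BFGS-B",
               control = list(maxit = maxit))
  structure(
    list(layers = mlp_unpack(fit$par, shapes), shapes = shapes,
         hidden = hidden, center = center, scale = scale,
         decay = decay, loss = fit$value, convergence = fit$convergence,
         n_features = ncol(X), n = n, seed = seed),
    class = "fog_mlp"
  )
}

#' Predict with a fitted multilayer perceptron
#'
#' @param object A `fog_mlp` model.
#' @param newdata Numeric matrix or `fog_windows` tibble.
#' @param type `"class"` (0/1, ties toward 0) or `"prob"`.
#' @param ... Unused.
#' @export
predict.fog_mlp <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- if (is.matrix(newdata)) newdata else window_matrix(newdata)
  if (ncol(X) != object$n_features) {
    abort(sprintf("Model expects %d features, got %d.",
                  object$n_features, ncol(X)),
          class = "fogcast_invalid_input")
  }
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  p <- mlp_forward(object$layers, Xs)$prob
  if (type == "prob") p else as.integer(p > 0.5)
}

## ---- random forest ---------------------------------------------------------

#' Fit the random-forest member
#'
#' Wraps [ranger::ranger()] at the configuration used for freeze
#' forecasting: maximum tree depth 200 and a class weight of 100 on the
#' freeze class against 1 on the no-freeze class, to counter the strong
#' class imbalance of freeze forecasting problems. Probability trees are
#' grown; predicted labels are 1 when the forest's freeze probability
#' exceeds 0.5 (ties toward 0).
#'
#' @param windows A `fog_windows` tibble with both classes present.
#' @param num_trees Number of trees (default 100).
#' @param max_depth Maximum tree depth (default 200).
#' @param class_weight Weight on the freeze class (the no-freeze class has
#'   weight 1).
#' @param seed Seed passed to ranger.
#' @return An object of class `fog_rf` wrapping the ranger forest.
#' @export
fit_rf <- function(windows, num_trees = 100L, max_depth = 200L,
                   class_weight = 100, seed = 1L) {
  X <- window_matrix(windows)
  y <- factor(windows$label, levels = c(0L, 1L))
  if (length(unique(windows$label)) < 2) {
    abort("Training data contains a single class; cannot fit the forest.",
          class = "fogcast_single_class")
  }
  df <- as.data.frame(X)
  df$.y <- y
  forest <- ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = num_trees, max.depth = max_depth,
    class.weights = c(1, class_weight), probability = TRUE,
    seed = seed, num.threads = 1
  )
  structure(list(forest = forest, n_features = ncol(X),
                 num_trees = num_trees, max_depth = max_depth,
                 class_weight = class_weight, seed = seed, n = nrow(X)),
            class = "fog_rf")
}

#' @rdname fit_rf
#' @param object A `fog_rf` model.
#' @param newdata Numeric matrix or `fog_windows` tibble.
#' @param type `"class"` (0/1, ties toward 0) or `"prob"`.
#' @param ... Unused.
#' @export
predict.fog_rf <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- if (is.matrix(newdata)) newdata else window_matrix(newdata)
  if (ncol(X) != object$n_features) {
    abort(sprintf("Model expects %d features, got %d.",
                  object$n_features, ncol(X)),
          class = "fogcast_invalid_input")
  }
  pr <- stats::predict(object$forest, data = as.data.frame(X),
                       num.threads = 1)$predictions
  p1 <- pr[, "1"]
  if (type == "prob") p1 else as.integer(p1 > 0.5)
}

## ---- ensemble --------------------------------------------------------------

#' Ensemble configuration
#'
#' Collects the member settings for [fit_ensemble()]. Defaults match the
#' forecasting setup: random forest with depth 200 and freeze-class weight
#' 100, and a 5 x 100 hidden-layer perceptron trained with L-BFGS. Tree
#' count, network size and iteration caps are configurable; reduced
#' settings are useful for large parameter sweeps.
#'
#' @param rf_trees,rf_max_depth,rf_class_weight Random-forest settings.
#' @param nn_hidden,nn_decay,nn_maxit Network settings.
#' @param variance_floor Naive-Bayes variance floor (`NULL` = automatic).
#' @param seed Seed shared by the stochastic members.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(rf_trees = 100L, rf_max_depth = 200L,
                            rf_class_weight = 100,
                            nn_hidden = rep(100L, 5), nn_decay = 1e-4,
                            nn_maxit = 500L, variance_floor = NULL,
                            seed = 1L) {
  structure(
    list(rf_trees = as.integer(rf_trees),
         rf_max_depth = as.integer(rf_max_depth),
         rf_class_weight = rf_class_weight,
         nn_hidden = as.integer(nn_hidden), nn_decay = nn_decay,
         nn_maxit = as.integer(nn_maxit), variance_floor = variance_floor,
         seed = as.integer(seed)),
    class = "ensemble_config"
  )
}

#' Fit the three-member forecasting ensemble
#'
#' Trains the Gaussian naive Bayes benchmark, the random forest and the
#' multilayer perceptron on identical rows. Member votes can then be
#' combined by minority or majority rule (see [combine_votes()]).
#'
#' @param windows A `fog_windows` tibble containing both classes.
#' @param config An [ensemble_config()].
#' @param members Which members to train (subset of `"nb"`, `"rf"`,
#'   `"nn"`); vote combination requires all three.
#' @return An object of class `fog_ensemble`.
#' @export
fit_ensemble <- function(windows, config = ensemble_config(),
                         members = c("nb", "rf", "nn")) {
  members <- match.arg(members, c("nb", "rf", "nn"), several.ok = TRUE)
  if (length(unique(windows$label)) < 2) {
    abort("Training data contains a single class; cannot fit the ensemble.",
          class = "fogcast_single_class")
  }
  fits <- list()
  if ("nb" %in% members) {
    fits$nb <- fit_gaussian_nb(windows, variance_floor = config$variance_floor)
  }
  if ("rf" %in% members) {
    fits$rf <- fit_rf(windows, num_trees = config$rf_trees,
                      max_depth = config$rf_max_depth,
                      class_weight = config$rf_class_weight,
                      seed = config$seed)
  }
  if ("nn" %in% members) {
    fits$nn <- fit_mlp(windows, hidden = config$nn_hidden,
                       decay = config$nn_decay, maxit = config$nn_maxit,
                       seed = config$seed)
  }
  structure(list(members = fits, config = config,
                 il = ncol(window_matrix(windows)), n = nrow(windows)),
            class = "fog_ensemble")
}

#' Member votes of an ensemble
#'
#' @param model A `fog_ensemble`.
#' @param newdata Numeric matrix or `fog_windows` tibble.
#' @return A tibble with one 0/1 column per trained member
#'   (`nb`, `rf`, `nn`).
#' @export
ensemble_votes <- function(model, newdata) {
  stopifnot(inherits(model, "fog_ensemble"))
  as_tibble(purrr::map(model$members, ~ predict(.x, newdata)))
}

#' Combine member votes by a vote rule
#'
#' The minority rule fires (predicts freeze) when at least one member
#' votes 1 — maximising sensitivity at the cost of false positives; the
#' majority rule requires at least two of the three members. Single-member
#' rules pass the corresponding member through. For every input the
#' minority prediction dominates the majority prediction, so minority
#' voting can only lower false negatives and raise false positives
#' relative to majority voting.
#'
#' @param votes A tibble/matrix of 0/1 member votes (columns `nb`, `rf`,
#'   `nn`).
#' @param rule One of `"minority"`, `"majority"`, `"nb_only"`,
#'   `"rf_only"`, `"nn_only"`.
#' @return An integer 0/1 vector.
#' @export
#' @examples
#' v <- tibble::tibble(nb = c(0, 1), rf = c(0, 1), nn = c(1, 0))
#' combine_votes(v, "minority")
#' combine_votes(v, "majority")
combine_votes <- function(votes,
                          rule = c("minority", "majority",
                                   "nb_only", "rf_only", "nn_only")) {
  rule <- match.arg(rule)
  V <- as.matrix(as_tibble(votes))
  if (rule %in% c("nb_only", "rf_only", "nn_only")) {
    member <- sub("_only", "", rule)
    if (!member %in% colnames(V)) {
      abort(sprintf("Vote column '%s' not present.", member),
            class = "fogcast_invalid_input")
    }
    return(as.integer(V[, member]))
  }
  if (ncol(V) != 3) {
    abort("Minority/majority voting needs exactly three member columns.",
          class = "fogcast_invalid_input")
  }
  s <- rowSums(V)
  if (rule == "minority") as.integer(s >= 1) else as.integer(s >= 2)
}

#' Predict with the ensemble under a vote rule
#'
#' @param object A `fog_ensemble`.
#' @param newdata Numeric matrix or `fog_windows` tibble.
#' @param rule Vote rule passed to [combine_votes()].
#' @param ... Unused.
#' @return Integer 0/1 labels.
#' @export
predict.fog_ensemble <- function(object, newdata, rule = "minority", ...) {
  combine_votes(ensemble_votes(object, newdata), rule)
}

#' @export
glance.fog_ensemble <- function(x, ...) {
  tibble(n = x$n, il = x$il, members = paste(names(x$members), collapse = "+"),
         rf_trees = x$config$rf_trees,
         rf_class_weight = x$config$rf_class_weight,
         nn_layers = length(x$config$nn_hidden), seed = x$config$seed)
}
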