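#' Confusion counts with freeze as the positive class
#'
#' @param truth,predicted Equal-length 0/1 vectors.
#' @return A one-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have the same length.",
          class = "fogcast_invalid_input")
  }
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  tibble(
    tp = sum(truth == 1L & predicted == 1L),
    fp = sum(truth == 0L & predicted == 1L),
    tn = sum(truth == 0L & predicted == 0L),
    fn = sum(truth == 1L & predicted == 0L)
  )
}

per_class_f1 <- function(truth, predicted, cl) {
  tp <- sum(truth == cl & predicted == cl)
  fp <- sum(truth != cl & predicted == cl)
  fn <- sum(truth == cl & predicted != cl)
  if (tp + fp + fn == 0) return(1) # class absent from truth and prediction
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Macro-averaged F1 score over the freeze and no-freeze classes
#'
#' The per-class F1 scores of classes 0 and 1 are averaged with equal
#' weight. A class absent from both the truth and the prediction
#' contributes F1 = 1 (there was nothing to get wrong); a class present on
#' one side but never correctly predicted contributes 0. The score is
#' therefore always defined, including on single-class inputs.
#'
#' @param truth,predicted Equal-length 0/1 vectors.
#' @return A scalar in `[0, 1]`.
#' @export
#' @examples
#' f1_macro(c(1, 1, 0, 0), c(1, 0, 0, 0)) # 11/15
f1_macro <- function(truth, predicted) {
  if (length(truth) == 0) {
    abort("Cannot score an empty label vector.",
          class = "fogcast_invalid_input")
  }
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have the same length.",
          class = "fogcast_invalid_input")
  }
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  mean(c(per_class_f1(truth, predicted, 0L),
         per_class_f1(truth, predicted, 1L)))
}

#' Leave-one-subject-out evaluation of the forecasting ensemble
#'
#' For each subject, the ensemble is trained on the pooled windows of all
#' other subjects and scored on the held-out subject's windows, so the
#' model has never seen the test subject. Returns one row per (subject,
#' model), where model is each trained member plus each requested vote
#' rule. A held-out subject with no valid windows, or a fold whose
#' training pool collapses to a single class, is recorded with `NA`
#' scores (missing, never zero).
#'
#' @param cohort Cohort tibble with `subject`, `force` and the label
#'   column.
#' @param params A [windowing_params()].
#' @param config An [ensemble_config()].
#' @param label_col Label column used for both training and scoring.
#' @param members Ensemble members to train.
#' @param rules Vote rules to score (only when all three members are
#'   trained).
#' @return A `fog_loso` tibble: `subject`, `model`, `f1`, `tp`, `fp`,
#'   `tn`, `fn`, `n_windows`, `n_train`.
#' @export
loso_evaluate <- function(cohort, params, config = ensemble_config(),
                          label_col = "label",
                          members = c("nb", "rf", "nn"),
                          rules = c("minority", "majority")) {
  windows <- window_cohort(cohort, params, label_col = label_col)
  subjects <- sort(unique(windows$subject))
  if (length(subjects) < 2) {
    abort("Leave-one-subject-out evaluation needs at least two subjects.",
          class = "fogcast_invalid_input")
  }
  vote_rules <- if (length(members) == 3) rules else character()
  model_names <- c(members, vote_rules)

  res <- purrr::map_dfr(subjects, function(s) {
    test <- dplyr::filter(as_tibble(windows), .data$subject == s)
    train <- dplyr::filter(as_tibble(windows), .data$subject != s)
    stopifnot(!any(train$subject == s)) # leakage guard
    miss <- tibble(subject = s, model = model_names, f1 = NA_real_,
                   tp = NA_integer_, fp = NA_integer_, tn = NA_integer_,
                   fn = NA_integer_, n_windows = nrow(test),
                   n_train = nrow(train))
    if (nrow(test) == 0 || length(unique(train$label)) < 2) return(miss)
    train_w <- new_fog_windows(train, params)
    test_w <- new_fog_windows(test, params)
    fit <- fit_ensemble(train_w, config, members = members)
    votes <- ensemble_votes(fit, test_w)
    preds <- as.list(votes)
    for (r in vote_rules) preds[[r]] <- combine_votes(votes, r)
    purrr::map_dfr(model_names, function(m) {
      cc <- confusion_counts(test$label, preds[[m]])
      tibble(subject = s, model = m,
             f1 = f1_macro(test$label, preds[[m]]),
             tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
             n_windows = nrow(test), n_train = nrow(train))
    })
  })
  structure(res, class = c("fog_loso", class(tibble())))
}

#' Sweep input and gap lengths
#'
#' Runs [loso_evaluate()] on the cross of the supplied IL and GL grids.
#' Grid points whose evaluation fails are kept as missing rows rather than
#' aborting the sweep.
#'
#' @inheritParams loso_evaluate
#' @param il_values,gl_values Non-empty integer grids (centiseconds).
#'   Defaults cover the neighbourhood of one and two stepping cycles.
#' @param tl,ol Target length and offset passed to [windowing_params()].
#' @return A `fog_sweep` tibble: the [loso_evaluate()] columns plus `il`
#'   and `gl`.
#' @export
sweep_f1 <- function(cohort, il_values = c(28, 57, 113, 226, 339),
                     gl_values = 0, tl = 1, ol = 28,
                     config = ensemble_config(), label_col = "label",
                     members = c("nb", "rf", "nn"),
                     rules = c("minority", "majority")) {
  if (length(il_values) == 0 || length(gl_values) == 0) {
    abort("IL and GL grids must be non-empty.",
          class = "fogcast_invalid_input")
  }
  grid <- tidyr::expand_grid(il = as.integer(il_values),
                             gl = as.integer(gl_values))
  res <- purrr::pmap_dfr(grid, function(il, gl) {
    params <- windowing_params(il = il, gl = gl, tl = tl, ol = ol)
    cell <- tryCatch(
      loso_evaluate(cohort, params, config, label_col = label_col,
                    members = members, rules = rules),
      error = function(e) {
        warn(sprintf("Grid cell IL=%d GL=%d failed: %s", il, gl,
                     conditionMessage(e)))
        tibble(subject = NA_character_, model = NA_character_,
               f1 = NA_real_, tp = NA_integer_, fp = NA_integer_,
               tn = NA_integer_, fn = NA_integer_,
               n_windows = NA_integer_, n_train = NA_integer_)
      }
    )
    dplyr::mutate(as_tibble(cell), il = il, gl = gl, .before = 1)
  })
  structure(res, class = c("fog_sweep", class(tibble())))
}

#' Summarise a sweep by median and SD across subjects
#'
#' Missing per-subject scores are excluded from the medians, never
#' imputed.
#'
#' @param sweep A `fog_sweep` tibble.
#' @return A tibble with `il`, `gl`, `model`, `median_f1`, `sd_f1`,
#'   `n_subjects`.
#' @export
sweep_summary <- function(sweep) {
  as_tibble(sweep) %>%
    filter(!is.na(.data$model)) %>%
    group_by(.data$il, .data$gl, .data$model) %>%
    summarise(
      median_f1 = median(.data$f1, na.rm = TRUE),
      sd_f1 = sd(.data$f1, na.rm = TRUE),
      n_subjects = sum(!is.na(.data$f1)),
      .groups = "drop"
    )
}

#' @export
tidy.fog_sweep <- function(x, ...) sweep_summary(x)

#' @export
tidy.fog_loso <- function(x, ...) as_tibble(x)

#' @export
glance.fog_loso <- function(x, ...) {
  as_tibble(x) %>%
    group_by(.data$model) %>%
    summarise(median_f1 = median(.data$f1, na.rm = TRUE),
              sd_f1 = sd(.data$f1, na.rm = TRUE),
              n_subjects = sum(!is.na(.data$f1)), .groups = "drop")
}

#' Spearman correlation between gap length and forecast performance
#'
#' Quantifies how performance decays as the forecast horizon grows. Either
#' correlates GL with the median-across-subjects F1 (one point per GL,
#' the headline mode) or with every per-subject score.
#'
#' @param sweep A `fog_sweep` tibble covering at least 3 GL values.
#' @param model Which model's scores to use (member name or vote rule).
#' @param mode `"median"` (default) or `"all"`.
#' @return A one-row tibble: `rho`, `p_value`, `n_points`, `model`,
#'   `mode`. `rho` is `NA` with a warning when the series is constant.
#' @export
gl_correlation <- function(sweep, model = "minority",
                           mode = c("median", "all")) {
  mode <- match.arg(mode)
  d <- as_tibble(sweep) %>%
    filter(.data$model == .env$model, !is.na(.data$f1))
  if (mode == "median") {
    d <- d %>% group_by(.data$gl) %>%
      summarise(f1 = median(.data$f1), .groups = "drop")
  }
  if (length(unique(d$gl)) < 3) {
    abort("Need at least 3 distinct GL values.",
          class = "fogcast_invalid_input")
  }
  if (length(unique(d$f1)) < 2) {
    warn("Constant F1 series; Spearman correlation undefined.")
    return(tibble(rho = NA_real_, p_value = NA_real_, n_points = nrow(d),
                  model = model, mode = mode))
  }
  ct <- suppressWarnings(cor.test(d$gl, d$f1, method = "spearman"))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value,
         n_points = nrow(d), model = model, mode = mode)
}

#' Compare classifiers by Kruskal-Wallis on per-subject F1
#'
#' @param scores A `fog_loso`/`fog_sweep` tibble (or any tibble with
#'   `model` and `f1` columns).
#' @param models Which models to compare (default the three members).
#' @return A one-row tibble: `statistic` (H), `p_value`, `df`, `n`.
#' @export
compare_classifiers <- function(scores, models = c("nb", "rf", "nn")) {
  d <- as_tibble(scores) %>%
    filter(.data$model %in% models, !is.na(.data$f1))
  counts <- dplyr::count(d, .data$model)
  if (nrow(counts) < 2 || any(counts$n < 2)) {
    abort("Need at least two groups with at least two observations each.",
          class = "fogcast_invalid_input")
  }
  kt <- kruskal.test(d$f1, factor(d$model))
  tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
         df = unname(kt$parameter), n = nrow(d))
}

#' Robustness of the random forest to its freeze-class weight
#'
#' Re-runs the leave-one-subject-out evaluation of the random forest for a
#' grid of freeze-class weights at a fixed windowing (default IL = 113,
#' GL = 0) and reports, per subject, the spread of F1 across weights. The
#' headline summary is the median over subjects of the per-subject SD of
#' F1 across weights, next to the median of the per-subject mean F1 — a
#' small ratio indicates the forecasts are robust to the weight choice.
#'
#' @inheritParams loso_evaluate
#' @param weights Freeze-class weights to test (default 1 and 10..100 in
#'   steps of 10).
#' @param il,gl,tl,ol Windowing for every weight.
#' @return A list of class `fog_weight_sweep` with `scores` (tibble:
#'   `weight`, `subject`, `f1`, ...) and `summary` (one row:
#'   `median_sd_f1`, `median_mean_f1`, `n_weights`, `n_subjects`).
#' @export
class_weight_sweep <- function(cohort, weights = c(1, seq(10, 100, by = 10)),
                               il = 113, gl = 0, tl = 1, ol = 28,
                               config = ensemble_config(),
                               label_col = "label") {
  stopifnot(length(weights) >= 1)
  params <- windowing_params(il = il, gl = gl, tl = tl, ol = ol)
  scores <- purrr::map_dfr(weights, function(w) {
    cfg <- config
    cfg$rf_class_weight <- w
    loso_evaluate(cohort, params, cfg, label_col = label_col,
                  members = "rf", rules = character()) %>%
      as_tibble() %>%
      dplyr::mutate(weight = w, .before = 1)
  })
  per_subject <- scores %>%
    filter(!is.na(.data$f1)) %>%
    group_by(.data$subject) %>%
    summarise(sd_f1 = if (dplyr::n() > 1) sd(.data$f1) else 0,
              mean_f1 = mean(.data$f1), .groups = "drop")
  summary <- tibble(
    median_sd_f1 = median(per_subject$sd_f1),
    median_mean_f1 = median(per_subject$mean_f1),
    n_weights = length(weights),
    n_subjects = nrow(per_subject)
  )
  structure(list(scores = scores, per_subject = per_subject,
                 summary = summary),
            class = "fog_weight_sweep")
}

#' @export
glance.fog_weight_sweep <- function(x, ...) x$summary
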