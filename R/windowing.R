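#' Windowing parameters for the forecast-classification transform
#'
#' A labeled force trace is turned into classification samples by sliding a
#' window of total length `WL = IL + GL + TL` along the trace with stride
#' `OL`. The first `IL` samples form the input vector, the next `GL`
#' samples are the forecast horizon (never used as features), and the
#' window's label is read from the final `TL` samples. With the default
#' `TL = 1` the label is the freeze state of the single sample `GL`
#' centiseconds after the input ends, so `GL` controls how early the
#' prediction is made.
#'
#' @param il Input length in centiseconds (>= 1).
#' @param gl Gap length (forecast horizon) in centiseconds (>= 0).
#' @param tl Target length in centiseconds (>= 1, default 1).
#' @param ol Offset between consecutive window starts in centiseconds
#'   (default 28, about a quarter of an average stepping cycle, so that no
#'   stepping cycle is skipped as the window slides).
#' @return A list of class `windowing_params` with fields `il`, `gl`, `tl`,
#'   `ol` and the derived total `wl`.
#' @export
#' @examples
#' windowing_params(il = 113, gl = 0)
windowing_params <- function(il, gl = 0, tl = 1, ol = 28) {
  il <- as.integer(il); gl <- as.integer(gl)
  tl <- as.integer(tl); ol <- as.integer(ol)
  stopifnot(il >= 1, gl >= 0, tl >= 1, ol >= 1)
  structure(list(il = il, gl = gl, tl = tl, ol = ol, wl = il + gl + tl),
            class = "windowing_params")
}

#' @export
print.windowing_params <- function(x, ...) {
  cat(sprintf("Windowing: IL=%d GL=%d TL=%d OL=%d (WL=%d cs)\n",
              x$il, x$gl, x$tl, x$ol, x$wl))
  invisible(x)
}

same_params <- function(a, b) {
  identical(unclass(a)[c("il", "gl", "tl", "ol")],
            unclass(b)[c("il", "gl", "tl", "ol")])
}

feature_names <- function(il) sprintf("f_%03d", seq_len(il))

new_fog_windows <- function(tbl, params) {
  structure(tbl, params = params,
            class = c("fog_windows", class(tibble())))
}

#' Window one labeled trace into classification samples
#'
#' Windows start at 0-based sample indices `0, OL, 2 OL, ...` for as long
#' as the whole window fits the trace; a window starting at `s` has input
#' `force[s, s + IL)` and label 1 iff any label in
#' `[s + IL + GL, s + IL + GL + TL)` equals 1. Trailing partial windows are
#' discarded. A trace shorter than `WL` yields an empty dataset with a
#' warning (trial lengths vary in practice), not an error.
#'
#' @param trace A tibble with a `force` column and the label column named
#'   by `label_col`; optionally a `subject` column (otherwise `subject_id`
#'   is used).
#' @param params A [windowing_params()].
#' @param label_col Name of the 0/1 label column to read targets from.
#' @param subject_id Subject identifier used when the trace carries none.
#' @return A `fog_windows` tibble: `subject`, `start_cs` (0-based window
#'   start), `label` (integer 0/1) and feature columns `f_001 ... f_<IL>`;
#'   the windowing parameters are attached as attribute `"params"`.
#' @export
#' @examples
#' tr <- tibble::tibble(force = sin(2 * pi * (0:999) / 113),
#'                      label = rep(0L, 1000))
#' w <- window_trace(tr, windowing_params(il = 113, gl = 0))
#' nrow(w) # floor((1000 - 114) / 28) + 1 = 32
window_trace <- function(trace, params, label_col = "label",
                         subject_id = "S01") {
  stopifnot(inherits(params, "windowing_params"),
            "force" %in% names(trace), label_col %in% names(trace))
  n <- nrow(trace)
  subj <- if ("subject" %in% names(trace)) trace$subject[1] else subject_id
  empty <- new_fog_windows(
    tibble(subject = character(), start_cs = integer(), label = integer()) %>%
      dplyr::bind_cols(as_tibble(matrix(numeric(), 0, params$il,
                                        dimnames = list(NULL, feature_names(params$il))))),
    params
  )
  if (n < params$wl) {
    warn(sprintf("Trace '%s' (%d samples) is shorter than WL=%d; no windows.",
                 subj, n, params$wl))
    return(empty)
  }
  starts <- seq.int(0L, n - params$wl, by = params$ol)
  force <- trace$force
  lab <- as.integer(trace[[label_col]])
  X <- matrix(force[outer(starts, seq_len(params$il) - 1L, "+") + 1L],
              nrow = length(starts))
  colnames(X) <- feature_names(params$il)
  t0 <- starts + params$il + params$gl
  y <- rep(0L, length(starts))
  for (k in seq_len(params$tl)) {
    y <- pmax(y, lab[t0 + k])
  }
  new_fog_windows(
    dplyr::bind_cols(
      tibble(subject = subj, start_cs = as.integer(starts), label = y),
      as_tibble(X)
    ),
    params
  )
}

#' Window every subject of a cohort
#'
#' Applies [window_trace()] per subject and pools the results.
#'
#' @inheritParams window_trace
#' @param cohort Cohort tibble with `subject`, `force` and the label column.
#' @return A pooled `fog_windows` tibble (see [window_trace()]).
#' @export
window_cohort <- function(cohort, params, label_col = "label") {
  parts <- cohort %>%
    dplyr::group_split(.data$subject) %>%
    purrr::map(~ window_trace(.x, params, label_col = label_col))
  pool_windows(parts)
}

#' Pool windowed datasets
#'
#' Concatenates windowed datasets built with identical parameters,
#' preserving per-row subject provenance.
#'
#' @param datasets A list of `fog_windows` tibbles.
#' @return A single `fog_windows` tibble.
#' @export
pool_windows <- function(datasets) {
  stopifnot(length(datasets) >= 1)
  params <- attr(datasets[[1]], "params")
  ok <- purrr::map_lgl(datasets, ~ same_params(attr(.x, "params"), params))
  if (!all(ok)) {
    abort("All datasets must share identical windowing parameters.",
          class = "fogcast_invalid_input")
  }
  new_fog_windows(bind_rows(lapply(datasets, as_tibble)), params)
}

#' Extract the feature matrix of a windowed dataset
#'
#' @param windows A `fog_windows` tibble.
#' @return A numeric matrix, one row per window, IL columns.
#' @export
window_matrix <- function(windows) {
  as.matrix(dplyr::select(as_tibble(windows), dplyr::starts_with("f_")))
}
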