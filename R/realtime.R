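#' Streaming real-time prediction over a force trace
#'
#' Replays a trace sample-at-a-time through a ring buffer of the model's
#' input length and emits a prediction every `OL` centiseconds, as a cueing
#' device would. No prediction is possible until the first `IL` samples
#' have arrived; the first emission targets sample `IL + GL` (0-based) and
#' subsequent emissions follow every `OL` samples. Each emission sees only
#' samples that precede its forecast horizon, so predictions are causal.
#' The deployment `OL` may differ from the training offset (e.g. 10 cs
#' instead of 28 cs) — only `IL` must match the model.
#'
#' @param trace Tibble with a `force` column; if it has a ground-truth
#'   column named by `label_col`, the label at each emission's target
#'   sample is attached.
#' @param model A [fit_ensemble()] model with all three members.
#' @param stream_params A [windowing_params()]; `il` must equal the
#'   model's input length.
#' @param label_col Optional ground-truth column name.
#' @return A `fog_timeline` tibble: `t_cs` (target sample), `vote_nb`,
#'   `vote_rf`, `vote_nn`, `minority`, `majority`, `gt` (NA when no truth
#'   is available).
#' @export
stream_predict <- function(trace, model, stream_params,
                           label_col = "label") {
  stopifnot(inherits(model, "fog_ensemble"),
            inherits(stream_params, "windowing_params"),
            "force" %in% names(trace))
  il <- stream_params$il; gl <- stream_params$gl
  tl <- stream_params$tl; ol <- stream_params$ol
  if (il != model$il) {
    abort(sprintf("Model input length (%d) differs from stream IL (%d).",
                  model$il, il),
          class = "fogcast_invalid_input")
  }
  n <- nrow(trace)
  if (n < stream_params$wl) {
    abort(sprintf("Trace (%d samples) shorter than WL = %d.", n,
                  stream_params$wl),
          class = "fogcast_invalid_input")
  }
  force <- trace$force
  labels <- if (label_col %in% names(trace)) {
    as.integer(trace[[label_col]])
  } else {
    NULL
  }

  starts <- seq.int(0L, n - stream_params$wl, by = ol)
  buf <- numeric(il)
  snapshots <- matrix(NA_real_, nrow = length(starts), ncol = il)
  next_win <- 1L
  for (i in seq.int(0L, n - 1L)) {        # samples arrive one at a time
    buf[(i %% il) + 1L] <- force[i + 1L]
    if (next_win <= length(starts) && i == starts[next_win] + il - 1L) {
      # unwrap the ring buffer into chronological order
      ord <- ((seq.int(i - il + 1L, i) %% il) + 1L)
      snapshots[next_win, ] <- buf[ord]
      next_win <- next_win + 1L
    }
  }
  colnames(snapshots) <- feature_names(il)

  votes <- ensemble_votes(model, snapshots)
  targets <- starts + il + gl
  gt <- if (is.null(labels)) {
    rep(NA_integer_, length(starts))
  } else {
    purrr::map_int(targets, function(t0) {
      max(labels[seq.int(t0 + 1L, t0 + tl)])
    })
  }
  out <- tibble(
    t_cs = as.integer(targets),
    vote_nb = votes$nb, vote_rf = votes$rf, vote_nn = votes$nn,
    minority = combine_votes(votes, "minority"),
    majority = combine_votes(votes, "majority"),
    gt = gt
  )
  structure(out, params = stream_params,
            class = c("fog_timeline", class(tibble())))
}

#' Error rates of a prediction timeline
#'
#' Scores the combined minority- and majority-vote outputs of a timeline
#' against its ground truth: false-positive rate `FP / (FP + TN)`,
#' false-negative rate `FN / (FN + TP)` and raw counts, one row per vote
#' rule. The member-mean counts `mfp` and `mfn` (FP/FN averaged over the
#' three members' own votes) are reported alongside; they do not depend on
#' the vote rule. Comparing the `fp`/`fn` columns across the two rows
#' shows the sensitivity/specificity trade: minority voting never has more
#' false negatives, and never fewer false positives, than majority voting.
#'
#' @param timeline A `fog_timeline` with non-missing `gt`.
#' @return A tibble with rows `minority` and `majority` and columns
#'   `rule`, `tp`, `fp`, `tn`, `fn`, `fp_rate`, `fn_rate`, `mfp`, `mfn`.
#' @export
timeline_error_rates <- function(timeline) {
  if (!all(c("gt", "minority", "majority") %in% names(timeline)) ||
      anyNA(timeline$gt)) {
    abort("Timeline must carry complete ground truth (`gt`).",
          class = "fogcast_invalid_input")
  }
  gt <- timeline$gt
  member_cols <- c("vote_nb", "vote_rf", "vote_nn")
  mfp <- mean(purrr::map_dbl(member_cols,
                             ~ confusion_counts(gt, timeline[[.x]])$fp))
  mfn <- mean(purrr::map_dbl(member_cols,
                             ~ confusion_counts(gt, timeline[[.x]])$fn))
  purrr::map_dfr(c("minority", "majority"), function(rule) {
    cc <- confusion_counts(gt, timeline[[rule]])
    tibble(
      rule = rule, tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
      fp_rate = if (cc$fp + cc$tn > 0) cc$fp / (cc$fp + cc$tn) else NA_real_,
      fn_rate = if (cc$fn + cc$tp > 0) cc$fn / (cc$fn + cc$tp) else NA_real_,
      mfp = mfp, mfn = mfn
    )
  })
}
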