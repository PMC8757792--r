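#' Plot a force trace with freeze shading
#'
#' Draws the vertical force over time and shades frozen stretches (from
#' the given label column), making episodes and the pre-freeze amplitude
#' decay visible.
#'
#' @param trace A trace tibble (`t_cs`, `force`, label column); for a
#'   cohort the subjects are facetted.
#' @param label_col Label column to shade (default `"label"`; `NULL`
#'   disables shading).
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, label_col = "label") {
  p <- ggplot2::ggplot(trace,
                       ggplot2::aes(x = .data$t_cs / 100, y = .data$force))
  if (!is.null(label_col) && label_col %in% names(trace)) {
    shade <- trace %>%
      group_by(dplyr::across(dplyr::any_of("subject"))) %>%
      dplyr::group_modify(function(d, ...) {
        runs <- episode_runs(d[[label_col]])
        tibble(xmin = d$t_cs[runs$start + 1] / 100,
               xmax = (d$t_cs[runs$start + 1] + runs$length) / 100)
      }) %>%
      ungroup()
    if (nrow(shade) > 0) {
      p <- p + ggplot2::geom_rect(
        data = shade,
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                     ymin = -Inf, ymax = Inf),
        inherit.aes = FALSE, fill = "firebrick", alpha = 0.15
      )
    }
  }
  p <- p + ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "Vertical force")
  if ("subject" %in% names(trace)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$subject))
  }
  p
}

#' @describeIn sweep_f1 Line plot of median F1 against IL or GL, one line
#'   per model (the axis with more than one value is used; with a single
#'   GL the IL axis is plotted).
#' @param object A `fog_sweep` tibble.
#' @param ... Unused.
#' @export
autoplot.fog_sweep <- function(object, ...) {
  s <- sweep_summary(object)
  axis <- if (dplyr::n_distinct(s$gl) > 1) "gl" else "il"
  lab <- if (axis == "gl") "Gap length GL (cs)" else "Input length IL (cs)"
  ggplot2::ggplot(s, ggplot2::aes(x = .data[[axis]], y = .data$median_f1,
                                  colour = .data$model)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$median_f1 - .data$sd_f1),
                   ymax = pmin(1, .data$median_f1 + .data$sd_f1)),
      width = 3, alpha = 0.5
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = lab, y = "Median F1 across subjects",
                  colour = "Model")
}

#' @describeIn stream_predict Timeline plot of the combined predictions
#'   against ground truth, one ribbon row per model output.
#' @param object A `fog_timeline`.
#' @param ... Unused.
#' @export
autoplot.fog_timeline <- function(object, ...) {
  long <- as_tibble(object) %>%
    tidyr::pivot_longer(c("vote_nb", "vote_rf", "vote_nn",
                          "minority", "majority", "gt"),
                        names_to = "series", values_to = "value") %>%
    dplyr::mutate(series = factor(.data$series,
                                  levels = c("gt", "minority", "majority",
                                             "vote_nb", "vote_rf", "vote_nn")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_cs / 100,
                                     y = .data$value)) +
    ggplot2::geom_step(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$series)) +
    ggplot2::scale_y_continuous(breaks = c(0, 1), limits = c(-0.1, 1.1)) +
    ggplot2::labs(x = "Time (s)", y = "Freeze prediction")
}
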