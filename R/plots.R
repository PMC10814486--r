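#' Plot a selection-experiment trajectory
#'
#' Mean FCM per stage with the min-max range as a ribbon — the standard
#' view of a selection trajectory (compare the published stage table).
#'
#' @param object A `selection_experiment` from
#'   [run_selection_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot selection_experiment
#' @export
autoplot.selection_experiment <- function(object, ...) {
  s <- object$summaries
  ggplot2::ggplot(s, ggplot2::aes(x = .data$stage)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$min_fcm, ymax = .data$max_fcm),
      fill = "grey80"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$avg_fcm), linewidth = 1) +
    ggplot2::geom_point(ggplot2::aes(y = .data$avg_fcm)) +
    ggplot2::geom_hline(yintercept = object$config$apoptosis_threshold,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(
      x = "selection stage", y = "FCM (%)",
      title = "Clone FCM under artificial selection",
      subtitle = "line: stage mean; ribbon: min-max; dashed: apoptosis threshold"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a binned FCM distribution
#'
#' @param object An `fcm_distribution` from [fcm_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fcm_distribution
#' @export
autoplot.fcm_distribution <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$bin_left + .data$bin_right) / 2,
                                  y = .data$mass)) +
    ggplot2::geom_col(width = d$bin_right - d$bin_left,
                      fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "FCM (%)", y = "probability mass") +
    ggplot2::theme_minimal()
}

#' Plot per-stage effective mutation rates (and defects, if present)
#'
#' @param object A `chaos_analysis` tibble from [analyze_stage_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot chaos_analysis
#' @export
autoplot.chaos_analysis <- function(object, ...) {
  d <- as_tibble(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$mu_x1e4)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "selection stage",
      y = expression("effective mutation rate (" %*% 10^-4 * ")"),
      title = "Effective mutation rate across selection stages"
    ) +
    ggplot2::theme_minimal()
  p
}
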