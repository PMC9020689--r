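#' Plot a statistic's trajectory across replicates
#'
#' Draws the per-generation mean of one recorded statistic with its 90%
#' prediction ribbon (5th/95th percentiles across replicates), faceted by
#' deme and coloured by the swept parameter where applicable.
#'
#' @param object A `culture_experiment`.
#' @param statistic Column to plot (default `"ne_simple"`).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.culture_experiment <- function(object, statistic = "ne_simple", ...) {
  stopifnot(statistic %in% names(object))
  gc <- group_cols(object)
  sweep <- attr(object, "sweep_param")
  df <- dplyr::summarise(
    dplyr::group_by(object,
                    dplyr::across(dplyr::all_of(c(gc, "generation")))),
    mean = mean(.data[[statistic]], na.rm = TRUE),
    lower = stats::quantile(.data[[statistic]], 0.05, na.rm = TRUE,
                            names = FALSE),
    upper = stats::quantile(.data[[statistic]], 0.95, na.rm = TRUE,
                            names = FALSE),
    .groups = "drop")
  aes <- if (!is.null(sweep) && sweep %in% names(df)) {
    ggplot2::aes(x = .data$generation, y = .data$mean,
                 colour = factor(.data[[sweep]]),
                 fill = factor(.data[[sweep]]))
  } else {
    ggplot2::aes(x = .data$generation, y = .data$mean)
  }
  p <- ggplot2::ggplot(df, aes) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = statistic, colour = sweep,
                  fill = sweep) +
    ggplot2::theme_minimal()
  if ("deme" %in% names(df)) p <- p + ggplot2::facet_wrap(~deme)
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot neutral drift trajectories
#'
#' Frequency of a focal variant over time in independent populations of the
#' same size: the smaller the population, the stronger the fluctuations and
#' the faster fixation or loss.
#'
#' @inheritParams drift_trajectory
#' @return A ggplot object.
#' @examples
#' set.seed(1)
#' plot_drift(n = 100, replicates = 8)
#' @export
plot_drift <- function(n, p0 = 0.5, generations = 100, replicates = 8) {
  df <- drift_trajectory(n, p0, generations, replicates)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$frequency,
                                   colour = factor(.data$replicate))) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "generation", y = "frequency of focal variant",
                  title = sprintf("N = %d", n)) +
    ggplot2::theme_minimal()
}
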