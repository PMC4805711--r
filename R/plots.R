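#' Plot an experiment grid
#'
#' Accuracy against degradation strength, one line per threshold index
#' (darker = smaller threshold) with the unequalized baseline dashed,
#' faceted by descriptor and measure.
#'
#' @param grid A `blur_experiment_grid` from [run_experiment()].
#' @return A ggplot object.
#' @export
plot_experiment_grid <- function(grid) {
  stopifnot(inherits(grid, "data.frame"))
  eq <- dplyr::filter(grid, !is.na(.data$theta_index))
  bl <- dplyr::filter(grid, is.na(.data$theta_index))
  p <- ggplot2::ggplot(eq, ggplot2::aes(x = .data$param, y = .data$accuracy)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$theta_index,
                                    colour = .data$theta_index)) +
    ggplot2::scale_colour_gradient(low = "grey10", high = "grey75",
                                   name = expression(Theta ~ "decile")) +
    ggplot2::facet_grid(descriptor ~ measure) +
    ggplot2::labs(x = "degradation strength", y = "accuracy") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (nrow(bl) > 0) {
    p <- p + ggplot2::geom_line(data = bl, linetype = "dashed")
  }
  p
}

#' @rdname plot_experiment_grid
#' @param object,... Autoplot interface to [plot_experiment_grid()].
#' @importFrom ggplot2 autoplot
#' @method autoplot blur_experiment_grid
#' @export
autoplot.blur_experiment_grid <- function(object, ...) {
  plot_experiment_grid(object)
}

#' Plot blur-prediction error curves
#'
#' @param table Output of [blur_prediction_error()] (rows from several
#'   measures/modes may be bound together).
#' @return A ggplot object; the dotted line marks the 0.5 guessing level.
#' @export
plot_prediction_error <- function(table) {
  stopifnot(inherits(table, "data.frame"))
  ggplot2::ggplot(table, ggplot2::aes(x = .data$base_sigma,
                                      y = .data$error_rate,
                                      colour = .data$measure)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::facet_wrap(~mode) +
    ggplot2::labs(x = expression("base blur" ~ sigma), y = "prediction error") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
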