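#' Pareto chart of uncertainty contributions
#'
#' Bar chart of per-quantity variance shares of the combined uncertainty,
#' in descending order, with the cumulative share overlaid.
#'
#' @param object A `mu_gum` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mu_gum <- function(object, ...) {
  d <- object$contributions |>
    dplyr::mutate(symbol = factor(.data$symbol, levels = .data$symbol))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$symbol)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$share), fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative_share, group = 1),
                       colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative_share),
                        colour = "firebrick") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "Share of combined variance",
                  title = "Uncertainty contributions (Pareto)") +
    ggplot2::theme_minimal()
}

#' Histogram of the Monte Carlo output distribution
#'
#' @param object A numeric vector of Monte Carlo samples (from
#'   [mcs_propagate()]); the summary interval, if supplied, is overlaid.
#' @param summary Optional `mu_mcs` object whose coverage interval and mean
#'   are drawn as vertical lines.
#' @param bins Number of bins (default 80).
#' @return A ggplot object.
#' @export
plot_mcs_distribution <- function(object, summary = NULL, bins = 80) {
  p <- ggplot2::ggplot(tibble::tibble(content = as.numeric(object)),
                       ggplot2::aes(x = .data$content)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::labs(x = "Simulated content (%)", y = "Count",
                  title = "Monte Carlo output distribution") +
    ggplot2::theme_minimal()
  if (!is.null(summary)) {
    p <- p +
      ggplot2::geom_vline(xintercept = summary$mean, colour = "firebrick") +
      ggplot2::geom_vline(xintercept = summary$interval,
                          linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Calibration line with fitted fit
#'
#' @param object A `mu_calibration` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mu_calibration <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$concentration, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$a0, slope = object$a1,
                         colour = "steelblue") +
    ggplot2::labs(x = "Concentration (mg/mL)", y = "Response",
                  title = "Calibration line (OLS)") +
    ggplot2::theme_minimal()
}
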