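## ggplot2 figures for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Cumulative-frequency plot of a risk distribution
#'
#' Empirical cumulative distribution of HI or TCR with the cautionary
#' threshold marked (HI = 1 or TCR = 1e-4 by default).
#'
#' @param dist A `risk_distribution`.
#' @param metric `"HI"` or `"TCR"`.
#' @param threshold Cautionary threshold drawn as a vertical line.
#' @return A ggplot object.
#' @export
plot_cumulative_risk <- function(dist, metric = c("HI", "TCR"),
                                 threshold = NULL) {
  metric <- match.arg(metric)
  threshold <- threshold %||% switch(metric, HI = 1, TCR = 1e-4)
  cf <- cumulative_frequency(dist, metric)
  lab <- paste0(metric, if (!is.na(dist$medium)) paste0(" (", dist$medium, ", ",
    dist$age_group, ")"))
  ggplot2::ggplot(cf, ggplot2::aes(x = .data$value,
      y = .data$cumulative_probability)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed",
      colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = lab, y = "Cumulative probability") +
    ggplot2::theme_minimal()
}

#' @rdname plot_cumulative_risk
#' @param object,... `autoplot` arguments (`object` is the
#'   `risk_distribution`).
#' @export
autoplot.risk_distribution <- function(object, metric = c("HI", "TCR"),
                                       threshold = NULL, ...) {
  plot_cumulative_risk(object, metric, threshold)
}

#' Tornado plot of Spearman sensitivities
#'
#' Horizontal bars of the Spearman correlation between each sampled input
#' and the hazard index, ordered by absolute magnitude.
#'
#' @param sens A `sensitivity_result` from [sensitivity_tornado()].
#' @return A ggplot object.
#' @export
plot_tornado <- function(sens) {
  stopifnot(inherits(sens, "sensitivity_result"))
  d <- tibble::as_tibble(sens)
  d$input <- factor(d$input, levels = rev(d$input))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rho, y = .data$input)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey30") +
    ggplot2::labs(
      x = paste0("Spearman rho vs ", attr(sens, "metric") %||% "HI"),
      y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_tornado
#' @param object,... `autoplot` arguments (`object` is the
#'   `sensitivity_result`).
#' @export
autoplot.sensitivity_result <- function(object, ...) {
  plot_tornado(object)
}
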