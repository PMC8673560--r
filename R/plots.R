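# Figures: the log-log scaling plot and the oxygen depth profiles.

#' Plot an allometric fit
#'
#' Log-log scatter of branch fold-change against area fold-change with the
#' fitted power law; points can be coloured by pressure when a `group`
#' column is supplied.
#'
#' @param fit an `allometric_fit`.
#' @param group optional grouping vector (e.g. pressure) matching the
#'   fitted points.
#' @return a ggplot object.
#' @export
plot_allometry <- function(fit, group = NULL) {
  d <- fit$data
  d$group <- if (is.null(group)) "all" else as.factor(group)
  xr <- range(d$x)
  line <- tibble(x = exp(seq(log(xr[1]), log(xr[2]), length.out = 50)))
  line$y <- fit$prefactor_c * line$x^fit$exponent_a
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2) +
    ggplot2::geom_line(data = line, colour = "black") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "fold-change in basal surface area",
      y = "fold-change in terminal branches",
      colour = NULL,
      subtitle = sprintf("y = %.2f x^%.2f  (R2 = %.2f)",
                         fit$prefactor_c, fit$exponent_a, fit$r_squared)
    ) +
    ggplot2::theme_classic()
}

#' Plot oxygen concentration against depth for a consumption sweep
#'
#' Concentration at depth for each consumption-rate multiplier, with the
#' 1 percent O2 equivalent marked as a dashed line.
#'
#' @param sweep result of [sweep_consumption()].
#' @return a ggplot object.
#' @export
plot_oxygen_sweep <- function(sweep) {
  g <- sweep$grid
  g$multiplier <- as.factor(g$multiplier)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$height_mm,
                                  y = .data$bottom_ml_dL,
                                  colour = .data$multiplier)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = sweep$phi_1pct_ml_dL,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "depth within medium column (mm)",
                  y = "O2 concentration (ml O2/dL)",
                  colour = "r multiplier") +
    ggplot2::theme_classic()
}
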