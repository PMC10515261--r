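#' Plot an exceedance function and optional tail fit
#'
#' Empirical conditional exceedance estimates with pointwise confidence
#' bounds on a log probability axis, overlaid with the fitted parametric
#' tail when given.
#'
#' @param acer A `riskcast_acer` object.
#' @param fit Optional `riskcast_tail_fit`.
#' @return A ggplot object.
#' @export
plot_acer <- function(acer, fit = NULL) {
  df <- tibble::as_tibble(acer) |> dplyr::filter(.data$numer > 0)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(lambda),
                  y = expression(hat(p)[k](lambda))) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    lam <- seq(min(df$lambda), max(df$lambda), length.out = 200)
    fitted <- tibble::tibble(lambda = lam, estimate = tail_prob(fit, lam))
    p <- p + ggplot2::geom_line(data = fitted, colour = "firebrick")
  }
  p
}

#' Plot a second-order difference plot
#'
#' @param sodp A `riskcast_sodp` object.
#' @return A ggplot object.
#' @export
plot_sodp <- function(sodp) {
  ggplot2::ggplot(sodp$points, ggplot2::aes(x = .data$d1, y = .data$d2)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::labs(x = expression(Delta[n]), y = expression(Delta[n + 1])) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
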