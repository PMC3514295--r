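#' Plot a calibration result as an empirical CDF against chi-square
#'
#' The replicate LRT statistics as an empirical cumulative distribution,
#' overlaid with the chi-square 1-df reference curve.
#'
#' @param object A `cm_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cm_calibration <- function(object, ...) {
  ec <- object$ecdf
  grid <- tibble::tibble(
    stat = seq(0, max(c(ec$stat, 1e-6)) * 1.05, length.out = 200)
  )
  grid$chi2_cdf <- stats::pchisq(grid$stat, df = 1)
  ggplot2::ggplot(ec, ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$ecdf), linewidth = 0.6) +
    ggplot2::geom_line(
      data = grid, ggplot2::aes(y = .data$chi2_cdf),
      colour = "red3"
    ) +
    ggplot2::labs(
      x = expression(2 * Delta * lnL),
      y = "cumulative probability",
      title = "Clade-model LRT statistics vs chi-square (1 df)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-site divergent-class posterior probabilities
#'
#' @param sites A tibble from [site_posteriors()].
#' @param threshold Flagging threshold drawn as a horizontal line.
#' @return A ggplot object.
#' @export
plot_site_posteriors <- function(sites, threshold = 0.75) {
  ggplot2::ggplot(sites, ggplot2::aes(
    x = .data$site, y = .data$pp_divergent,
    fill = .data$divergent_flag
  )) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::scale_fill_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "red3"),
      guide = "none"
    ) +
    ggplot2::labs(
      x = "codon site", y = "PP(divergent class)",
      title = "Empirical-Bayes divergent-site posteriors"
    ) +
    ggplot2::theme_minimal()
}
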