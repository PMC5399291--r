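#' Plot the detection-corrected annual abundance series
#'
#' @param object an `nmix_abundance` tibble from [derive_total_abundance()]
#' @param ... unused
#' @return a ggplot: posterior mean abundance per year with the CRI ribbon
#' @export
autoplot.nmix_abundance <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$year, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey80") +
    ggplot2::geom_line(colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "Year", y = "Total abundance (posterior mean, 95% CRI)") +
    ggplot2::theme_minimal()
}

#' Plot indicator posterior means from a variable-selection fit
#'
#' @param object a `bvs_fit`
#' @param ... unused
#' @return a ggplot: one bar per covariate with the importance bands shaded
#' @export
autoplot.bvs_fit <- function(object, ...) {
  df <- object$indicators
  up <- object$config$important
  lo <- object$config$unimportant
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$covariate, .data$posterior_mean),
                                   y = .data$posterior_mean,
                                   fill = .data$classification)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = up, ymax = 1,
                      fill = "darkseagreen", alpha = 0.25) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = 0, ymax = lo,
                      fill = "indianred", alpha = 0.25) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::scale_fill_manual(values = c(important = "darkgreen",
                                          inconclusive = "goldenrod",
                                          unimportant = "firebrick")) +
    ggplot2::coord_flip(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Indicator posterior mean", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the reliance-trend relationship across taxa
#'
#' @param table a trend table (see [shorebird_trends()])
#' @param percent show trends in percent per year
#' @return a ggplot: trend (with CRI bars) against Yellow Sea reliance,
#'   with an OLS line
#' @export
plot_reliance_trend <- function(table, percent = TRUE) {
  tab <- table
  if (percent) {
    tab$trend <- percent_per_year(tab$trend)
    tab$lo <- percent_per_year(tab$lo)
    tab$hi <- percent_per_year(tab$hi)
  }
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$reliance, y = .data$trend)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "grey40",
                         fill = "grey85") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.02, colour = "grey55") +
    ggplot2::geom_point(size = 2.2) +
    ggplot2::labs(x = "Yellow Sea reliance",
                  y = if (percent) "Population trend (% per year)" else "Trend (log scale)") +
    ggplot2::theme_minimal()
}
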