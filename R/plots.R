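#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter plot of a diversity-function regression
#'
#' @param object A `bef_fit` from [bef_regression()].
#' @param ... Unused.
#' @return A ggplot: communities as points, the OLS line, and the fit
#'   statistics in the subtitle.
#' @method autoplot bef_fit
#' @export
autoplot.bef_fit <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$metric, y = .data$response)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "steelblue") +
    ggplot2::labs(
      x = object$metric, y = object$response,
      title = sprintf("%s ~ %s", object$response, object$metric),
      subtitle = sprintf("R2 = %.2f, F(1,%d) = %.2f, p = %.3g",
                         g$r_squared, g$df_residual, g$statistic, g$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' t-ratio bar plot of a main-effects screen
#'
#' Per-species t-ratios with the two-sided significance threshold as dotted
#' lines, the usual way species-identity (selection) effects are displayed.
#'
#' @param object A `bef_screen` from [main_effects_screen()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bef_screen
#' @export
autoplot.bef_screen <- function(object, ...) {
  d <- tidy(object)
  tc <- attr(object, "t_crit")
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$species,
                                                     -abs(.data$t_ratio)),
                                  y = .data$t_ratio)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = c(-tc, tc), linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "t-ratio (estimate / SE)",
                  title = paste("Species main effects on",
                                attr(object, "response"))) +
    ggplot2::theme_minimal()
}

#' Overyielding ratios by richness level
#'
#' @param lrr Tibble from [overyielding_ratios()].
#' @param value_col `"lr_max"` or `"lr_mean"`.
#' @return A ggplot box plot with the zero line (no overyielding) marked.
#' @export
plot_overyielding <- function(lrr, value_col = c("lr_max", "lr_mean")) {
  value_col <- match.arg(value_col)
  d <- lrr[is.finite(lrr[[value_col]]), ]
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$richness),
                                  y = .data[[value_col]])) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~ response) +
    ggplot2::labs(x = "Species richness",
                  y = if (value_col == "lr_max") "LRmax (transgressive)"
                      else "LRmean (non-transgressive)") +
    ggplot2::theme_minimal()
}
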