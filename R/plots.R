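#' Plot extinction estimates with confidence intervals
#'
#' Point estimates of proportional extinction per group with their binomial
#' confidence bars.
#'
#' @param object An `extinction_estimates` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.extinction_estimates <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = stats::reorder(.data$group, -.data$value), y = .data$value)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", v * 100),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Proportional extinction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot per-group size reduction with bootstrap spread
#'
#' Median percent size reduction per group, with error bars of one bootstrap
#' standard deviation.
#'
#' @param object A `size_reduction_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.size_reduction_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = stats::reorder(.data$group, -.data$reduction_pct),
    y = .data$reduction_pct)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$reduction_pct - .data$boot_sd,
      ymax = .data$reduction_pct + .data$boot_sd), width = 0.25) +
    ggplot2::labs(x = NULL, y = "Median size reduction (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Scatter and fitted line for a group-level selectivity regression
#'
#' @param object An `ols_fit`.
#' @param ... Unused.
#' @return A ggplot object showing the points, the fitted line and its 95%
#'   confidence band.
#' @export
autoplot.ols_fit <- function(object, ...) {
  df <- tibble(x = object$x, y = object$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, linetype = "dashed",
                         colour = "black", fill = "grey80") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = object$xlab, y = object$ylab,
                  subtitle = sprintf("R² = %.3f, p = %.3g",
                                     object$r_squared, object$p_slope)) +
    ggplot2::theme_minimal()
}

#' Forest plot of logistic selectivity coefficients
#'
#' Coefficients of the genus-level logistic regression with bars of one
#' standard error on either side, annotated with significance marks
#' (`***` p < 0.001, `**` p < 0.01, `NS` otherwise).
#'
#' @param object A `logistic_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.logistic_fit <- function(object, ...) {
  td <- tidy(object, check_convergence = FALSE) |>
    filter(.data$term != "(Intercept)") |>
    mutate(signif = signif_stars(.data$p.value))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - .data$std.error,
      xmax = .data$estimate + .data$std.error)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$signif), vjust = -1) +
    ggplot2::labs(x = "Regression coefficient (log-odds of extinction)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
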