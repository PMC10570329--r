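# ggplot2 visualizations -----------------------------------------------------------

#' Coefficient plot for a pooled fit
#'
#' Pooled estimates with 95% confidence intervals, one row per model term.
#'
#' @param object an `iron_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.iron_fit <- function(object, ...) {
  d <- tidy.iron_fit(object)
  d <- d[d$term != "(Intercept)", ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate,
                                  y = stats::reorder(.data$term, .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "pooled coefficient (log-outcome scale)", y = NULL,
                  title = sprintf("ln(%s), %s stratum",
                                  object$spec$outcome, object$spec$stratum)) +
    ggplot2::theme_minimal()
}

#' Cross-validation curve and selection path for a stacked lasso
#'
#' @param object an `iron_selection` with `method = "lasso"`.
#' @param ... unused.
#' @return a ggplot of weighted CV mean squared error against log lambda,
#'   annotated with the number of nonzero coefficients.
#' @export
autoplot.iron_selection <- function(object, ...) {
  assert_that(identical(object$method, "lasso"),
              "autoplot is defined for lasso selection results")
  d <- object$path
  p <- ggplot2::ggplot(d, ggplot2::aes(x = log(.data$lambda), y = .data$cv_mse)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "log(lambda)", y = "weighted CV mean squared error") +
    ggplot2::theme_minimal()
  if (!is.na(object$lambda_min)) {
    p <- p + ggplot2::geom_vline(xintercept = log(object$lambda_min),
                                 linetype = "dashed")
  }
  p
}

#' Observed-versus-predicted calibration scatter
#'
#' Diagnostic scatter of observed log outcomes against model predictions on
#' one completed dataset, with the identity line and the calibration slope.
#'
#' @param data a complete cohort table.
#' @param spec an `iron_spec`.
#' @return a ggplot.
#' @export
plot_calibration <- function(data, spec) {
  fit <- fit_ols(data, spec)
  y <- log(data[[spec$outcome]])
  x <- build_design(data, spec$predictors, intercept = TRUE)
  keep <- stats::complete.cases(cbind(y, x))
  pred <- drop(x[keep, , drop = FALSE] %*% coef(fit))
  obs <- y[keep]
  slope <- calibration_slope(obs, pred)
  ggplot2::ggplot(tibble::tibble(predicted = pred, observed = obs),
                  ggplot2::aes(x = .data$predicted, y = .data$observed)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = sprintf("predicted ln(%s)", spec$outcome),
                  y = sprintf("observed ln(%s)", spec$outcome),
                  subtitle = sprintf("calibration slope = %.3f", slope)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
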