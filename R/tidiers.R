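# broom-style tidiers -------------------------------------------------------------

#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a pooled multivariable fit
#'
#' @param x an `iron_fit`.
#' @param ... unused.
#' @return tibble with one row per term: `term`, `estimate`, `std.error`,
#'   `statistic`, `df`, `p.value`, `conf.low`, `conf.high`, plus the Rubin
#'   variance components `W`, `B`, `T`.
#' @export
tidy.iron_fit <- function(x, ...) {
  dplyr::select(x$coefficients, "term", estimate = "qbar", std.error = "se",
                "statistic", "df", "p.value", "conf.low", "conf.high",
                "W", "B", "T")
}

#' @rdname tidy.iron_fit
#' @return `glance()`: one-row tibble with `r.squared` (apparent, averaged
#'   across imputations), `n_used`, `m`, `outcome`, `stratum`.
#' @export
glance.iron_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2_apparent, n_used = x$n_used, m = x$m,
                 outcome = x$spec$outcome, stratum = x$spec$stratum)
}

#' Tidy a variable-selection result
#'
#' For backward elimination, the pooled coefficients of the final model;
#' for the lasso, the original-scale coefficients at the chosen penalty.
#'
#' @param x an `iron_selection`.
#' @param ... unused.
#' @export
tidy.iron_selection <- function(x, ...) {
  if (x$method == "backward") {
    if (is.null(x$final_model)) {
      return(tibble::tibble(term = character(), estimate = numeric()))
    }
    tidy.iron_fit(x$final_model)
  } else {
    x$coefficients
  }
}

#' @rdname tidy.iron_selection
#' @export
glance.iron_selection <- function(x, ...) {
  tibble::tibble(method = x$method,
                 n_selected = length(x$selected),
                 n_candidates = length(x$spec$predictors),
                 lambda_min = if (x$method == "lasso") x$lambda_min else NA_real_,
                 r.squared = if (!is.null(x$final_model)) x$final_model$r2_apparent
                             else NA_real_)
}

#' Tidy a validation report
#'
#' One row per performance statistic, in the layout of the performance block
#' of the model tables.
#'
#' @param x an `iron_validation`.
#' @param ... unused.
#' @export
tidy.iron_validation <- function(x, ...) {
  tibble::tibble(
    statistic = c("r2_apparent", "calibration_slope", "r2_corrected", "optimism_r2"),
    value = c(x$r2_apparent, x$slope_internal, x$r2_corrected, x$optimism_r2)
  )
}

#' @rdname tidy.iron_validation
#' @export
glance.iron_validation <- function(x, ...) {
  tibble::tibble(r2_apparent = x$r2_apparent, optimism_r2 = x$optimism_r2,
                 r2_corrected = x$r2_corrected, slope_internal = x$slope_internal,
                 n = x$n, m = x$m, B = x$B,
                 outcome = x$spec$outcome, stratum = x$spec$stratum)
}
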