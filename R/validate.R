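# Internal validation: apparent performance, bootstrap optimism, calibration ----

#' Proportion of explained variation
#'
#' `1 - SSE/SST`, with SST about the mean of the observed values. For
#' predictions evaluated on data the model was not fit to (the bootstrap
#' test step) the value may be negative; it is returned untruncated, since
#' truncation would bias the optimism average.
#'
#' @param observed,predicted numeric vectors of equal length (>= 2).
#' @return scalar R-squared.
#' @export
r_squared <- function(observed, predicted) {
  assert_that(length(observed) == length(predicted) && length(observed) >= 2,
              "observed and predicted must be equal-length vectors (n >= 2)")
  sst <- sum((observed - mean(observed))^2)
  assert_that(sst > 0, "R-squared undefined: observed values are constant")
  1 - sum((observed - predicted)^2) / sst
}

#' Calibration slope
#'
#' Slope from the regression of observed outcomes on model predictions
#' (with intercept). A slope of 1 indicates a well-calibrated model; below 1,
#' predictions are more extreme than the outcomes (overfitting), and the
#' slope can serve as a uniform shrinkage factor.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return scalar slope.
#' @export
calibration_slope <- function(observed, predicted) {
  assert_that(length(observed) == length(predicted),
              "observed and predicted must have equal length")
  assert_that(sd(predicted) > 0, "calibration slope undefined: constant predictions")
  vp <- sum((predicted - mean(predicted))^2)
  sum((predicted - mean(predicted)) * (observed - mean(observed))) / vp
}

#' Harrell's bootstrap optimism correction on one complete dataset
#'
#' Implements the five-step bootstrap internal-validation procedure:
#' (1) fit the model and compute apparent performance on the observed data;
#' (2) draw a bootstrap sample of n rows with replacement; (3) refit on the
#' bootstrap sample and compute the training-sample performance; (4) apply
#' the bootstrap-sample coefficients to the original data and compute the
#' test performance; (5) repeat B times. Optimism is the mean of
#' (training - test) R-squared; the corrected R-squared is apparent minus
#' optimism; the internally validated calibration slope is the mean of the
#' test-step slopes (the apparent slope of an OLS fit on its own training
#' data is exactly 1 by construction and carries no information).
#'
#' @param data one complete cohort table.
#' @param spec an `iron_spec`.
#' @param B bootstrap replicates.
#' @param seed integer seed.
#' @param max_redraws budget for replacing rank-deficient bootstrap designs.
#' @return an object of class `iron_validation`: apparent and corrected
#'   statistics plus a tibble of per-replicate detail.
#' @export
bootstrap_optimism <- function(data, spec, B = 200, seed = 1L, max_redraws = 25L) {
  assert_that(B >= 1, "B must be >= 1")
  data <- tibble::as_tibble(data)
  fit0 <- fit_ols(data, spec)
  y <- log(data[[spec$outcome]])
  x <- build_design(data, spec$predictors, intercept = TRUE)
  assert_that(!anyNA(cbind(y, x)), "bootstrap_optimism expects complete data")
  pred0 <- drop(x %*% coef(fit0))
  r2_app <- r_squared(y, pred0)
  slope_app <- calibration_slope(y, pred0)
  n <- nrow(data)
  reps <- with_seed(child_seed(seed, 3L), {
    redraws <- 0L
    purrr::map_dfr(seq_len(B), function(b) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        xb <- x[idx, , drop = FALSE]
        yb <- y[idx]
        fit_b <- lm.fit(xb, yb)
        if (fit_b$rank == ncol(xb)) break
        redraws <<- redraws + 1L
        assert_that(redraws <= max_redraws,
                    "too many rank-deficient bootstrap designs")
      }
      beta_b <- fit_b$coefficients
      pred_train <- drop(xb %*% beta_b)
      pred_test <- drop(x %*% beta_b)
      tibble::tibble(
        replicate = b,
        r2_train = r_squared(yb, pred_train),
        r2_test = r_squared(y, pred_test),
        slope_test = calibration_slope(y, pred_test)
      )
    })
  })
  optimism_r2 <- mean(reps$r2_train - reps$r2_test)
  structure(list(
    spec = spec, B = B, seed = seed, n = n, m = 1L,
    r2_apparent = r2_app, slope_apparent = slope_app,
    optimism_r2 = optimism_r2,
    r2_corrected = r2_app - optimism_r2,
    slope_internal = mean(reps$slope_test),
    replicates = reps,
    by_imputation = NULL
  ), class = "iron_validation")
}

#' Bootstrap internal validation across an imputed stack
#'
#' Runs [bootstrap_optimism()] independently on each completed dataset
#' (with derived child seeds) and averages apparent R-squared, optimism,
#' corrected R-squared and calibration slope across imputations.
#'
#' @inheritParams fit_full
#' @param B bootstrap replicates per imputation.
#' @param seed master seed; imputation `j` uses a derived child seed.
#' @return an `iron_validation` whose top-level statistics are
#'   across-imputation means; `by_imputation` holds the per-imputation
#'   reports.
#' @export
validate_mi <- function(stack, spec, B = 200, seed = 1L) {
  stack <- as_mi_stack(stack)
  reports <- lapply(seq_len(stack$m), function(j) {
    bootstrap_optimism(stack$data[[j]], spec, B = B,
                       seed = child_seed(seed, 200L + j))
  })
  stat <- function(name) vapply(reports, `[[`, numeric(1), name)
  structure(list(
    spec = spec, B = B, seed = seed, n = reports[[1]]$n, m = stack$m,
    r2_apparent = mean(stat("r2_apparent")),
    slope_apparent = mean(stat("slope_apparent")),
    optimism_r2 = mean(stat("optimism_r2")),
    r2_corrected = mean(stat("r2_corrected")),
    slope_internal = mean(stat("slope_internal")),
    replicates = NULL,
    by_imputation = tibble::tibble(
      imputation = seq_len(stack$m),
      r2_apparent = stat("r2_apparent"),
      optimism_r2 = stat("optimism_r2"),
      r2_corrected = stat("r2_corrected"),
      slope_internal = stat("slope_internal")
    )
  ), class = "iron_validation")
}

#' @export
print.iron_validation <- function(x, ...) {
  cat(sprintf("<iron_validation> ln(%s), %s stratum: n = %d, m = %d, B = %d\n",
              x$spec$outcome, x$spec$stratum, x$n, x$m, x$B))
  cat(sprintf("  apparent R^2:   %.3f\n", x$r2_apparent))
  cat(sprintf("  optimism:       %.3f\n", x$optimism_r2))
  cat(sprintf("  corrected R^2:  %.3f\n", x$r2_corrected))
  cat(sprintf("  calib. slope:   %.3f\n", x$slope_internal))
  invisible(x)
}

#' Write a validation report as JSON and a summary CSV
#'
#' The CSV mirrors the three-row performance block of the model tables:
#' apparent R-squared, calibration slope, corrected R-squared.
#'
#' @param report an `iron_validation`.
#' @param json_path,csv_path output paths (either may be `NULL` to skip).
#' @param detail include per-replicate detail in the JSON.
#' @return invisibly, the report.
#' @export
write_validation_report <- function(report, json_path = NULL, csv_path = NULL,
                                    detail = FALSE) {
  if (!is.null(json_path)) {
    payload <- list(
      outcome = report$spec$outcome, stratum = report$spec$stratum,
      n = report$n, m = report$m, B = report$B,
      r2_apparent = report$r2_apparent, slope_apparent = report$slope_apparent,
      optimism_r2 = report$optimism_r2, r2_corrected = report$r2_corrected,
      slope_internal = report$slope_internal
    )
    if (detail && !is.null(report$replicates)) payload$replicates <- report$replicates
    if (!is.null(report$by_imputation)) payload$by_imputation <- report$by_imputation
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "columns")
  }
  if (!is.null(csv_path)) {
    utils::write.csv(
      data.frame(statistic = c("Apparent R^2", "Calibration slope", "Corrected R^2"),
                 value = c(report$r2_apparent, report$slope_internal,
                           report$r2_corrected)),
      csv_path, row.names = FALSE)
  }
  invisible(report)
}
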