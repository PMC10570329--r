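# Rubin's rules ----------------------------------------------------------------

#' Pool per-imputation estimates with Rubin's rules
#'
#' Combines `m` per-imputation estimates and standard errors: pooled point
#' estimate is the mean; within-imputation variance `W` is the mean squared
#' SE; between-imputation variance `B` is the sample variance of the
#' estimates (divisor `m - 1`); total variance `T = W + (1 + 1/m) B`. The
#' reference distribution is t with `nu = (m - 1) (1 + W / ((1 + 1/m) B))^2`
#' degrees of freedom, capped at `df_complete` when supplied.
#'
#' @param estimates numeric vector of per-imputation point estimates.
#' @param ses numeric vector of per-imputation standard errors.
#' @param df_complete optional complete-data degrees of freedom cap.
#' @return one-row tibble: `qbar`, `W`, `B`, `T`, `se`, `df`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high`, `m`.
#' @export
pool_rubin <- function(estimates, ses, df_complete = Inf) {
  m <- length(estimates)
  assert_that(m >= 1, "pool_rubin() needs at least one estimate")
  assert_that(length(ses) == m, "estimates and ses must have equal length")
  qbar <- mean(estimates)
  W <- mean(ses^2)
  if (m == 1) {
    # degenerate pooling: single imputation, no between-imputation spread
    se <- ses[1]
    df <- df_complete
    stat <- qbar / se
    p <- 2 * pt(-abs(stat), df)
    ci <- qbar + c(-1, 1) * qt(0.975, df) * se
    return(tibble::tibble(qbar = qbar, W = W, B = NA_real_, T = W, se = se,
                          df = df, statistic = stat, p.value = p,
                          conf.low = ci[1], conf.high = ci[2], m = m))
  }
  B <- var(estimates)
  Tv <- W + (1 + 1 / m) * B
  se <- sqrt(Tv)
  df <- if (B > 0) (m - 1) * (1 + W / ((1 + 1 / m) * B))^2 else Inf
  df <- min(df, df_complete)
  stat <- qbar / se
  p <- 2 * pt(-abs(stat), df)
  ci <- qbar + c(-1, 1) * qt(0.975, df) * se
  tibble::tibble(qbar = qbar, W = W, B = B, T = Tv, se = se, df = df,
                 statistic = stat, p.value = p,
                 conf.low = ci[1], conf.high = ci[2], m = m)
}

#' Pool a performance statistic across imputations
#'
#' Performance statistics (R-squared, calibration slopes, optimism) are
#' combined by arithmetic averaging across imputations; the per-imputation
#' spread is reported alongside.
#'
#' @param values numeric vector, one statistic per imputation.
#' @return one-row tibble: `pooled`, `sd`, `min`, `max`, `m`.
#' @export
pool_performance <- function(values) {
  assert_that(length(values) >= 1, "pool_performance() needs at least one value")
  tibble::tibble(pooled = mean(values),
                 sd = if (length(values) > 1) sd(values) else NA_real_,
                 min = min(values), max = max(values), m = length(values))
}
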