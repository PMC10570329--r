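# Model specification and OLS fitting under multiple imputation -----------------

#' Specify a prediction model
#'
#' @param outcome one of `"ferritin"`, `"serum_iron"`,
#'   `"transferrin_saturation"`; modeled on the natural-log scale.
#' @param stratum `"pre"`, `"post"` or `"combined"`; determines the default
#'   predictor set ([predictor_set()]).
#' @param predictors ordered character vector of model terms; defaults to the
#'   stratum's full questionnaire set.
#' @return an object of class `iron_spec`.
#' @export
model_spec <- function(outcome = c("ferritin", "serum_iron", "transferrin_saturation"),
                       stratum = c("pre", "post", "combined"),
                       predictors = NULL) {
  outcome <- match.arg(outcome)
  stratum <- match.arg(stratum)
  predictors <- predictors %||% predictor_set(stratum)
  if (stratum == "combined") {
    assert_that("menopause" %in% predictors,
                "the combined-stratum model must include the menopause indicator")
  }
  structure(list(outcome = outcome, stratum = stratum, predictors = predictors),
            class = "iron_spec")
}

#' @export
print.iron_spec <- function(x, ...) {
  cat(sprintf("<iron_spec> ln(%s), %s stratum, %d predictor(s)\n",
              x$outcome, x$stratum, length(x$predictors)))
  invisible(x)
}

# Single-dataset OLS of the log outcome on the spec's terms. Returns the lm
# fit plus the design used (for reuse in bootstrap prediction).
fit_ols <- function(data, spec) {
  y <- log(data[[spec$outcome]])
  x <- build_design(data, spec$predictors, intercept = FALSE)
  keep <- stats::complete.cases(cbind(y, x))
  df <- as.data.frame(x[keep, , drop = FALSE])
  names(df) <- spec$predictors
  df$.y <- y[keep]
  fit <- lm(.y ~ ., data = df)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  fit
}

#' Fit the full multivariable model on an imputed stack
#'
#' Per-imputation ordinary least squares of the log outcome on the
#' specification's predictors, with coefficients and confidence intervals
#' pooled by Rubin's rules and apparent R-squared averaged across
#' imputations.
#'
#' @param stack an `iron_mi` imputed stack (use `as_mi_stack()` to wrap a
#'   single complete dataset).
#' @param spec an `iron_spec`.
#' @return an object of class `iron_fit`: list with `spec`, `coefficients`
#'   (pooled tibble, one row per term incl. the intercept), `r2_apparent`,
#'   `r2_by_imputation`, `n_used`, `m`.
#' @export
fit_full <- function(stack, spec) {
  stack <- as_mi_stack(stack)
  terms_all <- c("(Intercept)", spec$predictors)
  fits <- lapply(stack$data, function(d) fit_ols(d, spec))
  est <- vapply(fits, function(f) coef(f)[terms_all], numeric(length(terms_all)))
  ses <- vapply(fits, function(f) sqrt(diag(vcov(f)))[terms_all], numeric(length(terms_all)))
  est <- matrix(est, nrow = length(terms_all))
  ses <- matrix(ses, nrow = length(terms_all))
  n_used <- stats::nobs(fits[[1]])
  df_com <- n_used - length(terms_all)
  pooled <- purrr::map_dfr(seq_along(terms_all), function(i) {
    pool_rubin(est[i, ], ses[i, ], df_complete = df_com)
  })
  pooled <- dplyr::mutate(pooled, term = terms_all, .before = 1)
  r2s <- vapply(fits, function(f) summary(f)$r.squared, numeric(1))
  structure(list(spec = spec, coefficients = pooled,
                 r2_apparent = mean(r2s), r2_by_imputation = r2s,
                 n_used = n_used, m = stack$m),
            class = "iron_fit")
}

#' @export
print.iron_fit <- function(x, ...) {
  cat(sprintf("<iron_fit> ln(%s), %s stratum: n = %d, m = %d, apparent R^2 = %.3f\n",
              x$spec$outcome, x$spec$stratum, x$n_used, x$m, x$r2_apparent))
  print(dplyr::select(x$coefficients, "term", "qbar", "se", "p.value",
                      "conf.low", "conf.high"), n = Inf)
  invisible(x)
}

#' Age-adjusted univariable screen for one predictor
#'
#' Per-imputation OLS of the log outcome on the predictor plus age (age is
#' included in every screening model), with the predictor's slope pooled by
#' Rubin's rules.
#'
#' @inheritParams fit_full
#' @param predictor a single model term (not `"age"`).
#' @param outcome outcome name.
#' @return one-row tibble: the pooled estimate for `predictor`.
#' @export
fit_univariable <- function(stack, predictor, outcome) {
  assert_that(!identical(predictor, "age"),
              "age is the adjustment variable, not a screened predictor")
  stack <- as_mi_stack(stack)
  spec <- structure(list(outcome = outcome, stratum = "custom",
                         predictors = c(predictor, "age")), class = "iron_spec")
  for (d in stack$data) {
    x <- build_design(d, predictor, intercept = FALSE)
    if (sd(x[!is.na(x)]) == 0) abort(paste0("constant predictor column: ", predictor))
  }
  fits <- lapply(stack$data, function(d) fit_ols(d, spec))
  est <- vapply(fits, function(f) coef(f)[[predictor]], numeric(1))
  ses <- vapply(fits, function(f) sqrt(diag(vcov(f)))[[predictor]], numeric(1))
  df_com <- stats::nobs(fits[[1]]) - 3
  out <- pool_rubin(est, ses, df_complete = df_com)
  dplyr::mutate(out, term = predictor, outcome = outcome, .before = 1)
}

#' Run the univariable screen over every predictor of a stratum
#'
#' @inheritParams fit_full
#' @param outcome outcome name.
#' @param stratum stratum whose predictor set is screened.
#' @return tibble, one row per predictor.
#' @export
screen_univariable <- function(stack, outcome, stratum = "pre") {
  preds <- setdiff(predictor_set(stratum), "age")
  purrr::map_dfr(preds, function(p) fit_univariable(stack, p, outcome))
}

#' Backward elimination with pooled p-values
#'
#' Fits the full model in every imputed dataset, pools each coefficient with
#' Rubin's rules, then repeatedly removes the predictor with the largest
#' pooled p-value while that p-value is at or above the threshold. Ties on
#' the largest p-value drop the later predictor in specification order. Age
#' is eligible for removal like any other predictor.
#'
#' @inheritParams fit_full
#' @param p_threshold retention threshold (default 0.05).
#' @return an object of class `iron_selection`: list with `method`,
#'   `selected`, `path` (tibble: step, dropped term, pooled p), and
#'   `final_model` (an `iron_fit`).
#' @export
backward_select <- function(stack, spec, p_threshold = 0.05) {
  stack <- as_mi_stack(stack)
  assert_that(length(spec$predictors) >= 1, "need at least one predictor")
  current <- spec$predictors
  path <- tibble::tibble(step = integer(), dropped = character(), p.value = numeric())
  step <- 0L
  repeat {
    if (length(current) == 0) {
      fit <- NULL
      break
    }
    sp <- structure(list(outcome = spec$outcome, stratum = spec$stratum,
                         predictors = current), class = "iron_spec")
    fit <- fit_full(stack, sp)
    coefs <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
    worst_p <- max(coefs$p.value)
    if (worst_p < p_threshold) break
    # ties: drop the later term in spec order
    worst_terms <- coefs$term[coefs$p.value == worst_p]
    drop_term <- worst_terms[which.max(match(worst_terms, current))]
    step <- step + 1L
    path <- dplyr::bind_rows(path, tibble::tibble(step = step, dropped = drop_term,
                                                  p.value = worst_p))
    current <- setdiff(current, drop_term)
  }
  structure(list(method = "backward", selected = current, path = path,
                 final_model = fit, spec = spec, p_threshold = p_threshold),
            class = "iron_selection")
}

#' @export
print.iron_selection <- function(x, ...) {
  cat(sprintf("<iron_selection> method = %s, %d of %d predictor(s) selected\n",
              x$method, length(x$selected), length(x$spec$predictors)))
  cat("  selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(intercept only)", "\n")
  invisible(x)
}

# Wrap a plain data frame as a single-imputation stack.
#' Treat a complete dataset as a one-imputation stack
#'
#' @param data a complete cohort tibble, or an existing `iron_mi` object
#'   (returned unchanged).
#' @return an `iron_mi` with `m = 1`.
#' @export
as_mi_stack <- function(data) {
  if (inherits(data, "iron_mi")) return(data)
  structure(list(m = 1L, data = list(tibble::as_tibble(data)),
                 log = tibble::tibble(variable = character(), method = character(),
                                      n_missing = integer()),
                 seed = NA_integer_),
            class = "iron_mi")
}
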