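# Sample construction and descriptive statistics -------------------------------

#' Exclude participants missing all three serum markers
#'
#' Removes rows where serum iron, ferritin and UIBC are all missing (rows
#' with at least one observed marker are kept). Row order is preserved; the
#' number of removed rows is attached as attribute `n_excluded` and reported
#' via a message.
#'
#' @param cohort cohort tibble.
#' @param quiet suppress the log message.
#' @return the filtered tibble.
#' @export
exclude_all_missing_outcomes <- function(cohort, quiet = FALSE) {
  all_missing <- is.na(cohort$serum_iron) & is.na(cohort$ferritin) & is.na(cohort$uibc)
  out <- cohort[!all_missing, , drop = FALSE]
  attr(out, "n_excluded") <- sum(all_missing)
  if (!quiet) {
    inform(sprintf("excluded %d participant(s) missing all baseline serum markers; %d retained",
                   sum(all_missing), nrow(out)))
  }
  out
}

#' Transferrin saturation from serum iron and UIBC
#'
#' `100 * iron / (iron + uibc)`: the percentage of iron-binding sites
#' occupied. Returns `NA` where either input is missing, and `NA` with a
#' warning where `iron + uibc == 0` (undefined ratio).
#'
#' @param iron serum iron (mcg/dL), positive.
#' @param uibc unsaturated iron-binding capacity, same units, non-negative.
#' @return transferrin saturation in percent.
#' @export
compute_transferrin_saturation <- function(iron, uibc) {
  tibc <- iron + uibc
  ts <- 100 * iron / tibc
  undefined <- !is.na(tibc) & tibc == 0
  if (any(undefined)) {
    warn(sprintf("%d observation(s) with iron + UIBC = 0; transferrin saturation undefined",
                 sum(undefined)))
    ts[undefined] <- NA_real_
  }
  ts
}

#' Split a cohort by menopause status
#'
#' @param cohort cohort tibble with a `menopause` column (1 = postmenopausal).
#' @param quiet suppress the log message about rows with missing status.
#' @return named list with elements `post`, `pre` (disjoint tibbles) and
#'   `n_missing_menopause`.
#' @export
stratify_by_menopause <- function(cohort, quiet = FALSE) {
  miss <- is.na(cohort$menopause)
  if (!quiet && any(miss)) {
    inform(sprintf("%d row(s) with missing menopause status excluded from both strata",
                   sum(miss)))
  }
  list(post = cohort[!miss & cohort$menopause == 1, , drop = FALSE],
       pre = cohort[!miss & cohort$menopause == 0, , drop = FALSE],
       n_missing_menopause = sum(miss))
}

#' Descriptive summary of a cohort
#'
#' Medians and interquartile ranges (quartiles by linear interpolation,
#' `stats::quantile` type 7) for continuous variables, counts and percentages
#' for binaries, and pairwise-complete Spearman correlations (average ranks
#' for ties) among the three serum outcomes.
#'
#' @param cohort cohort tibble.
#' @return an object of class `iron_describe`: list with tibbles `continuous`
#'   and `categorical`, and matrix `spearman`.
#' @export
describe_cohort <- function(cohort) {
  num_vars <- intersect(
    c("serum_iron", "ferritin", "uibc", "transferrin_saturation", "age", "bmi",
      "alcohol", "exercise", "meat", "dietary_supp_iron", "dietary_supp_calcium",
      "years_pregnant_breastfeeding", "ep_use_years", "reproductive_lifespan",
      "years_since_lmp"),
    names(cohort))
  cont <- purrr::map_dfr(num_vars, function(v) {
    x <- cohort[[v]][!is.na(cohort[[v]])]
    if (length(x) == 0) {
      return(tibble::tibble(variable = v, n = 0L, median = NA_real_,
                            iqr_low = NA_real_, iqr_high = NA_real_,
                            all_missing = TRUE))
    }
    q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
    tibble::tibble(variable = v, n = length(x), median = q[2],
                   iqr_low = q[1], iqr_high = q[3], all_missing = FALSE)
  })
  bin_vars <- intersect(c("menopause", binary_predictors()), names(cohort))
  cat <- purrr::map_dfr(bin_vars, function(v) {
    x <- cohort[[v]][!is.na(cohort[[v]])]
    tibble::tibble(variable = v, n = length(x), n_yes = sum(x == 1),
                   percent_yes = if (length(x)) 100 * mean(x == 1) else NA_real_)
  })
  outs <- intersect(model_outcomes(), names(cohort))
  sp <- matrix(NA_real_, length(outs), length(outs), dimnames = list(outs, outs))
  for (i in seq_along(outs)) for (j in seq_along(outs)) {
    n_pairs <- sum(!is.na(cohort[[outs[i]]]) & !is.na(cohort[[outs[j]]]))
    sp[i, j] <- if (i == j) 1 else if (n_pairs < 2) NA_real_ else
      suppressWarnings(cor(cohort[[outs[i]]], cohort[[outs[j]]],
                           method = "spearman", use = "pairwise.complete.obs"))
  }
  structure(list(continuous = cont, categorical = cat, spearman = sp),
            class = "iron_describe")
}

#' @export
print.iron_describe <- function(x, ...) {
  cat("<iron_describe>\n\nContinuous (median [IQR]):\n")
  print(x$continuous, n = Inf)
  cat("\nCategorical (% yes):\n")
  print(x$categorical, n = Inf)
  cat("\nSpearman correlations (pairwise complete):\n")
  print(round(x$spearman, 3))
  invisible(x)
}

#' Write a descriptive summary as a table-shaped CSV
#'
#' @param desc an `iron_describe` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_describe_csv <- function(desc, path) {
  cont <- dplyr::mutate(desc$continuous,
                        summary = sprintf("%.2f [%.2f, %.2f]", .data$median,
                                          .data$iqr_low, .data$iqr_high),
                        type = "continuous")
  cat <- dplyr::mutate(desc$categorical,
                       summary = sprintf("%d (%.1f)", .data$n_yes, .data$percent_yes),
                       type = "categorical")
  tab <- dplyr::bind_rows(
    dplyr::select(cont, "variable", "type", "n", "summary"),
    dplyr::select(cat, "variable", "type", "n", "summary")
  )
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
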