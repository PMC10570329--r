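# Variable catalog ------------------------------------------------------------
#
# One row per participant; outcome columns hold serum biomarkers, predictor
# columns hold questionnaire-derived quantities. Calcium is *stored* in mg but
# enters every model in decigrams via the derived term `calcium_dg`
# (= dietary_supp_calcium / 100); the transform lives in build_design() so raw
# data keep their native unit.

outcome_vars <- function() c("serum_iron", "ferritin", "uibc", "transferrin_saturation")

model_outcomes <- function() c("ferritin", "serum_iron", "transferrin_saturation")

binary_predictors <- function() {
  c("aspirin", "statin", "blood_donation_12mo", "ida_ever", "polyps_ever",
    "ibd_ever", "pcos_ever", "preeclampsia_ever")
}

continuous_predictors <- function(stratum = c("pre", "post")) {
  stratum <- match.arg(stratum)
  base <- c("age", "bmi", "alcohol", "exercise", "meat", "dietary_supp_iron",
            "dietary_supp_calcium", "years_pregnant_breastfeeding")
  if (stratum == "post") {
    base <- c(base, "ep_use_years", "reproductive_lifespan", "years_since_lmp")
  }
  base
}

#' Predictor sets for each modelling stratum
#'
#' Returns the ordered predictor list used by the multivariable models.
#' Premenopausal models use 16 questionnaire predictors; postmenopausal
#' models add three reproductive-history variables that are only defined
#' after menopause (years of estrogen/progesterone use, reproductive life
#' span, years since last menstrual period); the combined model uses the
#' shared (premenopausal) set plus a menopause indicator.
#'
#' `calcium_dg` is a derived model term (stored calcium in mg divided by 100).
#'
#' @param stratum one of `"pre"`, `"post"`, `"combined"`.
#' @return character vector of model-term names.
#' @export
predictor_set <- function(stratum = c("pre", "post", "combined")) {
  stratum <- match.arg(stratum)
  shared <- c("age", "aspirin", "statin", "blood_donation_12mo", "ida_ever",
              "polyps_ever", "ibd_ever", "pcos_ever", "preeclampsia_ever",
              "alcohol", "bmi", "exercise", "years_pregnant_breastfeeding",
              "calcium_dg", "dietary_supp_iron", "meat")
  switch(stratum,
    pre = shared,
    post = c(shared, "ep_use_years", "reproductive_lifespan", "years_since_lmp"),
    combined = c(shared, "menopause")
  )
}

#' Map model terms to the cohort columns they are computed from
#'
#' Identity for ordinary terms; `calcium_dg` maps to the stored
#' `dietary_supp_calcium` column (mg).
#'
#' @param terms character vector of model-term names.
#' @return named character vector of column names.
#' @export
term_source_cols <- function(terms) {
  vapply(terms, function(tm) {
    if (tm == "calcium_dg") "dietary_supp_calcium" else tm
  }, character(1), USE.NAMES = TRUE)
}

# Design matrix for fitting / generation: applies the mg -> dg calcium
# transform; keeps column order = term order.
build_design <- function(data, terms, intercept = TRUE) {
  cols <- lapply(terms, function(tm) {
    if (tm == "calcium_dg") {
      data[["dietary_supp_calcium"]] / 100
    } else {
      v <- data[[tm]]
      if (is.null(v)) abort(paste0("unknown model term: ", tm))
      as.numeric(v)
    }
  })
  x <- do.call(cbind, cols)
  colnames(x) <- terms
  if (intercept) x <- cbind(`(Intercept)` = 1, x)
  x
}

# Default data-generating coefficients ----------------------------------------
#
# Per-unit effects on the natural-log outcome scale, by stratum. They encode
# the association pattern the generator emulates: recent blood donation and a
# history of iron-deficiency anemia strongly lower all three biomarkers;
# alcohol and red meat raise ferritin; BMI raises ferritin but lowers serum
# iron and transferrin saturation; calcium intake lowers postmenopausal
# ferritin. Intercepts are calibrated separately (see calibrate_generator).

default_betas <- function() {
  list(
    ferritin = list(
      pre = c(age = 0.014, aspirin = 0.098, statin = 0.140,
              blood_donation_12mo = -0.700, ida_ever = -0.347,
              polyps_ever = 0.016, ibd_ever = 0.592, pcos_ever = 0.112,
              preeclampsia_ever = 0.388, alcohol = 0.008, bmi = 0.008,
              exercise = 0.003, years_pregnant_breastfeeding = -0.009,
              calcium_dg = -0.003, dietary_supp_iron = 0.002, meat = 0.016),
      post = c(age = 0.013, aspirin = 0.056, statin = 0.024,
               blood_donation_12mo = -1.121, ida_ever = -0.234,
               polyps_ever = -0.046, ibd_ever = 0.151, pcos_ever = -0.056,
               preeclampsia_ever = 0.107, alcohol = 0.006, bmi = 0.003,
               exercise = 0.000, years_pregnant_breastfeeding = -0.001,
               calcium_dg = -0.014, dietary_supp_iron = 0.001, meat = 0.018,
               ep_use_years = -0.005, reproductive_lifespan = -0.003,
               years_since_lmp = 0.001)
    ),
    serum_iron = list(
      pre = c(age = -0.005, aspirin = 0.018, statin = -0.008,
              blood_donation_12mo = -0.253, ida_ever = -0.175,
              polyps_ever = -0.069, ibd_ever = 0.038, pcos_ever = -0.207,
              preeclampsia_ever = 0.018, alcohol = 0.006, bmi = -0.030,
              exercise = 0.007, years_pregnant_breastfeeding = 0.001,
              calcium_dg = 0.007, dietary_supp_iron = 0.000, meat = 0.004),
      post = c(age = 0.003, aspirin = 0.125, statin = -0.081,
               blood_donation_12mo = -0.167, ida_ever = -0.101,
               polyps_ever = -0.067, ibd_ever = 0.260, pcos_ever = -0.024,
               preeclampsia_ever = -0.015, alcohol = 0.004, bmi = -0.033,
               exercise = 0.004, years_pregnant_breastfeeding = 0.001,
               calcium_dg = 0.003, dietary_supp_iron = -0.002, meat = 0.006,
               ep_use_years = 0.007, reproductive_lifespan = 0.002,
               years_since_lmp = -0.007)
    ),
    transferrin_saturation = list(
      pre = c(age = -0.002, aspirin = 0.019, statin = -0.042,
              blood_donation_12mo = -0.394, ida_ever = -0.214,
              polyps_ever = 0.010, ibd_ever = 0.124, pcos_ever = -0.181,
              preeclampsia_ever = 0.089, alcohol = 0.004, bmi = -0.033,
              exercise = 0.005, years_pregnant_breastfeeding = -0.004,
              calcium_dg = 0.004, dietary_supp_iron = 0.001, meat = 0.003),
      post = c(age = 0.010, aspirin = 0.134, statin = -0.119,
               blood_donation_12mo = -0.406, ida_ever = -0.105,
               polyps_ever = -0.067, ibd_ever = 0.240, pcos_ever = -0.133,
               preeclampsia_ever = -0.003, alcohol = 0.002, bmi = -0.037,
               exercise = 0.003, years_pregnant_breastfeeding = -0.002,
               calcium_dg = -0.004, dietary_supp_iron = -0.001, meat = 0.010,
               ep_use_years = 0.004, reproductive_lifespan = 0.000,
               years_since_lmp = -0.008)
    )
  )
}
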