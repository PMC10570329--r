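# Packaged default configuration ----------------------------------------------
#
# Marginals reproduce the target cohort's descriptive statistics (medians and
# interquartile ranges for continuous variables, stratum prevalences for
# binaries). Quantities the descriptive table does not report (alcohol,
# exercise, red meat spreads; IDA prevalence) use values typical of U.S.
# cohorts of women aged 35-74; the methods vignette discusses each choice.
#
# Intercepts, residual SDs, residual correlations and the missingness scale
# were fixed once by calibrate_generator() (Monte-Carlo search against the
# target medians, stratum R-squared values, outcome Spearman correlations and
# any-missing fractions) and are frozen here so the packaged defaults are
# plain constants.

default_covariates <- function() {
  ln <- function(median, sdlog, cap) list(family = "lognormal",
                                          meanlog = log(median), sdlog = sdlog, cap = cap)
  tn <- function(mean, sd, lower, upper) list(family = "truncnorm",
                                              mean = mean, sd = sd, lower = lower, upper = upper)
  bin <- function(p) list(family = "bernoulli", p = p)
  list(
    age = list(pre = tn(46.7, 5.4, 35, 60), post = tn(59.8, 7.1, 45, 74)),
    bmi = list(pre = tn(25.9, 5.8, 16, 55), post = tn(26.7, 5.9, 16, 55)),
    alcohol = list(pre = ln(4, 1.0, 90), post = ln(4, 1.0, 90)),
    exercise = list(pre = ln(9, 0.55, 60), post = ln(9, 0.55, 60)),
    meat = list(pre = ln(7, 0.6, 40), post = ln(7, 0.6, 40)),
    dietary_supp_iron = list(pre = ln(18.7, 0.699, 150), post = ln(24.6, 0.635, 150)),
    dietary_supp_calcium = list(pre = ln(947.7, 0.669, 6000), post = ln(1472.7, 0.577, 6000)),
    years_pregnant_breastfeeding = list(pre = ln(2.94, 1.3, 25), post = ln(2.56, 1.05, 25)),
    ep_use_years = list(pre = NULL, post = ln(3, 1.0, 30)),
    years_since_lmp = list(pre = NULL, post = ln(9, 0.9, 40)),
    reproductive_lifespan = list(pre = NULL, post = list(family = "derived")),
    menarche_age = list(pre = tn(12.9, 1.3, 9, 17), post = tn(12.9, 1.3, 9, 17)),
    aspirin = list(pre = bin(0.166), post = bin(0.358)),
    statin = list(pre = bin(0.134), post = bin(0.311)),
    blood_donation_12mo = list(pre = bin(0.164), post = bin(0.127)),
    ida_ever = list(pre = bin(0.20), post = bin(0.15)),
    polyps_ever = list(pre = bin(0.079), post = bin(0.232)),
    ibd_ever = list(pre = bin(0.010), post = bin(0.016)),
    pcos_ever = list(pre = bin(0.029), post = bin(0.024)),
    preeclampsia_ever = list(pre = bin(0.074), post = bin(0.052))
  )
}

# Frozen calibration output (see calibrate_generator).
default_intercepts <- function() {
  list(
    ferritin = c(pre = 2.7394, post = 3.8027),
    serum_iron = c(pre = 5.3993, post = 5.1328),
    transferrin_saturation = c(pre = 4.2443, post = 3.8804)
  )
}

default_sigma <- function() {
  list(
    pre = c(ferritin = 0.9048, serum_iron = 0.3385, transferrin_saturation = 0.3786),
    post = c(ferritin = 0.8886, serum_iron = 0.1863, transferrin_saturation = 0.1658)
  )
}

default_rho <- function() {
  c(iron_ts = 0.9414, ferritin_iron = 0.2466, ferritin_ts = 0.3558)
}

# Per-variable missing-at-random rates, scaled so that the fraction of rows
# with at least one missing model variable matches the targets (17%
# premenopausal, 24% postmenopausal).
default_missingness <- function() {
  list(
    pre = c(polyps_ever = 0.04635, alcohol = 0.02607, pcos_ever = 0.01564,
            statin = 0.01796, aspirin = 0.01796, dietary_supp_calcium = 0.01332,
            dietary_supp_iron = 0.01332, years_pregnant_breastfeeding = 0.00348,
            bmi = 0.00058, preeclampsia_ever = 0.00145, ibd_ever = 0.00753,
            blood_donation_12mo = 0.00093, meat = 0.00579, exercise = 0.00579,
            ida_ever = 0.01159),
    post = c(polyps_ever = 0.08262, alcohol = 0.04639, pcos_ever = 0.03178,
             statin = 0.00953, aspirin = 0.01017, dietary_supp_calcium = 0.01462,
             dietary_supp_iron = 0.01462, years_pregnant_breastfeeding = 0.00381,
             bmi = 0.00064, preeclampsia_ever = 0.00159, ibd_ever = 0.00826,
             blood_donation_12mo = 0.00102, meat = 0.00636, exercise = 0.00636,
             ida_ever = 0.01271, ep_use_years = 0.01907,
             reproductive_lifespan = 0.00318, years_since_lmp = 0.00318),
    coef_age = 0.40, coef_bmi = 0.25,
    outcome_rates = c(serum_iron = 0.007, ferritin = 0.006, uibc = 0.049)
  )
}

#' Packaged default generator configuration
#'
#' The shipped default emulates a cohort of 3200 women: 1073 premenopausal,
#' 2125 postmenopausal, and 2 with missing menopause status, of whom 29
#' (allocated across strata by size) lose all three serum markers, so that
#' the exclusion filter leaves 3171 analyzable participants splitting into
#' strata of 2106 and 1063 plus the 2 with unknown menopause status.
#'
#' @param seed master seed stored in the config (stages may override).
#' @return an `iron_generator_config`.
#' @export
default_generator_config <- function(seed = 20230101) {
  generator_config(
    n_pre = 1073, n_post = 2125,
    n_menopause_missing = 2,
    n_all_missing_outcomes = 29,
    seed = seed
  )
}
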