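# Generator configuration -----------------------------------------------------

#' Construct a synthetic-cohort generator configuration
#'
#' A `iron_generator_config` fully parameterizes the synthetic cohort:
#' stratum sizes, per-variable covariate marginals, coefficient maps of the
#' three log-scale outcome models, residual standard deviations and residual
#' correlations, and per-variable missing-at-random rates.
#'
#' @param n_pre,n_post rows generated for the pre-/postmenopausal strata.
#' @param n_menopause_missing extra rows whose menopause indicator is missing
#'   (their covariates and outcomes are still generated from a randomly
#'   assigned latent stratum).
#' @param n_all_missing_outcomes rows whose three serum markers are all set
#'   missing by [impose_missingness()]; must not exceed `n_pre + n_post`.
#' @param covariates named list of per-variable marginal specs, each a list
#'   with entries `pre` and/or `post`, each of those a list with a `family`
#'   (`"truncnorm"`, `"lognormal"`, or `"bernoulli"`) and its parameters.
#' @param betas coefficient maps: `betas[[outcome]][[stratum]]` is a named
#'   numeric vector of per-unit effects on the natural-log outcome scale.
#' @param intercepts `intercepts[[outcome]][[stratum]]`, log-scale intercepts.
#' @param sigma residual SDs on the log scale: `sigma[[stratum]]` is a named
#'   numeric vector over the three outcomes.
#' @param rho residual correlations among the three log-scale outcome errors:
#'   named vector with elements `iron_ts`, `ferritin_iron`, `ferritin_ts`.
#' @param missingness list with per-stratum named rate vectors (`pre`,
#'   `post`), logistic dependence coefficients `coef_age`, `coef_bmi` (on
#'   standardized age/BMI, making the mechanism missing-at-random), and
#'   `outcome_rates` for partially missing serum markers.
#' @param seed default master seed used when a stage is called without one.
#' @return an object of class `iron_generator_config`.
#' @seealso [default_generator_config()], [generate_cohort()],
#'   [impose_missingness()], [calibrate_generator()]
#' @export
generator_config <- function(n_pre, n_post,
                             n_menopause_missing = 0,
                             n_all_missing_outcomes = 0,
                             covariates = default_covariates(),
                             betas = default_betas(),
                             intercepts = default_intercepts(),
                             sigma = default_sigma(),
                             rho = default_rho(),
                             missingness = default_missingness(),
                             seed = 20230101) {
  cfg <- structure(
    list(n_pre = as.integer(n_pre), n_post = as.integer(n_post),
         n_menopause_missing = as.integer(n_menopause_missing),
         n_all_missing_outcomes = as.integer(n_all_missing_outcomes),
         covariates = covariates, betas = betas, intercepts = intercepts,
         sigma = sigma, rho = rho, missingness = missingness,
         seed = as.integer(seed)),
    class = "iron_generator_config"
  )
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  assert_that(cfg$n_pre >= 0 && cfg$n_post >= 0,
              "stratum sizes must be non-negative")
  assert_that(cfg$n_all_missing_outcomes <= cfg$n_pre + cfg$n_post,
              "n_all_missing_outcomes cannot exceed n_pre + n_post")
  for (s in c("pre", "post")) {
    sig <- cfg$sigma[[s]]
    assert_that(all(sig > 0), paste0("residual SDs must be positive (", s, ")"))
  }
  assert_that(all(abs(cfg$rho) < 1), "residual correlations must lie in (-1, 1)")
  ok <- eigen(rho_matrix(cfg$rho), symmetric = TRUE, only.values = TRUE)$values
  assert_that(all(ok > 0), "residual correlation matrix must be positive definite")
  for (out in names(cfg$betas)) {
    for (s in names(cfg$betas[[out]])) {
      keys <- names(cfg$betas[[out]][[s]])
      known <- c(names(cfg$covariates), "calcium_dg", "menopause")
      bad <- setdiff(keys, known)
      assert_that(length(bad) == 0,
                  paste0("unknown coefficient key(s): ", paste(bad, collapse = ", ")))
    }
  }
  for (s in c("pre", "post")) {
    prev <- vapply(cfg$covariates, function(cv) {
      sp <- cv[[s]]
      if (!is.null(sp) && identical(sp$family, "bernoulli")) sp$p else NA_real_
    }, numeric(1))
    prev <- prev[!is.na(prev)]
    assert_that(all(prev >= 0 & prev <= 1), "binary prevalences must lie in [0, 1]")
    rates <- cfg$missingness[[s]]
    assert_that(all(rates >= 0 & rates <= 1), "missingness rates must lie in [0, 1]")
  }
  orate <- cfg$missingness$outcome_rates
  assert_that(all(orate >= 0 & orate <= 1), "outcome missingness rates must lie in [0, 1]")
  invisible(cfg)
}

# Residual correlation matrix in outcome order (ferritin, iron, ts).
rho_matrix <- function(rho) {
  m <- diag(3)
  dimnames(m) <- list(c("ferritin", "serum_iron", "transferrin_saturation"),
                      c("ferritin", "serum_iron", "transferrin_saturation"))
  m["ferritin", "serum_iron"] <- m["serum_iron", "ferritin"] <- rho[["ferritin_iron"]]
  m["ferritin", "transferrin_saturation"] <-
    m["transferrin_saturation", "ferritin"] <- rho[["ferritin_ts"]]
  m["serum_iron", "transferrin_saturation"] <-
    m["transferrin_saturation", "serum_iron"] <- rho[["iron_ts"]]
  m
}

#' @export
print.iron_generator_config <- function(x, ...) {
  cat("<iron_generator_config>\n")
  cat(sprintf("  strata: %d premenopausal, %d postmenopausal (+%d menopause-missing)\n",
              x$n_pre, x$n_post, x$n_menopause_missing))
  cat(sprintf("  all-missing-outcome rows: %d\n", x$n_all_missing_outcomes))
  cat(sprintf("  residual SD (pre):  %s\n",
              paste(sprintf("%s=%.3f", names(x$sigma$pre), x$sigma$pre), collapse = ", ")))
  cat(sprintf("  residual SD (post): %s\n",
              paste(sprintf("%s=%.3f", names(x$sigma$post), x$sigma$post), collapse = ", ")))
  cat(sprintf("  residual correlations: %s\n",
              paste(sprintf("%s=%.3f", names(x$rho), x$rho), collapse = ", ")))
  invisible(x)
}

# YAML round-trip --------------------------------------------------------------

#' Read / write a generator configuration as YAML
#'
#' @param cfg an `iron_generator_config`.
#' @param path file path.
#' @return `write_generator_config()` returns `path` invisibly;
#'   `read_generator_config()` returns the configuration object.
#' @export
write_generator_config <- function(cfg, path) {
  # named numeric vectors must become maps, not sequences, to keep their names
  as_map <- function(x) as.list(x)
  out <- unclass(cfg)
  out$betas <- lapply(out$betas, function(by_str) lapply(by_str, as_map))
  out$intercepts <- lapply(out$intercepts, as_map)
  out$sigma <- lapply(out$sigma, as_map)
  out$rho <- as_map(out$rho)
  out$missingness$pre <- as_map(out$missingness$pre)
  out$missingness$post <- as_map(out$missingness$post)
  out$missingness$outcome_rates <- as_map(out$missingness$outcome_rates)
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # yaml flattens named numeric vectors to lists; restore
  relist_num <- function(x) if (is.list(x)) unlist(x) else x
  for (out in names(raw$betas)) raw$betas[[out]] <- lapply(raw$betas[[out]], relist_num)
  raw$intercepts <- lapply(raw$intercepts, relist_num)
  raw$sigma <- lapply(raw$sigma, relist_num)
  raw$rho <- relist_num(raw$rho)
  raw$missingness$pre <- relist_num(raw$missingness$pre)
  raw$missingness$post <- relist_num(raw$missingness$post)
  raw$missingness$outcome_rates <- relist_num(raw$missingness$outcome_rates)
  generator_config(
    n_pre = raw$n_pre, n_post = raw$n_post,
    n_menopause_missing = raw$n_menopause_missing,
    n_all_missing_outcomes = raw$n_all_missing_outcomes,
    covariates = raw$covariates, betas = raw$betas, intercepts = raw$intercepts,
    sigma = raw$sigma, rho = raw$rho, missingness = raw$missingness,
    seed = raw$seed
  )
}
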