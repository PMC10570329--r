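# Synthetic cohort generation --------------------------------------------------

draw_covariate <- function(n, spec) {
  switch(spec$family,
    truncnorm = rtruncnorm(n, spec$mean, spec$sd, spec$lower, spec$upper),
    lognormal = rlnorm_capped(n, spec$meanlog, spec$sdlog, spec$cap),
    bernoulli = rbinom(n, 1, spec$p),
    abort(paste0("unknown covariate family: ", spec$family))
  )
}

# Draw one stratum's covariate block. Age, years since last menstrual period
# and reproductive life span are linked by construction: the postmenopausal
# reproductive life span is (age - years since LMP) - age at menarche, so the
# three are mutually consistent row by row.
draw_stratum_covariates <- function(n, stratum, covariates) {
  out <- list()
  for (nm in names(covariates)) {
    spec <- covariates[[nm]][[stratum]]
    if (nm == "reproductive_lifespan") next
    if (is.null(spec)) {
      out[[nm]] <- rep(NA_real_, n)
    } else {
      out[[nm]] <- draw_covariate(n, spec)
    }
  }
  if (stratum == "post") {
    # keep age at last period >= 30 by capping years since LMP at age - 30
    out$years_since_lmp <- pmin(out$years_since_lmp, pmax(out$age - 30, 0.5))
    out$reproductive_lifespan <- pmax((out$age - out$years_since_lmp) - out$menarche_age, 10)
  } else {
    out$reproductive_lifespan <- rep(NA_real_, n)
  }
  tb <- tibble::as_tibble(out)
  tb$menarche_age <- NULL
  tb
}

#' True linear predictor of the data-generating model
#'
#' Log-scale linear predictor `intercept + X beta` for one outcome and
#' stratum, using the generating coefficients stored in the configuration.
#' This is the oracle prediction rule: regressing observed log outcomes on
#' it in a fresh sample gives a calibration slope of 1 up to sampling noise.
#'
#' @param data cohort rows of the given stratum.
#' @param config an `iron_generator_config`.
#' @param outcome outcome name.
#' @param stratum `"pre"` or `"post"`.
#' @return numeric vector of log-scale linear predictors.
#' @export
true_linear_predictor <- function(data, config, outcome, stratum) {
  beta <- config$betas[[outcome]][[stratum]]
  x <- build_design(data, names(beta), intercept = FALSE)
  drop(x %*% beta) + config$intercepts[[outcome]][[stratum]]
}

#' Generate a synthetic cohort
#'
#' Draws covariates from the configured per-stratum marginals, then generates
#' the three serum outcomes on the natural-log scale as `X beta + eps` with
#' stratum-specific coefficients and correlated residuals, and derives UIBC
#' from serum iron and transferrin saturation so that the saturation formula
#' `ts = 100 * iron / (iron + uibc)` holds exactly. The returned table has no
#' missing values apart from the structurally absent postmenopause-only
#' variables in premenopausal rows (and the missing menopause indicator for
#' the configured number of unknown-status rows).
#'
#' @param config an [generator_config()] object.
#' @param seed integer seed; defaults to the seed stored in `config`.
#' @return a tibble with one row per participant (class `tbl_df`), columns
#'   as documented in [predictor_set()] plus `participant_id`, `menopause`
#'   and the four serum columns.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_generator_config(config)
  with_seed(child_seed(seed, 1L), {
    n_mm <- config$n_menopause_missing
    # latent stratum for menopause-missing rows, proportional to stratum sizes
    mm_latent <- if (n_mm > 0) {
      sample(c("pre", "post"), n_mm, replace = TRUE,
             prob = c(config$n_pre, config$n_post) / (config$n_pre + config$n_post))
    } else character(0)
    blocks <- list()
    for (s in c("pre", "post")) {
      n_s <- c(pre = config$n_pre, post = config$n_post)[[s]] + sum(mm_latent == s)
      if (n_s == 0) next
      cov <- draw_stratum_covariates(n_s, s, config$covariates)
      cov$menopause <- as.numeric(s == "post")
      cov$.latent_stratum <- s
      blocks[[s]] <- generate_outcomes(cov, config, s)
    }
    cohort <- dplyr::bind_rows(blocks)
    # blank the menopause indicator on the designated rows (one per latent draw)
    if (n_mm > 0) {
      for (s in unique(mm_latent)) {
        k <- sum(mm_latent == s)
        idx <- which(cohort$.latent_stratum == s)
        cohort$menopause[sample(idx, k)] <- NA_real_
      }
    }
    cohort <- cohort[sample(nrow(cohort)), ]
    cohort$.latent_stratum <- NULL
    cohort$participant_id <- seq_len(nrow(cohort))
    dplyr::relocate(cohort, "participant_id", "menopause", "serum_iron",
                    "ferritin", "uibc", "transferrin_saturation")
  })
}

generate_outcomes <- function(cov, config, stratum) {
  n <- nrow(cov)
  outs <- model_outcomes()
  lp <- vapply(outs, function(o) true_linear_predictor(cov, config, o, stratum),
               numeric(n))
  sig <- config$sigma[[stratum]][outs]
  cormat <- rho_matrix(config$rho)[outs, outs]
  sigma_mat <- diag(sig) %*% cormat %*% diag(sig)
  eps <- rmvnorm_chol(n, sigma_mat)
  ln_out <- lp + eps
  # transferrin saturation must stay below 100% for UIBC to be positive;
  # redraw the residual triple for the (rare) offending rows
  guard <- 0
  repeat {
    bad <- which(ln_out[, "transferrin_saturation"] >= log(99.5))
    if (length(bad) == 0) break
    guard <- guard + 1
    assert_that(guard <= 1000, "failed to keep transferrin saturation below 100%")
    eps_new <- rmvnorm_chol(length(bad), sigma_mat)
    ln_out[bad, ] <- lp[bad, , drop = FALSE] + eps_new
  }
  iron <- exp(ln_out[, "serum_iron"])
  ts <- exp(ln_out[, "transferrin_saturation"])
  ferritin <- exp(ln_out[, "ferritin"])
  assert_that(all(iron > 0) && all(ferritin > 0) && all(ts > 0 & ts < 100),
              "generated outcomes out of range")
  uibc <- iron * (100 - ts) / ts
  cov$serum_iron <- iron
  cov$ferritin <- ferritin
  cov$uibc <- uibc
  cov$transferrin_saturation <- 100 * iron / (iron + uibc)
  cov
}

# MAR missingness ---------------------------------------------------------------

# Solve the logistic intercept so the average missingness probability over the
# realized covariates equals the target rate.
solve_logit_intercept <- function(eta_cov, rate) {
  if (rate <= 0) return(-Inf)
  if (rate >= 1) return(Inf)
  f <- function(a) mean(plogis(a + eta_cov)) - rate
  uniroot(f, c(-25, 25), tol = 1e-10)$root
}

#' Impose missing-at-random missingness on a generated cohort
#'
#' Each variable's missingness indicator follows a logistic model on
#' standardized age and BMI (age only, for BMI itself), so missingness
#' depends only on fully observed covariates -- missing at random by
#' construction: the generator never reads the value it deletes. In
#' addition, exactly `n_all_missing_outcomes` rows (allocated across strata
#' by size, largest-remainder rounding) have all three serum markers set
#' missing, emulating participants without usable baseline serum. Transferrin
#' saturation is blanked whenever serum iron or UIBC is missing, because it
#' is derived from them.
#'
#' @inheritParams generate_cohort
#' @param cohort a cohort tibble from [generate_cohort()] (no MAR missingness
#'   yet).
#' @return the cohort with `NA` cells; attribute `n_all_missing` records the
#'   number of rows blanked entirely.
#' @export
impose_missingness <- function(cohort, config, seed = config$seed) {
  rates_by_stratum <- config$missingness[c("pre", "post")]
  for (r in rates_by_stratum) {
    assert_that(all(r >= 0 & r <= 1), "missingness rates must lie in [0, 1]")
  }
  with_seed(child_seed(seed, 2L), {
    out <- cohort
    stratum_of <- ifelse(is.na(out$menopause), NA, ifelse(out$menopause == 1, "post", "pre"))
    # menopause-unknown rows take the premenopausal (shared-variable) rates
    stratum_of[is.na(stratum_of)] <- "pre"
    for (s in c("pre", "post")) {
      idx <- which(stratum_of == s)
      if (length(idx) == 0) next
      rates <- config$missingness[[s]]
      z_age <- as.numeric(scale(out$age[idx]))
      z_bmi <- as.numeric(scale(out$bmi[idx]))
      z_age[is.na(z_age)] <- 0; z_bmi[is.na(z_bmi)] <- 0
      all_rates <- c(rates, config$missingness$outcome_rates)
      miss_ind <- matrix(FALSE, length(idx), length(all_rates),
                         dimnames = list(NULL, names(all_rates)))
      for (v in names(all_rates)) {
        rate <- all_rates[[v]]
        if (rate <= 0) next
        if (is.null(out[[v]])) next
        eta_cov <- if (v == "bmi") config$missingness$coef_age * z_age
                   else config$missingness$coef_age * z_age +
                        config$missingness$coef_bmi * z_bmi
        a <- solve_logit_intercept(eta_cov, rate)
        miss_ind[, v] <- runif(length(idx)) < plogis(a + eta_cov)
      }
      # keep chance all-three-outcome deletions from colliding with the
      # exact all-missing count below: restore ferritin on such rows
      ocols <- intersect(c("serum_iron", "ferritin", "uibc"), colnames(miss_ind))
      if (length(ocols) == 3) {
        collide <- rowSums(miss_ind[, ocols, drop = FALSE]) == 3
        miss_ind[collide, "ferritin"] <- FALSE
      }
      for (v in colnames(miss_ind)) {
        hit <- miss_ind[, v]
        if (any(hit)) out[[v]][idx[hit]] <- NA
      }
    }
    # exact all-missing-outcome rows, allocated across strata by size
    n_amo <- config$n_all_missing_outcomes
    if (n_amo > 0) {
      eligible <- list(pre = which(stratum_of == "pre" & !is.na(out$menopause)),
                       post = which(stratum_of == "post"))
      sizes <- vapply(eligible, length, integer(1))
      quota <- n_amo * sizes / sum(sizes)
      take <- floor(quota)
      rem <- n_amo - sum(take)
      if (rem > 0) {
        order_rem <- order(quota - take, decreasing = TRUE)
        take[order_rem[seq_len(rem)]] <- take[order_rem[seq_len(rem)]] + 1
      }
      for (s in names(eligible)) {
        rows <- sample(eligible[[s]], take[[s]])
        out[rows, c("serum_iron", "ferritin", "uibc", "transferrin_saturation")] <- NA_real_
      }
    }
    out$transferrin_saturation[is.na(out$serum_iron) | is.na(out$uibc)] <- NA_real_
    attr(out, "n_all_missing") <- n_amo
    out
  })
}

# CSV round-trip ----------------------------------------------------------------

#' Write / read a cohort table as CSV with a JSON metadata sidecar
#'
#' Cells are written with empty string = missing (structural and
#' missing-at-random missingness collapse to one missing code on export);
#' the sidecar records column types and the package version.
#'
#' @param cohort cohort tibble.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @return `write_cohort_csv()` returns `path` invisibly; `read_cohort_csv()`
#'   returns the cohort tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  meta <- list(
    columns = lapply(cohort, function(x) class(x)[1]),
    n_rows = nrow(cohort),
    package_version = as.character(utils::packageVersion("ironpredict"))
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}
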