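# Multiple imputation by chained equations --------------------------------------
#
# Continuous variables: Bayesian predictive-mean matching (posterior draw of
# the regression coefficients, match on predicted mean, sample one of k
# nearest observed donors). Binary variables: logistic regression with an
# approximate posterior draw of the coefficients, imputed by a Bernoulli
# draw; perfect separation or a failed fit falls back to donor sampling.
# Serum outcomes are modeled on the log scale (they are log-normal);
# predictive-mean matching still imputes observed raw values. Transferrin
# saturation is never imputed directly: it is recomputed from completed serum
# iron and UIBC so the saturation identity survives imputation.

imputable_variables <- function(data) {
  cand <- intersect(
    c("serum_iron", "ferritin", "uibc", "age", "bmi", "alcohol", "exercise",
      "meat", "dietary_supp_iron", "dietary_supp_calcium",
      "years_pregnant_breastfeeding", "ep_use_years", "reproductive_lifespan",
      "years_since_lmp", binary_predictors()),
    names(data))
  # structurally all-missing columns (wrong stratum) are not imputable
  cand <- cand[vapply(cand, function(v) any(!is.na(data[[v]])), logical(1))]
  cand[vapply(cand, function(v) anyNA(data[[v]]), logical(1))]
}

log_scale_vars <- function() c("serum_iron", "ferritin", "uibc")

# One Bayesian PMM step. x: predictor matrix (complete), y: vector with NA,
# obs/mis: row indices. Returns imputed values for mis.
pmm_impute <- function(x, y, obs, mis, k = 5) {
  xo <- x[obs, , drop = FALSE]
  yo <- y[obs]
  qrx <- qr(xo)
  keep <- qrx$pivot[seq_len(qrx$rank)]
  xo <- xo[, keep, drop = FALSE]
  xm <- x[mis, keep, drop = FALSE]
  fit <- lm.fit(xo, yo)
  beta_hat <- fit$coefficients
  res <- fit$residuals
  df <- max(length(obs) - length(beta_hat), 1)
  s2_hat <- sum(res^2) / df
  s2_star <- sum(res^2) / rchisq(1, df)
  xtx_inv <- chol2inv(chol(crossprod(xo) + diag(1e-10, ncol(xo))))
  beta_star <- beta_hat +
    drop(crossprod(chol(xtx_inv), rnorm(length(beta_hat)))) * sqrt(s2_star)
  yhat_obs <- drop(xo %*% beta_hat)
  yhat_mis <- drop(xm %*% beta_star)
  # k nearest donors by predicted mean, one sampled per missing cell
  ord <- order(yhat_obs)
  yhat_sorted <- yhat_obs[ord]
  pos <- findInterval(yhat_mis, yhat_sorted)
  n_obs <- length(yhat_sorted)
  vapply(seq_along(yhat_mis), function(i) {
    lo <- max(1, pos[i] - k); hi <- min(n_obs, pos[i] + k)
    window <- lo:hi
    d <- abs(yhat_sorted[window] - yhat_mis[i])
    donors <- window[order(d)][seq_len(min(k, length(window)))]
    yo[ord[sample(donors, 1)]]
  }, numeric(1))
}

logistic_impute <- function(x, y, obs, mis) {
  xo <- x[obs, -1, drop = FALSE]  # glm adds its own intercept
  yo <- y[obs]
  imp <- tryCatch({
    dfit <- as.data.frame(xo)
    dfit$.y <- yo
    fit <- suppressWarnings(glm(.y ~ ., data = dfit, family = binomial()))
    if (!fit$converged || any(is.na(coef(fit)))) stop("unstable logistic fit")
    V <- suppressWarnings(vcov(fit))
    if (anyNA(V)) stop("singular information")
    beta_star <- coef(fit) +
      drop(crossprod(chol(V + diag(1e-10, ncol(V))), rnorm(ncol(V))))
    xm <- cbind(1, x[mis, -1, drop = FALSE])
    p <- plogis(drop(xm %*% beta_star))
    rbinom(length(mis), 1, p)
  }, error = function(e) NULL)
  if (is.null(imp)) {
    list(values = sample(yo, length(mis), replace = TRUE), fallback = TRUE)
  } else {
    list(values = imp, fallback = FALSE)
  }
}

#' Multiple imputation by chained equations
#'
#' Produces `m` completed copies of a cohort table. Missing cells are
#' initialized by random draws from each variable's observed values, then
#' the chained-equations sweep cycles through the incomplete variables in
#' order of ascending missingness for `n_iter` iterations; each chain is
#' independent. Serum outcomes participate as predictors in every
#' imputation model and are themselves imputed (on the log scale, by
#' predictive-mean matching). Columns that are entirely missing in `data`
#' (structurally absent variables of the other stratum) are left untouched.
#'
#' @param data cohort tibble (typically one menopause stratum).
#' @param m number of completed datasets.
#' @param n_iter chained-equation sweeps per chain.
#' @param k donors for predictive-mean matching.
#' @param seed integer master seed; chain `j` uses a derived child seed.
#' @return an object of class `iron_mi`: list with `m`, `data` (list of
#'   completed tibbles), `log` (per-variable method and missing count),
#'   `seed`.
#' @export
impute_cohort <- function(data, m = 5, n_iter = 10, k = 5, seed = 1L) {
  assert_that(m >= 1, "m must be >= 1")
  vars <- imputable_variables(data)
  # a core variable with zero observed values cannot be imputed; structurally
  # absent postmenopause-only columns (and derived TS) are exempt
  structural <- c("ep_use_years", "reproductive_lifespan", "years_since_lmp",
                  "transferrin_saturation")
  core <- setdiff(intersect(c(outcome_vars(), binary_predictors(),
                              continuous_predictors("post")), names(data)),
                  structural)
  zero_obs <- core[vapply(core, function(v) all(is.na(data[[v]])), logical(1))]
  if (length(zero_obs)) {
    abort(paste0("variable(s) with zero observed values: ",
                 paste(zero_obs, collapse = ", ")))
  }
  miss_n <- vapply(vars, function(v) sum(is.na(data[[v]])), integer(1))
  vars <- vars[order(miss_n[vars])]  # visit order: ascending missingness
  imp_log <- tibble::tibble(
    variable = vars,
    method = ifelse(vars %in% binary_predictors(), "logistic", "pmm"),
    n_missing = as.integer(miss_n[vars])
  )
  if (length(vars) == 0) {
    return(structure(list(m = m, data = replicate(m, data, simplify = FALSE),
                          log = imp_log, seed = seed), class = "iron_mi"))
  }
  mis_idx <- lapply(vars, function(v) which(is.na(data[[v]])))
  names(mis_idx) <- vars
  completed <- vector("list", m)
  for (chain in seq_len(m)) {
    completed[[chain]] <- with_seed(child_seed(seed, 100L + chain), {
      run_chain(data, vars, mis_idx, n_iter, k)
    })
  }
  # observed-cell preservation invariant
  for (chain in seq_len(m)) {
    for (v in vars) {
      obs <- setdiff(seq_len(nrow(data)), mis_idx[[v]])
      stopifnot(identical(completed[[chain]][[v]][obs], data[[v]][obs]))
    }
  }
  structure(list(m = m, data = completed, log = imp_log, seed = seed),
            class = "iron_mi")
}

run_chain <- function(data, vars, mis_idx, n_iter, k) {
  work <- data
  # initialize by marginal draws from observed values
  for (v in vars) {
    obs_vals <- work[[v]][!is.na(work[[v]])]
    work[[v]][mis_idx[[v]]] <- sample(obs_vals, length(mis_idx[[v]]), replace = TRUE)
  }
  pred_pool <- setdiff(
    intersect(c("menopause", "serum_iron", "ferritin", "uibc", "age", "bmi",
                "alcohol", "exercise", "meat", "dietary_supp_iron",
                "dietary_supp_calcium", "years_pregnant_breastfeeding",
                "ep_use_years", "reproductive_lifespan", "years_since_lmp",
                binary_predictors()),
              names(data)),
    character(0))
  # drop structurally missing / constant columns from the predictor pool
  usable <- vapply(pred_pool, function(v) {
    x <- work[[v]]
    !anyNA(x) || v %in% vars
  }, logical(1))
  pred_pool <- pred_pool[usable]
  for (iter in seq_len(n_iter)) {
    for (v in vars) {
      preds <- setdiff(pred_pool, v)
      xs <- lapply(preds, function(p) {
        x <- as.numeric(work[[p]])
        if (p %in% log_scale_vars()) log(x) else x
      })
      x <- cbind(1, do.call(cbind, xs))
      sds <- apply(x[, -1, drop = FALSE], 2, sd)
      x <- x[, c(TRUE, sds > 0), drop = FALSE]
      mis <- mis_idx[[v]]
      obs <- setdiff(seq_len(nrow(work)), mis)
      if (v %in% binary_predictors()) {
        res <- logistic_impute(x, work[[v]], obs, mis)
        work[[v]][mis] <- res$values
      } else if (v %in% log_scale_vars()) {
        y <- log(as.numeric(work[[v]]))
        imp_log_vals <- pmm_impute(x, y, obs, mis, k)
        work[[v]][mis] <- exp(imp_log_vals)
      } else {
        work[[v]][mis] <- pmm_impute(x, as.numeric(work[[v]]), obs, mis, k)
      }
    }
  }
  # derived outcome: recompute transferrin saturation from completed iron/UIBC
  if (all(c("serum_iron", "uibc", "transferrin_saturation") %in% names(work))) {
    ts_mis <- which(is.na(data$transferrin_saturation))
    if (length(ts_mis)) {
      work$transferrin_saturation[ts_mis] <-
        compute_transferrin_saturation(work$serum_iron[ts_mis], work$uibc[ts_mis])
    }
  }
  work
}

#' @export
print.iron_mi <- function(x, ...) {
  cat(sprintf("<iron_mi> %d imputations of %d rows (seed %d)\n",
              x$m, nrow(x$data[[1]]), x$seed))
  if (nrow(x$log)) print(x$log, n = Inf) else cat("  nothing to impute\n")
  invisible(x)
}

#' Serialize an imputed stack as a directory of CSVs plus a manifest
#'
#' @param stack an `iron_mi` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_imputed_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (j in seq_len(stack$m)) {
    utils::write.csv(stack$data[[j]],
                     file.path(dir, sprintf("imputation_%03d.csv", j)),
                     row.names = FALSE, na = "")
  }
  manifest <- list(m = stack$m, seed = stack$seed,
                   methods = as.list(setNames(stack$log$method, stack$log$variable)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
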