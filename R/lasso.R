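# Stacked lasso across imputations ----------------------------------------------
#
# The m completed datasets are stacked vertically and every row carries weight
# 1/m, so each participant contributes unit total weight to the pooled
# objective
#
#   (1 / (2 W)) * sum_i w_i (y_i - b0 - x_i' beta)^2 + lambda * sum_j |beta_j|
#
# with W = sum_i w_i. Predictors are standardized to weighted mean 0 /
# variance 1 (the intercept is unpenalized and absorbed by centering), the
# solution path is computed by cyclic coordinate descent with warm starts,
# and lambda is chosen by K-fold cross-validation minimizing weighted MSE
# with all m copies of a participant assigned to the same fold.

soft_threshold <- function(z, lambda) sign(z) * pmax(abs(z) - lambda, 0)

# Coordinate descent for one lambda on standardized data. X: n x p with
# weighted mean 0, weighted var 1; y centered; w weights summing to W.
cd_lasso_one <- function(x, y, w, beta, lambda, tol = 1e-10, max_iter = 10000L) {
  W <- sum(w)
  r <- y - drop(x %*% beta)
  p <- length(beta)
  for (iter in seq_len(max_iter)) {
    max_delta <- 0
    for (j in seq_len(p)) {
      bj_old <- beta[j]
      z <- sum(w * x[, j] * r) / W + bj_old
      bj_new <- soft_threshold(z, lambda)
      if (bj_new != bj_old) {
        r <- r - (bj_new - bj_old) * x[, j]
        beta[j] <- bj_new
        max_delta <- max(max_delta, abs(bj_new - bj_old))
      }
    }
    if (max_delta < tol) break
  }
  beta
}

# Standardize, run the path, return coefficients on the original scale.
lasso_path <- function(x, y, w, lambda_grid, tol = 1e-10) {
  W <- sum(w)
  xm <- colSums(w * x) / W
  xc <- sweep(x, 2, xm)
  xsd <- sqrt(colSums(w * xc^2) / W)
  # constant columns can never enter the model: leave them centered at zero
  # with unit scale so their coefficients stay exactly 0 along the path
  const <- xsd == 0
  xsd[const] <- 1
  xs <- sweep(xc, 2, xsd, "/")
  ym <- sum(w * y) / W
  yc <- y - ym
  p <- ncol(x)
  beta <- numeric(p)
  coefs_std <- matrix(0, p, length(lambda_grid),
                      dimnames = list(colnames(x), NULL))
  for (l in seq_along(lambda_grid)) {
    beta <- cd_lasso_one(xs, yc, w, beta, lambda_grid[l], tol = tol)
    coefs_std[, l] <- beta
  }
  coefs <- coefs_std / xsd
  intercepts <- ym - colSums(coefs * xm)
  list(lambda = lambda_grid, beta = coefs, a0 = intercepts,
       beta_std = coefs_std, x_mean = xm, x_sd = xsd, y_mean = ym)
}

lambda_max_weighted <- function(x, y, w) {
  W <- sum(w)
  xm <- colSums(w * x) / W
  xc <- sweep(x, 2, xm)
  xsd <- sqrt(colSums(w * xc^2) / W)
  xs <- sweep(xc, 2, xsd, "/")
  yc <- y - sum(w * y) / W
  max(abs(colSums(w * xs * yc) / W))
}

#' Stacked, weighted lasso for variable selection under multiple imputation
#'
#' @inheritParams fit_full
#' @param lambda optional decreasing penalty grid; by default `n_lambda`
#'   log-spaced values from the smallest penalty that zeroes every
#'   coefficient down to `lambda_min_ratio` times it.
#' @param n_lambda,lambda_min_ratio grid construction parameters.
#' @param K cross-validation folds (participant-grouped).
#' @param seed seed for the fold assignment.
#' @param cv if `FALSE`, skip cross-validation and return the full path only
#'   (with `lambda_min` unset).
#' @return an object of class `iron_selection` with `method = "lasso"`;
#'   `path` holds the lambda grid, CV mean squared errors and nonzero counts;
#'   `coefficients` the original-scale coefficients at the CV-chosen lambda;
#'   `selected` the nonzero terms.
#' @export
stacked_lasso <- function(stack, spec, lambda = NULL, n_lambda = 100,
                          lambda_min_ratio = 1e-3, K = 10, seed = 1L,
                          cv = TRUE) {
  stack <- as_mi_stack(stack)
  stacked <- dplyr::bind_rows(stack$data)
  y <- log(stacked[[spec$outcome]])
  x <- build_design(stacked, spec$predictors, intercept = FALSE)
  keep <- stats::complete.cases(cbind(y, x))
  assert_that(all(keep), "stacked lasso expects completed (imputed) data")
  n_per <- nrow(stack$data[[1]])
  w <- rep(1 / stack$m, nrow(stacked))
  pid <- rep(seq_len(n_per), times = stack$m)

  if (is.null(lambda)) {
    lmax <- lambda_max_weighted(x, y, w)
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
  }
  assert_that(length(lambda) >= 1, "empty lambda grid")
  lambda <- sort(lambda, decreasing = TRUE)

  full_path <- lasso_path(x, y, w, lambda)

  cvm <- rep(NA_real_, length(lambda))
  lambda_min <- NA_real_
  if (cv) {
    folds <- with_seed(child_seed(seed, 7L), {
      sample(rep(seq_len(K), length.out = n_per))
    })[pid]
    sse <- matrix(0, K, length(lambda))
    wsum <- numeric(K)
    for (f in seq_len(K)) {
      tr <- folds != f
      pf <- lasso_path(x[tr, , drop = FALSE], y[tr], w[tr], lambda)
      pred <- sweep(x[!tr, , drop = FALSE] %*% pf$beta, 2, pf$a0, "+")
      sse[f, ] <- colSums(w[!tr] * (y[!tr] - pred)^2)
      wsum[f] <- sum(w[!tr])
    }
    cvm <- colSums(sse) / sum(wsum)
    lambda_min <- lambda[which.min(cvm)]
  }
  use_lambda <- if (cv) lambda_min else min(lambda)
  l_idx <- which(lambda == use_lambda)[1]
  beta_sel <- full_path$beta[, l_idx]
  selected <- names(beta_sel)[beta_sel != 0]
  if (length(selected) == 0) {
    warn("all coefficients zero at the chosen lambda; intercept-only model")
  }
  coefficients <- tibble::tibble(
    term = c("(Intercept)", colnames(x)),
    estimate = c(full_path$a0[l_idx], unname(beta_sel))
  )
  path_tbl <- tibble::tibble(
    lambda = lambda,
    cv_mse = cvm,
    n_nonzero = colSums(full_path$beta != 0)
  )
  structure(list(method = "lasso", selected = selected, path = path_tbl,
                 coefficients = coefficients, lambda_min = lambda_min,
                 full_path = full_path, spec = spec, K = K,
                 final_model = NULL),
            class = "iron_selection")
}
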