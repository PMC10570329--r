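# A stacked fixture with real between-imputation variation: impute a small
# cohort with MAR gaps.
lasso_fixture <- function(m = 3, n = 350, seed = 23) {
  cfg <- small_config(n_pre = n, n_post = 0)
  co <- impose_missingness(generate_cohort(cfg, seed = seed), cfg, seed = seed)
  impute_cohort(co, m = m, n_iter = 3, seed = seed)
}

test_that("the unpenalized limit equals stacked weighted least squares", {
  stk <- lasso_fixture()
  spec <- model_spec("ferritin", "pre")
  res <- stacked_lasso(stk, spec, lambda = c(0.5, 0.1, 0), cv = FALSE)
  est <- setNames(res$coefficients$estimate, res$coefficients$term)
  # independent oracle: weighted OLS on the stacked data
  stacked <- dplyr::bind_rows(stk$data)
  y <- log(stacked$ferritin)
  x <- build_design(stacked, spec$predictors, intercept = FALSE)
  d <- as.data.frame(x); d$.y <- y
  ols <- lm(.y ~ ., data = d, weights = rep(1 / stk$m, nrow(d)))
  expect_equal(unname(est[c("(Intercept)", spec$predictors)]),
               unname(coef(ols)), tolerance = 1e-6)
})

test_that("penalties at or above lambda_max zero every coefficient (KKT)", {
  stk <- lasso_fixture()
  spec <- model_spec("ferritin", "pre")
  stacked <- dplyr::bind_rows(stk$data)
  y <- log(stacked$ferritin)
  x <- build_design(stacked, spec$predictors, intercept = FALSE)
  w <- rep(1 / stk$m, nrow(x))
  lmax <- ironpredict:::lambda_max_weighted(x, y, w)
  res <- suppressWarnings(
    stacked_lasso(stk, spec, lambda = c(lmax * 1.001, lmax), cv = FALSE))
  expect_warning(
    res2 <- stacked_lasso(stk, spec, lambda = c(lmax * 2, lmax * 1.5), cv = FALSE),
    "intercept-only")
  beta <- res$coefficients$estimate[res$coefficients$term != "(Intercept)"]
  expect_true(all(beta == 0))
  # and just below lambda_max at least one coefficient enters
  res3 <- stacked_lasso(stk, spec, lambda = lmax * 0.95, cv = FALSE)
  expect_gt(length(res3$selected), 0)
})

test_that("the coordinate-descent path matches glmnet on identical stacked copies", {
  skip_if_not_installed("glmnet")
  cfg <- small_config(n_pre = 300, n_post = 0)
  co <- generate_cohort(cfg, seed = 24)
  # m identical copies: the 1/m weights are immaterial, so an unweighted
  # single-copy glmnet fit is an exact independent oracle
  stk <- structure(list(m = 3L, data = list(co, co, co),
                        log = tibble::tibble(), seed = 1L), class = "iron_mi")
  spec <- model_spec("ferritin", "pre")
  y <- log(co$ferritin)
  x <- build_design(co, spec$predictors, intercept = FALSE)
  lam <- exp(seq(log(0.3), log(0.003), length.out = 20))
  ours <- stacked_lasso(stk, spec, lambda = lam, cv = FALSE)
  gn <- glmnet::glmnet(x, y, alpha = 1, lambda = lam, standardize = TRUE,
                       thresh = 1e-12)
  ours_beta <- ours$full_path$beta
  gn_beta <- as.matrix(gn$beta)
  expect_equal(unname(ours_beta), unname(gn_beta), tolerance = 1e-4)
  expect_equal(unname(ours$full_path$a0), unname(gn$a0), tolerance = 1e-4)
})

test_that("glmnet also agrees under genuinely unequal imputation weights", {
  skip_if_not_installed("glmnet")
  stk <- lasso_fixture(m = 3)
  spec <- model_spec("ferritin", "pre")
  stacked <- dplyr::bind_rows(stk$data)
  y <- log(stacked$ferritin)
  x <- build_design(stacked, spec$predictors, intercept = FALSE)
  w <- rep(1 / stk$m, nrow(x))
  lam <- exp(seq(log(0.2), log(0.005), length.out = 12))
  ours <- stacked_lasso(stk, spec, lambda = lam, cv = FALSE)
  gn <- glmnet::glmnet(x, y, weights = w, alpha = 1, lambda = lam,
                       standardize = TRUE, thresh = 1e-12)
  expect_equal(unname(ours$full_path$beta), unname(as.matrix(gn$beta)),
               tolerance = 1e-4)
})

test_that("the active set shrinks as the penalty grows", {
  stk <- lasso_fixture()
  res <- stacked_lasso(stk, model_spec("ferritin", "pre"), n_lambda = 40,
                       cv = FALSE)
  nz <- res$path$n_nonzero  # lambda is stored in decreasing order
  expect_true(all(diff(rev(nz)) <= 1e-8 + 0))  # non-increasing in lambda
  expect_equal(nz[1], 0)
  expect_error(stacked_lasso(stk, model_spec("ferritin", "pre"),
                             lambda = numeric(0)), "empty")
})

test_that("cross-validated selection keeps a strong signal and prunes noise", {
  cfg <- donation_only_config(n_pre = 1000, beta_don = -0.8, sigma = 0.4)
  co <- generate_cohort(cfg, seed = 25)
  res <- stacked_lasso(as_mi_stack(co), model_spec("ferritin", "pre"), seed = 9)
  expect_true("blood_donation_12mo" %in% res$selected)
  noise <- setdiff(predictor_set("pre"), "blood_donation_12mo")
  expect_lte(length(intersect(res$selected, noise)), length(noise) * 0.5)
  expect_false(is.na(res$lambda_min))
  # selection is reproducible given the seed
  res2 <- stacked_lasso(as_mi_stack(co), model_spec("ferritin", "pre"), seed = 9)
  expect_identical(res$selected, res2$selected)
})
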