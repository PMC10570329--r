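test_that("Rubin pooling reproduces the closed-form hand example", {
  p <- pool_rubin(c(1, 3), c(1, 1))
  expect_equal(p$qbar, 2)
  expect_equal(p$W, 1)
  expect_equal(p$B, 2)
  expect_equal(p$T, 4)
  expect_equal(p$se, 2)
})

test_that("pooling degenerates sensibly", {
  # identical estimates: no between-imputation variance
  p <- pool_rubin(rep(1.5, 4), rep(0.2, 4))
  expect_equal(p$B, 0)
  expect_equal(p$T, p$W)
  # m = 1: total variance collapses to the single SE, B undefined
  p1 <- pool_rubin(2, 0.5, df_complete = 10)
  expect_equal(p1$T, 0.25)
  expect_true(is.na(p1$B))
  expect_error(pool_rubin(numeric(0), numeric(0)), "at least one")
  # total variance never below within-imputation variance
  set.seed(1)
  for (i in 1:20) {
    est <- rnorm(7); se <- runif(7, 0.1, 2)
    pp <- pool_rubin(est, se)
    expect_gte(pp$T, pp$W)
  }
})

test_that("performance statistics pool by averaging", {
  expect_equal(pool_performance(c(0.10, 0.20))$pooled, 0.15)
  expect_equal(pool_performance(rep(0.42, 5))$pooled, 0.42)
  expect_error(pool_performance(numeric(0)), "at least one")
})

test_that("imputing a complete table returns m identical copies", {
  cfg <- small_config(n_pre = 120, n_post = 0)
  co <- generate_cohort(cfg, seed = 9)
  stk <- impute_cohort(co, m = 3, seed = 1)
  expect_equal(stk$m, 3)
  for (j in 1:3) expect_identical(stk$data[[j]], co)
  expect_equal(nrow(stk$log), 0)
})

test_that("chained equations fill every gap, preserve observed cells, and stay in range", {
  cfg <- small_config(n_pre = 0, n_post = 400)
  co <- impose_missingness(generate_cohort(cfg, seed = 10), cfg, seed = 10)
  stk <- impute_cohort(co, m = 2, n_iter = 5, seed = 2)
  for (j in 1:2) {
    d <- stk$data[[j]]
    for (v in stk$log$variable) {
      obs <- !is.na(co[[v]])
      expect_identical(d[[v]][obs], co[[v]][obs])
      expect_false(anyNA(d[[v]]))
      # predictive-mean matching only ever imputes observed donor values
      if (!v %in% c("serum_iron", "ferritin", "uibc")) {
        expect_true(all(d[[v]][!obs] %in% co[[v]][obs]))
      }
    }
    # the saturation identity survives imputation
    expect_equal(d$transferrin_saturation,
                 compute_transferrin_saturation(d$serum_iron, d$uibc),
                 tolerance = 1e-9)
  }
  # chains are reproducible given the seed, and distinct across chains
  stk2 <- impute_cohort(co, m = 2, n_iter = 5, seed = 2)
  expect_identical(stk$data, stk2$data)
  expect_false(identical(stk$data[[1]], stk$data[[2]]))
})

test_that("a variable with zero observed values is refused by name", {
  cfg <- small_config(n_pre = 0, n_post = 50)
  co <- generate_cohort(cfg, seed = 11)
  co$bmi <- NA_real_
  expect_error(impute_cohort(co, m = 1, seed = 1), "bmi")
})

test_that("pooled MI estimates recover the pre-deletion fit under MAR", {
  cfg <- small_config(n_pre = 1200, n_post = 0)
  full <- generate_cohort(cfg, seed = 12)
  holey <- impose_missingness(full, cfg, seed = 12)
  stk <- impute_cohort(holey, m = 5, n_iter = 5, seed = 3)
  spec <- model_spec("ferritin", "pre")
  fit_mi <- fit_full(stk, spec)
  fit_oracle <- fit_full(as_mi_stack(full), spec)
  mi_est <- setNames(fit_mi$coefficients$qbar, fit_mi$coefficients$term)
  or_est <- setNames(fit_oracle$coefficients$qbar, fit_oracle$coefficients$term)
  or_se <- setNames(fit_oracle$coefficients$se, fit_oracle$coefficients$term)
  for (term in c("blood_donation_12mo", "ida_ever", "alcohol", "bmi")) {
    expect_lt(abs(mi_est[[term]] - or_est[[term]]), 3 * or_se[[term]])
  }
  expect_lt(abs(fit_mi$r2_apparent - fit_oracle$r2_apparent), 0.05)
})

test_that("postmenopause-only variables stay structurally missing in premenopausal data", {
  cfg <- small_config(n_pre = 300, n_post = 0)
  co <- impose_missingness(generate_cohort(cfg, seed = 13), cfg, seed = 13)
  stk <- impute_cohort(co, m = 1, seed = 4)
  expect_true(all(is.na(stk$data[[1]]$ep_use_years)))
  expect_true(all(is.na(stk$data[[1]]$years_since_lmp)))
  expect_false("ep_use_years" %in% stk$log$variable)
})
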