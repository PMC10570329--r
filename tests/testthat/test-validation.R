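test_that("R-squared and calibration slope follow their defining identities", {
  obs <- c(1, 2, 3)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(r_squared(1:3, 1:4), "equal-length")

  pred <- rnorm(50)
  expect_equal(calibration_slope(pred, pred), 1)
  expect_equal(calibration_slope(pred, pred / 2), 2)
  expect_error(calibration_slope(pred, rep(1, 50)), "constant")
})

test_that("an OLS fit is exactly calibrated on its own training data", {
  set.seed(26)
  d <- null_regression_data(120, 6) |> as_log_cohort()
  spec <- null_spec(6)
  fit <- ironpredict:::fit_ols(d, spec)
  x <- build_design(d, spec$predictors, intercept = TRUE)
  pred <- drop(x %*% coef(fit))
  expect_equal(calibration_slope(log(d$y_raw), pred), 1, tolerance = 1e-10)
})

test_that("bootstrap optimism arithmetic and reproducibility hold", {
  set.seed(27)
  d <- null_regression_data(150, 5) |> as_log_cohort()
  spec <- null_spec(5)
  v <- bootstrap_optimism(d, spec, B = 30, seed = 4)
  expect_equal(v$r2_corrected, v$r2_apparent - v$optimism_r2)
  expect_equal(v$optimism_r2, mean(v$replicates$r2_train - v$replicates$r2_test))
  expect_equal(v$slope_internal, mean(v$replicates$slope_test))
  expect_equal(nrow(v$replicates), 30)
  v2 <- bootstrap_optimism(d, spec, B = 30, seed = 4)
  expect_identical(v$replicates, v2$replicates)
  v3 <- bootstrap_optimism(d, spec, B = 30, seed = 5)
  expect_false(identical(v$replicates, v3$replicates))
  expect_error(bootstrap_optimism(d, spec, B = 0, seed = 1), "B must be")
})

test_that("test-step R-squared may go negative and is not truncated", {
  set.seed(28)
  d <- null_regression_data(60, 12) |> as_log_cohort()
  v <- bootstrap_optimism(d, null_spec(12), B = 80, seed = 6)
  expect_true(any(v$replicates$r2_test < 0))
  expect_gt(v$optimism_r2, 0)
})

test_that("optimism grows with model size and shrinks with sample size", {
  set.seed(29)
  opt <- function(n, p) {
    d <- null_regression_data(n, p) |> as_log_cohort()
    mean(replicate(4, {
      dd <- null_regression_data(n, p) |> as_log_cohort()
      bootstrap_optimism(dd, null_spec(p), B = 60,
                         seed = sample.int(1e6, 1))$optimism_r2
    }))
  }
  o_small_n <- opt(100, 8)
  o_big_n <- opt(1200, 8)
  o_small_p <- opt(200, 3)
  o_big_p <- opt(200, 14)
  expect_gt(o_small_n, o_big_n)
  expect_gt(o_big_p, o_small_p)
})

test_that("validate_mi averages per-imputation reports and matches m = 1 directly", {
  cfg <- small_config(n_pre = 250, n_post = 0)
  co <- generate_cohort(cfg, seed = 30)
  spec <- model_spec("ferritin", "pre")
  vm <- validate_mi(as_mi_stack(co), spec, B = 25, seed = 8)
  direct <- bootstrap_optimism(co, spec, B = 25,
                               seed = ironpredict:::child_seed(8, 201L))
  expect_equal(vm$r2_apparent, direct$r2_apparent)
  expect_equal(vm$optimism_r2, direct$optimism_r2)
  expect_equal(vm$slope_internal, direct$slope_internal)
  # multi-imputation report is the mean of its per-imputation rows
  holey <- impose_missingness(co, cfg, seed = 30)
  stk <- impute_cohort(holey, m = 3, n_iter = 3, seed = 5)
  vm3 <- validate_mi(stk, spec, B = 20, seed = 9)
  expect_equal(vm3$r2_corrected, mean(vm3$by_imputation$r2_corrected))
  expect_equal(vm3$slope_internal, mean(vm3$by_imputation$slope_internal))
  expect_equal(nrow(vm3$by_imputation), 3)
})

test_that("validation reports serialize to JSON and a three-row summary CSV", {
  cfg <- small_config(n_pre = 150, n_post = 0)
  co <- generate_cohort(cfg, seed = 31)
  v <- validate_mi(as_mi_stack(co), model_spec("ferritin", "pre"), B = 10, seed = 2)
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_validation_report(v, json_path = jp, csv_path = cp)
  back <- jsonlite::read_json(jp)
  expect_equal(back$r2_apparent, v$r2_apparent, tolerance = 1e-9)
  csv <- utils::read.csv(cp)
  expect_equal(nrow(csv), 3)
  expect_equal(csv$value[csv$statistic == "Apparent R^2"], v$r2_apparent,
               tolerance = 1e-9)
})
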