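test_that("generation is deterministic given config and seed, and seeds differ", {
  cfg <- small_config()
  a <- generate_cohort(cfg, seed = 5)
  b <- generate_cohort(cfg, seed = 5)
  c <- generate_cohort(cfg, seed = 6)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$ferritin, c$ferritin)))
})

test_that("generated cohort has the configured shape and no premature missingness", {
  cfg <- small_config(n_pre = 150, n_post = 250, n_mm = 2)
  co <- generate_cohort(cfg, seed = 1)
  expect_equal(nrow(co), 402)
  expect_equal(sum(is.na(co$menopause)), 2)
  expect_equal(sum(co$menopause == 0, na.rm = TRUE), 150)
  expect_equal(sum(co$menopause == 1, na.rm = TRUE), 250)
  # only structural missingness: postmenopause-only columns in non-post rows
  post_only <- c("ep_use_years", "years_since_lmp", "reproductive_lifespan")
  shared <- setdiff(names(co), c(post_only, "menopause"))
  expect_false(anyNA(co[, shared]))
  is_post <- co$menopause %in% 1
  for (v in post_only) {
    expect_false(anyNA(co[[v]][is_post]))
    expect_true(all(is.na(co[[v]][co$menopause %in% 0])))
  }
})

test_that("outcomes are positive and the saturation identity holds exactly", {
  co <- generate_cohort(small_config(), seed = 3)
  expect_true(all(co$serum_iron > 0))
  expect_true(all(co$ferritin > 0))
  expect_true(all(co$uibc > 0))
  expect_true(all(co$transferrin_saturation > 0 & co$transferrin_saturation < 100))
  ts_re <- compute_transferrin_saturation(co$serum_iron, co$uibc)
  expect_equal(ts_re, co$transferrin_saturation, tolerance = 1e-12)
  # implied total iron-binding capacity is conserved
  tibc <- co$serum_iron + co$uibc
  expect_equal(100 * co$serum_iron / tibc, co$transferrin_saturation,
               tolerance = 1e-12)
})

test_that("zero effects and vanishing noise collapse outcomes to the intercept", {
  cfg <- noiseless_config(n_pre = 300)
  for (o in names(cfg$betas)) for (s in c("pre", "post")) cfg$betas[[o]][[s]][] <- 0
  co <- generate_cohort(cfg, seed = 2)
  expect_equal(log(co$ferritin),
               rep(cfg$intercepts$ferritin[["pre"]], 300), tolerance = 1e-6)
  fit <- fit_full(as_mi_stack(co), model_spec("serum_iron", "pre"))
  expect_lt(fit$r2_apparent, 0.1)  # pure noise-free constant: nothing to explain
})

test_that("noiseless generation recovers the generating coefficients by OLS", {
  cfg <- noiseless_config(n_pre = 500)
  co <- generate_cohort(cfg, seed = 4)
  fit <- fit_full(as_mi_stack(co), model_spec("ferritin", "pre"))
  expect_gt(fit$r2_apparent, 0.999999)
  est <- setNames(fit$coefficients$qbar, fit$coefficients$term)
  truth <- cfg$betas$ferritin$pre
  expect_equal(est[names(truth)], truth, tolerance = 1e-5)
})

test_that("marginal fidelity: simulated prevalences and medians track the config", {
  cfg <- small_config(n_pre = 25000, n_post = 25000)
  co <- generate_cohort(cfg, seed = 9)
  pre <- co[co$menopause %in% 0, ]
  post <- co[co$menopause %in% 1, ]
  for (v in c("blood_donation_12mo", "statin", "polyps_ever")) {
    expect_lt(abs(mean(pre[[v]]) - cfg$covariates[[v]]$pre$p), 0.011)
    expect_lt(abs(mean(post[[v]]) - cfg$covariates[[v]]$post$p), 0.011)
  }
  expect_equal(median(pre$bmi), cfg$covariates$bmi$pre$mean, tolerance = 0.02)
  expect_equal(median(post$dietary_supp_calcium),
               exp(cfg$covariates$dietary_supp_calcium$post$meanlog),
               tolerance = 0.02)
  # stratum medians of serum iron fall within the published interquartile range
  expect_gt(median(pre$serum_iron), 74)
  expect_lt(median(pre$serum_iron), 115)
  expect_gt(median(post$serum_iron), 74)
  expect_lt(median(post$serum_iron), 115)
})

test_that("configuration invariants are enforced", {
  expect_error(generator_config(n_pre = -1, n_post = 10), "non-negative")
  expect_error(generator_config(n_pre = 5, n_post = 5, n_all_missing_outcomes = 11),
               "cannot exceed")
  cfg <- small_config()
  cfg$sigma$pre[["ferritin"]] <- -1
  expect_error(validate_generator_config(cfg), "positive")
  cfg <- small_config()
  cfg$rho[["iron_ts"]] <- 1.2
  expect_error(validate_generator_config(cfg), "correlations")
  cfg <- small_config()
  cfg$betas$ferritin$pre <- c(cfg$betas$ferritin$pre, nonexistent_thing = 1)
  expect_error(validate_generator_config(cfg), "nonexistent_thing")
  cfg <- small_config()
  cfg$covariates$statin$pre$p <- 1.4
  expect_error(validate_generator_config(cfg), "prevalences")
})

test_that("generator config survives a YAML round trip", {
  cfg <- small_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(cfg, path)
  back <- read_generator_config(path)
  expect_equal(back$betas, cfg$betas)
  expect_equal(back$sigma, cfg$sigma)
  expect_equal(back$rho, cfg$rho)
  # regeneration agrees up to serialization precision of the parameters
  expect_equal(generate_cohort(back, seed = 3), generate_cohort(cfg, seed = 3),
               tolerance = 1e-8)
})

test_that("the true linear predictor is the population regression surface", {
  cfg <- small_config(n_pre = 4000, n_post = 0)
  co <- generate_cohort(cfg, seed = 12)
  lp <- true_linear_predictor(co, cfg, "ferritin", "pre")
  # regressing realized log outcomes on the oracle predictor: slope ~ 1
  expect_equal(calibration_slope(log(co$ferritin), lp), 1, tolerance = 0.05)
})
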