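test_that("age-adjusted univariable screens isolate the generating effect", {
  cfg <- donation_only_config(n_pre = 3000, beta_don = -0.7, sigma = 0.3)
  co <- generate_cohort(cfg, seed = 14)
  stk <- as_mi_stack(co)
  don <- fit_univariable(stk, "blood_donation_12mo", "ferritin")
  expect_lt(abs(don$qbar - -0.7), 0.06)
  expect_lt(don$p.value, 1e-10)
  # a predictor with no generating effect: slope near zero
  nul <- fit_univariable(stk, "statin", "ferritin")
  expect_lt(abs(nul$qbar), 3 * nul$se)
})

test_that("univariable screen guards its preconditions", {
  co <- generate_cohort(small_config(n_pre = 80, n_post = 0), seed = 15)
  expect_error(fit_univariable(as_mi_stack(co), "age", "ferritin"), "age")
  co$statin <- 0
  expect_error(fit_univariable(as_mi_stack(co), "statin", "ferritin"),
               "constant")
})

test_that("the calibrated premenopausal model shows the published sign pattern", {
  cfg <- default_generator_config()
  co <- generate_cohort(cfg, seed = 16)
  pre <- co[co$menopause %in% 0, ]
  stk <- as_mi_stack(pre)
  for (o in c("ferritin", "serum_iron", "transferrin_saturation")) {
    don <- fit_univariable(stk, "blood_donation_12mo", o)
    expect_lt(don$qbar, 0)       # recent donation lowers all three biomarkers
    expect_lt(don$p.value, 0.01)
  }
})

test_that("full-model fit pools coefficients near the generating values", {
  cfg <- default_generator_config()
  co <- generate_cohort(cfg, seed = 17)
  pre <- co[co$menopause %in% 0, ]
  fit <- fit_full(as_mi_stack(pre), model_spec("ferritin", "pre"))
  tab <- tidy(fit)
  don <- tab[tab$term == "blood_donation_12mo", ]
  expect_lt(abs(don$estimate - -0.700), 0.25)
  expect_true(all(c("estimate", "conf.low", "conf.high", "W", "B", "T") %in%
                    names(tab)))
  g <- glance(fit)
  expect_equal(g$n_used, nrow(pre))
  expect_gte(g$r.squared, 0)
  expect_lte(g$r.squared, 1)
})

test_that("rank-deficient designs are reported with the offending columns", {
  co <- generate_cohort(small_config(n_pre = 200, n_post = 0), seed = 18)
  co$dup <- co$alcohol
  spec <- structure(list(outcome = "ferritin", stratum = "custom",
                         predictors = c("alcohol", "dup", "age")),
                    class = "iron_spec")
  expect_error(fit_full(as_mi_stack(co), spec), "dup")
})

test_that("backward elimination keeps strong signals and empties on noise", {
  # strong effects at large n: nothing is dropped
  cfg <- donation_only_config(n_pre = 4000, beta_don = -1, sigma = 0.2)
  cfg$betas$ferritin$pre[["ida_ever"]] <- -0.5
  cfg$betas$ferritin$pre[["bmi"]] <- 0.05
  co <- generate_cohort(cfg, seed = 19)
  spec <- model_spec("ferritin", "pre",
                     predictors = c("blood_donation_12mo", "ida_ever", "bmi"))
  sel <- backward_select(as_mi_stack(co), spec)
  expect_setequal(sel$selected, c("blood_donation_12mo", "ida_ever", "bmi"))
  expect_equal(nrow(sel$path), 0)
  # pure noise: everything is dropped, and each surviving p < threshold at exit
  cfg0 <- donation_only_config(n_pre = 300, beta_don = 0, sigma = 0.5)
  co0 <- generate_cohort(cfg0, seed = 20)
  spec0 <- model_spec("ferritin", "pre",
                      predictors = c("statin", "aspirin", "pcos_ever", "meat"))
  sel0 <- backward_select(as_mi_stack(co0), spec0)
  expect_length(sel0$selected, 0)
  expect_null(sel0$final_model)
  expect_lte(nrow(sel0$path), length(spec0$predictors))
})

test_that("selected predictors all beat the threshold on exit", {
  cfg <- default_generator_config()
  co <- generate_cohort(cfg, seed = 21)
  pre <- co[co$menopause %in% 0, ]
  sel <- backward_select(as_mi_stack(pre), model_spec("ferritin", "pre"))
  expect_gt(length(sel$selected), 0)
  coefs <- sel$final_model$coefficients
  expect_true(all(coefs$p.value[coefs$term != "(Intercept)"] < 0.05))
  expect_true(all(sel$selected %in% predictor_set("pre")))
  # the dominant generating effects survive selection
  expect_true(all(c("blood_donation_12mo", "ida_ever") %in% sel$selected))
})

test_that("coefficient recovery is unbiased at scale", {
  cfg <- small_config(n_pre = 10000, n_post = 0)
  co <- generate_cohort(cfg, seed = 22)
  fit <- fit_full(as_mi_stack(co), model_spec("ferritin", "pre"))
  est <- setNames(fit$coefficients$qbar, fit$coefficients$term)
  se <- setNames(fit$coefficients$se, fit$coefficients$term)
  truth <- cfg$betas$ferritin$pre
  for (term in names(truth)) {
    expect_lt(abs(est[[term]] - truth[[term]]), 4 * se[[term]])
  }
})
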