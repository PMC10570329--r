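# Shared fixtures: small configurations so most tests run in seconds.

small_config <- function(n_pre = 150, n_post = 250, n_mm = 0, n_amo = 0,
                         seed = 101) {
  cfg <- generator_config(n_pre = n_pre, n_post = n_post,
                          n_menopause_missing = n_mm,
                          n_all_missing_outcomes = n_amo, seed = seed)
  # upweight the rare health conditions so tiny test cohorts keep
  # non-constant binary columns
  for (v in c("ibd_ever", "pcos_ever")) {
    cfg$covariates[[v]]$pre$p <- 0.10
    cfg$covariates[[v]]$post$p <- 0.10
  }
  cfg
}

# Config whose outcomes are (nearly) deterministic functions of the
# covariates: residual SDs shrunk to eps, correlations zeroed.
noiseless_config <- function(n_pre = 400, n_post = 0, sigma_eps = 1e-8) {
  cfg <- small_config(n_pre = n_pre, n_post = n_post)
  for (s in c("pre", "post")) {
    cfg$sigma[[s]][] <- sigma_eps
  }
  cfg$rho[] <- 0
  cfg
}

# Config with a single active effect (recent blood donation on ferritin);
# everything else zeroed.
donation_only_config <- function(n_pre = 2000, beta_don = -0.7, sigma = 0.3) {
  cfg <- small_config(n_pre = n_pre, n_post = 0)
  for (o in names(cfg$betas)) {
    for (s in c("pre", "post")) cfg$betas[[o]][[s]][] <- 0
  }
  cfg$betas$ferritin$pre[["blood_donation_12mo"]] <- beta_don
  for (s in c("pre", "post")) cfg$sigma[[s]][] <- sigma
  cfg$rho[] <- 0
  cfg
}

# Null regression data: p standard-normal predictors, outcome pure noise.
null_regression_data <- function(n, p) {
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  tibble::as_tibble(as.data.frame(x)) |>
    dplyr::mutate(y = rnorm(n))
}

null_spec <- function(p) {
  structure(list(outcome = "y_raw", stratum = "custom",
                 predictors = paste0("x", seq_len(p))),
            class = "iron_spec")
}

# bootstrap_optimism and fit_ols model log(outcome); wrap the null outcome so
# log(exp(y)) = y.
as_log_cohort <- function(d) dplyr::mutate(d, y_raw = exp(y), y = NULL)
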