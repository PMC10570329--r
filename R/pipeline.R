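# End-to-end orchestration -------------------------------------------------------

#' Run configuration for the full pipeline
#'
#' @param generator an `iron_generator_config`, or a path to a cohort CSV
#'   (written by [write_cohort_csv()]) to analyze instead of simulating.
#' @param m imputations; `n_iter` chained-equation sweeps; `B` bootstrap
#'   replicates; `p_threshold` backward-elimination threshold; `K_folds`
#'   lasso cross-validation folds.
#' @param strata subset of `c("pre", "post", "combined")` to run.
#' @param outcomes subset of the three serum outcomes to run.
#' @param run_selection,run_validation,run_univariable stage switches.
#' @param complete_case analyze complete cases instead of imputing.
#' @param seed master seed.
#' @param out_dir output directory.
#' @return an object of class `iron_run_config`.
#' @export
run_config <- function(generator = default_generator_config(),
                       m = 5, n_iter = 10, B = 200, p_threshold = 0.05,
                       K_folds = 10,
                       strata = c("pre", "post", "combined"),
                       outcomes = model_outcomes(),
                       run_selection = TRUE, run_validation = TRUE,
                       run_univariable = FALSE,
                       complete_case = FALSE,
                       seed = 1L, out_dir = tempfile("ironpredict_run_")) {
  assert_that(m >= 1, "m must be >= 1")
  assert_that(B >= 1, "B must be >= 1")
  assert_that(p_threshold > 0 && p_threshold < 1, "p_threshold must lie in (0, 1)")
  structure(list(generator = generator, m = m, n_iter = n_iter, B = B,
                 p_threshold = p_threshold, K_folds = K_folds,
                 strata = match.arg(strata, several.ok = TRUE),
                 outcomes = match.arg(outcomes, model_outcomes(), several.ok = TRUE),
                 run_selection = run_selection, run_validation = run_validation,
                 run_univariable = run_univariable,
                 complete_case = complete_case,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "iron_run_config")
}

#' Execute the full analysis pipeline
#'
#' Generates (or loads) the cohort, applies the exclusion filter, stratifies
#' by menopause status, writes descriptive summaries, imputes each stratum,
#' fits the full multivariable models, runs both variable-selection
#' procedures, and performs bootstrap internal validation -- for every
#' requested outcome and stratum, including the combined model with the
#' menopause indicator. All outputs (table-shaped CSVs, validation JSONs, a
#' run manifest with content hashes, and a log) land in `config$out_dir`.
#'
#' @param config an [run_config()] object.
#' @return invisibly, a list with the in-memory results (`cohort`, `strata`,
#'   `describe`, `fits`, `selections`, `validations`, `manifest`).
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  stage <- "setup"
  manifest <- list(seed = config$seed, m = config$m, B = config$B,
                   package_version = as.character(utils::packageVersion("ironpredict")))
  result <- list()
  tryCatch({
    stage <- "generate"
    if (is.character(config$generator)) {
      raw <- read_cohort_csv(config$generator)
      manifest$source <- config$generator
    } else {
      raw <- generate_cohort(config$generator, seed = config$seed)
      raw <- impose_missingness(raw, config$generator, seed = config$seed)
      manifest$source <- "synthetic"
    }
    manifest$n_generated <- nrow(raw)
    log_line("generated/loaded %d rows", nrow(raw))

    stage <- "exclude"
    cohort <- exclude_all_missing_outcomes(raw, quiet = TRUE)
    manifest$n_excluded_all_missing <- attr(cohort, "n_excluded")
    manifest$n_analyzed <- nrow(cohort)
    log_line("excluded %d all-missing-outcome rows; %d analyzed",
             attr(cohort, "n_excluded"), nrow(cohort))

    stage <- "stratify"
    strata <- stratify_by_menopause(cohort, quiet = TRUE)
    manifest$n_post <- nrow(strata$post)
    manifest$n_pre <- nrow(strata$pre)
    manifest$n_missing_menopause <- strata$n_missing_menopause
    log_line("strata: %d post, %d pre, %d missing menopause",
             nrow(strata$post), nrow(strata$pre), strata$n_missing_menopause)

    stage <- "describe"
    desc <- describe_cohort(cohort)
    write_describe_csv(desc, file.path(config$out_dir, "table1_total.csv"))
    for (s in c("pre", "post")) {
      write_describe_csv(describe_cohort(strata[[s]]),
                         file.path(config$out_dir, sprintf("table1_%s.csv", s)))
    }

    stage <- "impute"
    combined_data <- dplyr::bind_rows(strata$post, strata$pre)
    analysis_sets <- list(pre = strata$pre, post = strata$post,
                          combined = combined_data)
    stacks <- list()
    for (s in intersect(config$strata, c("pre", "post", "combined"))) {
      dat <- analysis_sets[[s]]
      if (config$complete_case) {
        model_cols <- unique(c(term_source_cols(predictor_set(s)), "menopause",
                               outcome_vars()))
        cc <- dat[stats::complete.cases(dat[, intersect(model_cols, names(dat))]), ]
        stacks[[s]] <- as_mi_stack(cc)
      } else if (s == "combined") {
        # reuse the stratified imputations: combined stack = row-bound copies
        pre_stack <- stacks[["pre"]] %||%
          impute_cohort(strata$pre, m = config$m, n_iter = config$n_iter,
                        seed = child_seed(config$seed, 31L))
        post_stack <- stacks[["post"]] %||%
          impute_cohort(strata$post, m = config$m, n_iter = config$n_iter,
                        seed = child_seed(config$seed, 32L))
        stacks[[s]] <- structure(list(
          m = config$m,
          data = purrr::map2(post_stack$data, pre_stack$data, dplyr::bind_rows),
          log = dplyr::bind_rows(post_stack$log, pre_stack$log),
          seed = config$seed), class = "iron_mi")
      } else {
        stacks[[s]] <- impute_cohort(dat, m = config$m, n_iter = config$n_iter,
                                     seed = child_seed(config$seed,
                                                       if (s == "pre") 31L else 32L))
      }
      log_line("stratum %s: stack of m = %d", s, stacks[[s]]$m)
    }

    fits <- list(); selections <- list(); validations <- list(); screens <- list()
    for (s in names(stacks)) {
      for (o in config$outcomes) {
        key <- paste(s, o, sep = ".")
        spec <- model_spec(o, s)
        stage <- paste0("fit:", key)
        fits[[key]] <- fit_full(stacks[[s]], spec)
        log_line("%s: apparent R^2 = %.3f", key, fits[[key]]$r2_apparent)
        if (config$run_univariable && s != "combined") {
          stage <- paste0("univariable:", key)
          screens[[key]] <- screen_univariable(stacks[[s]], o, s)
        }
        if (config$run_selection) {
          stage <- paste0("backward:", key)
          bw <- backward_select(stacks[[s]], spec, config$p_threshold)
          stage <- paste0("lasso:", key)
          la <- stacked_lasso(stacks[[s]], spec, K = config$K_folds,
                              seed = child_seed(config$seed, 41L))
          selections[[key]] <- list(backward = bw, lasso = la)
          write_model_table(fits[[key]], bw, la,
                            file.path(config$out_dir, sprintf("model_%s.csv", key)))
          jsonlite::write_json(
            list(backward = bw$path, lasso_lambda_min = la$lambda_min),
            file.path(config$out_dir, sprintf("selection_%s.json", key)),
            auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "columns")
        }
        if (config$run_validation) {
          stage <- paste0("validate:", key)
          validations[[key]] <- validate_mi(stacks[[s]], spec, B = config$B,
                                            seed = child_seed(config$seed, 51L))
          write_validation_report(
            validations[[key]],
            json_path = file.path(config$out_dir, sprintf("validation_%s.json", key)),
            csv_path = file.path(config$out_dir, sprintf("performance_%s.csv", key)))
          log_line("%s: corrected R^2 = %.3f, slope = %.3f", key,
                   validations[[key]]$r2_corrected,
                   validations[[key]]$slope_internal)
        }
      }
    }

    stage <- "manifest"
    files <- setdiff(list.files(config$out_dir), "manifest.json")
    manifest$outputs <- lapply(files, function(f) {
      list(file = f, md5 = unname(tools::md5sum(file.path(config$out_dir, f))))
    })
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    result <- list(cohort = cohort, strata = strata, describe = desc,
                   stacks = stacks, fits = fits, selections = selections,
                   validations = validations, screens = screens,
                   manifest = manifest, out_dir = config$out_dir)
  }, error = function(e) {
    log_line("ERROR in stage %s: %s", stage, conditionMessage(e))
    abort(sprintf("pipeline failed in stage '%s': %s", stage, conditionMessage(e)))
  })
  invisible(result)
}

# Model-table CSV: backward / lasso / full-ML estimates side by side.
write_model_table <- function(fit, backward, lasso, path) {
  ml <- dplyr::select(fit$coefficients, "term", ml_estimate = "qbar",
                      conf.low = "conf.low", conf.high = "conf.high")
  bw_terms <- backward$selected
  bw_est <- if (!is.null(backward$final_model)) {
    stats::setNames(backward$final_model$coefficients$qbar,
                    backward$final_model$coefficients$term)
  } else c("(Intercept)" = NA_real_)
  la_est <- stats::setNames(lasso$coefficients$estimate, lasso$coefficients$term)
  tab <- dplyr::mutate(
    ml,
    backward = ifelse(ml$term %in% c(bw_terms, "(Intercept)"),
                      unname(bw_est[ml$term]), NA_real_),
    lasso = ifelse(ml$term %in% c(lasso$selected, "(Intercept)"),
                   unname(la_est[ml$term]), NA_real_)
  )
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
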