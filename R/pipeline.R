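# End-to-end orchestration: simulate -> prepare -> fit -> stability ->
# evaluate -> report, driven by one configuration and one seed. These
# functions back the command-line entry point in inst/scripts/crashsev.R.

#' Run the full severity-analysis pipeline
#'
#' Simulates (or loads) crash data, fits the multinomial-logit and
#' random-parameters models, runs the pairwise and joint temporal-stability
#' tests when more than one year is present, cross-validates the
#' random-forest baseline, and evaluates every model with the
#' comprehensive-cost framework. All numeric outputs are returned
#' machine-readable; [write_pipeline_outputs()] serialises them.
#'
#' @param config A [sim_config()] (for synthetic data) or a crash tibble
#'   (already prepared).
#' @param spec Model specification for estimation; defaults to the config's
#'   own spec when `config` is a `sim_config`.
#' @param halton A [halton_config()].
#' @param forest A [forest_config()].
#' @param costs A [cost_table()].
#' @param fit_random If `FALSE`, skip the random-parameters fit (MNL and
#'   forest only).
#' @return A list: `data`, `fits` (named list of `severity_fit`s),
#'   `forest_cv`, `stability`, `reports` (list of [evaluation_report()]s),
#'   `comparison` (from [compare_models()]).
#' @export
run_pipeline <- function(config, spec = NULL, halton = halton_config(),
                         forest = forest_config(), costs = cost_table_2017(),
                         fit_random = TRUE) {
  if (inherits(config, "sim_config")) {
    data <- if (!is.null(config$years) && length(config$years) >= 2) {
      simulate_crashes_years(config)
    } else {
      simulate_crashes(config)
    }
    spec <- spec %||% config$spec
  } else {
    data <- tibble::as_tibble(config)
    if (is.null(spec)) abort("`spec` is required when `config` is a dataset.")
  }

  fits <- list(mnl = fit_mnl(data, as_mnl_spec(spec)))
  if (fit_random && n_random_dims(spec) > 0) {
    fits$rpl <- fit_rpl(data, spec, halton)
  }

  stability <- NULL
  if ("year" %in% names(data) && length(unique(data$year)) >= 2) {
    stability <- stability_matrix(data, as_mnl_spec(spec), halton)
  }

  forest_cv <- kfold_cv(data, forest)

  reports <- list()
  main_fit <- fits$rpl %||% fits$mnl
  main_label <- if (!is.null(fits$rpl)) "rpl" else "mnl"
  pred <- predict_severity(data, main_fit)
  reports[[main_label]] <- evaluation_report(
    confusion_matrix(data$severity, pred$.pred_class), costs, model = main_label
  )
  reports$rf <- evaluation_report(forest_cv$confusion, costs, model = "rf")

  list(
    data = data, fits = fits, forest_cv = forest_cv, stability = stability,
    reports = reports, comparison = compare_models(reports)
  )
}

#' Write pipeline outputs to a directory
#'
#' Serialises every result of [run_pipeline()]: the dataset and coefficient
#' tables as headered CSV, the stability matrix (raw and formatted), the
#' model comparison (full precision and printed style), and a JSON manifest
#' recording the seed, draw settings and log-likelihoods.
#'
#' @param result Output of [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @param seed Seed to record in the manifest.
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir, seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_crash_csv(result$data, file.path(dir, "crashes.csv"))
  for (nm in names(result$fits)) {
    readr::write_csv(tidy(result$fits[[nm]]),
                     file.path(dir, paste0("coefficients_", nm, ".csv")))
  }
  if (!is.null(result$stability)) {
    readr::write_csv(result$stability, file.path(dir, "stability_matrix.csv"))
    readr::write_csv(format_stability_matrix(result$stability),
                     file.path(dir, "stability_matrix_formatted.csv"))
  }
  readr::write_csv(result$forest_cv$predictions, file.path(dir, "rf_cv_predictions.csv"))
  readr::write_csv(compare_models(result$reports, "full"),
                   file.path(dir, "model_comparison.csv"))
  readr::write_csv(compare_models(result$reports, "printed"),
                   file.path(dir, "model_comparison_printed.csv"))
  manifest <- list(
    seed = seed,
    n_obs = nrow(result$data),
    models = names(result$fits),
    loglik = lapply(result$fits, function(f) f$loglik),
    converged = lapply(result$fits, function(f) f$converged),
    n_draws = lapply(result$fits, function(f) {
      if (is.null(f$halton)) NA else f$halton$n_draws
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
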