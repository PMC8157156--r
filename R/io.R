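# Reading and writing the crash CSV dialect and the plain-text (YAML)
# configuration format.

#' Write a crash dataset to CSV
#'
#' Headered CSV with columns `crash_id`, `year`, `severity` (coded PDO / I /
#' FI), then one 0/1 column per covariate. [read_crash_csv()] inverts it
#' losslessly.
#'
#' @param data Crash tibble (as produced by [simulate_crashes()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_crash_csv <- function(data, path) {
  out <- data
  out$severity <- as.character(out$severity)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a crash dataset from CSV
#'
#' @param path CSV file written by [write_crash_csv()] (or following the
#'   same layout).
#' @return A crash tibble with `severity` as a factor over
#'   [severity_levels()].
#' @export
read_crash_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"severity" %in% names(data)) {
    abort("File is missing the required `severity` column.")
  }
  data$severity <- as_severity(data$severity)
  data
}

parse_spec_yaml <- function(node) {
  fixed <- lapply(node$fixed %||% list(), unlist)
  random <- lapply(node$random %||% list(), function(r) {
    random_term(r$term, level = r$level,
                mean_shifters = unlist(r$mean_shifters) %||% character(),
                var_shifters = unlist(r$var_shifters) %||% character())
  })
  model_spec(
    fixed = fixed, random = random,
    levels = unlist(node$levels) %||% severity_levels(),
    base = node$base %||% "PDO"
  )
}

#' Read a model specification from a YAML file
#'
#' The file holds `base` (optional, default PDO), `fixed` (a map from level
#' to a list of terms) and `random` (a list of entries with `term`, `level`,
#' optional `mean_shifters` and `var_shifters`). See
#' `system.file("extdata", "example_sim_config.yaml", package = "crashsev")`
#' for the full configuration dialect.
#'
#' @param path YAML file path.
#' @return A [model_spec()].
#' @export
read_model_spec <- function(path) {
  parse_spec_yaml(yaml::read_yaml(path))
}

#' Read a synthetic-data configuration from a YAML file
#'
#' Top-level keys: `n_crashes`, `seed`, `covariates` (list of `name`,
#' `group`, `prevalence` entries), `spec` (as in [read_model_spec()]),
#' `params` (a map from parameter name to value) and optional `years`
#' (list of `year` plus optional `shift` maps).
#'
#' @param path YAML file path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in c("n_crashes", "covariates", "spec", "params")) {
    if (is.null(cfg[[key]])) abort(sprintf("Config is missing the `%s` key.", key))
  }
  covs <- dplyr::bind_rows(lapply(cfg$covariates, function(cv) {
    covariate_spec(cv$name, cv$group %||% "crash", cv$prevalence %||% 0.5)
  }))
  years <- if (!is.null(cfg$years)) {
    lapply(cfg$years, function(y) list(year = y$year, shift = unlist(y$shift)))
  }
  sim_config(
    n_crashes = cfg$n_crashes, covariates = covs,
    spec = parse_spec_yaml(cfg$spec),
    params = unlist(cfg$params),
    seed = cfg$seed %||% 1L, years = years
  )
}
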