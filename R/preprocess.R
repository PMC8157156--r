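# Raw-extract preprocessing: multi-vehicle selection, incomplete-record
# removal, first-vehicle deduplication, severity recoding. Raw crash
# extracts are occupant/vehicle-level (one row per vehicle per crash), with
# `numvehs` the vehicle count and `vehno` the vehicle index within a crash;
# the analysis table has exactly one row per crash.

#' Keep multi-vehicle crashes
#'
#' Filters a raw crash table to crashes involving at least `min_vehicles`
#' vehicles. A multi-vehicle crash is conventionally one involving two or
#' more vehicles, so the default is 2; raise it to study higher-occupancy
#' collisions only.
#'
#' @param raw Raw crash table with a `numvehs` column.
#' @param min_vehicles Minimum vehicle count retained (default 2).
#' @return The filtered tibble, row order preserved.
#' @export
filter_multivehicle <- function(raw, min_vehicles = 2) {
  if (!"numvehs" %in% names(raw)) abort("`raw` is missing the `numvehs` column.")
  dplyr::filter(tibble::as_tibble(raw), .data$numvehs >= min_vehicles)
}

#' Drop rows with missing required information
#'
#' Removes rows with a missing value in any required column and records how
#' many rows each column disqualified (a row failing several columns is
#' removed once). Which tokens count as missing is configurable; by default
#' only `NA` and the empty string do, but police-coded sentinel values
#' (e.g. `"9"` codes) can be added.
#'
#' @param raw Raw crash table.
#' @param required_columns Character vector of columns that must be
#'   non-missing.
#' @param na_tokens Values treated as missing (default `NA` and `""`).
#' @return The filtered tibble; the removal log (a tibble of per-column
#'   counts plus rows removed in total) is attached as attribute
#'   `"removal_log"`.
#' @export
drop_incomplete <- function(raw, required_columns, na_tokens = c(NA, "")) {
  raw <- tibble::as_tibble(raw)
  missing_cols <- setdiff(required_columns, names(raw))
  if (length(missing_cols)) {
    abort(paste0("Required column(s) absent from the table: ",
                 paste(missing_cols, collapse = ", ")))
  }
  is_missing <- function(x) is.na(x) | as.character(x) %in% na_tokens[!is.na(na_tokens)]
  flags <- vapply(required_columns, function(cl) is_missing(raw[[cl]]),
                  logical(nrow(raw)))
  flags <- matrix(flags, nrow = nrow(raw))
  drop <- rowSums(flags) > 0
  log <- tibble::tibble(
    column = required_columns,
    n_missing = colSums(flags)
  )
  out <- raw[!drop, , drop = FALSE]
  attr(out, "removal_log") <- list(per_column = log, rows_removed = sum(drop))
  out
}

#' Keep the first vehicle of each crash
#'
#' Raw extracts repeat crash-level information once per vehicle; to avoid
#' that built-in collinearity, only the first vehicle's row (minimal
#' `vehno`) is retained per `crash_id`. If the minimal `vehno` is
#' duplicated, the first occurrence wins and a warning reports the affected
#' crashes.
#'
#' @param raw Raw crash table with `crash_id` and `vehno` columns.
#' @return A tibble with exactly one row per crash, in first-appearance
#'   order of `crash_id`.
#' @export
select_first_vehicle <- function(raw) {
  for (cl in c("crash_id", "vehno")) {
    if (!cl %in% names(raw)) abort(sprintf("`raw` is missing the `%s` column.", cl))
  }
  raw <- tibble::as_tibble(raw)
  raw$.row <- seq_len(nrow(raw))
  picked <- raw |>
    dplyr::group_by(.data$crash_id) |>
    dplyr::slice_min(.data$vehno, n = 1, with_ties = TRUE) |>
    dplyr::ungroup()
  dup <- picked |>
    dplyr::count(.data$crash_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    warn(sprintf(
      "Duplicated minimal `vehno` in %d crash(es); keeping the first occurrence.",
      nrow(dup)
    ))
    picked <- picked |>
      dplyr::group_by(.data$crash_id) |>
      dplyr::slice_min(.data$.row, n = 1) |>
      dplyr::ungroup()
  }
  picked <- picked[order(picked$.row), , drop = FALSE]
  picked$.row <- NULL
  picked
}

#' Default 5-to-3-level severity collapse
#'
#' Maps KABCO-style police codes to the three analysis levels: no injury
#' (`O`) to PDO; possible (`C`), non-incapacitating (`B`) and
#' incapacitating (`A`) injury to I; killed (`K`) to FI. Codes already on
#' the 3-level scale map to themselves.
#'
#' @return A named character vector (names = raw codes, values = analysis
#'   levels).
#' @export
default_severity_map <- function() {
  c(O = "PDO", C = "I", B = "I", A = "I", K = "FI",
    PDO = "PDO", I = "I", FI = "FI")
}

#' Recode severity onto the three analysis levels
#'
#' Collapses the raw severity coding onto the ordered levels PDO < I < FI
#' via an explicit mapping; every observed code must be covered, and
#' unmapped codes are reported by name.
#'
#' @param raw Crash table with a `severity` column.
#' @param mapping Named character vector from raw code to level; default
#'   [default_severity_map()].
#' @return The tibble with `severity` replaced by a factor over
#'   [severity_levels()].
#' @export
encode_severity <- function(raw, mapping = default_severity_map()) {
  if (!"severity" %in% names(raw)) abort("`raw` is missing the `severity` column.")
  raw <- tibble::as_tibble(raw)
  codes <- as.character(raw$severity)
  unmapped <- setdiff(unique(codes[!is.na(codes)]), names(mapping))
  if (length(unmapped)) {
    abort(paste0("Unmapped severity code(s): ",
                 paste(dQuote(unmapped, q = FALSE), collapse = ", "),
                 ". Extend `mapping` to cover them."))
  }
  bad_target <- setdiff(unique(mapping), severity_levels())
  if (length(bad_target)) {
    abort(paste0("Mapping targets outside the severity levels: ",
                 paste(bad_target, collapse = ", ")))
  }
  raw$severity <- factor(unname(mapping[codes]), levels = severity_levels())
  raw
}

#' Full raw-extract preparation pipeline
#'
#' Composes the four preprocessing steps — multi-vehicle filter, removal of
#' incomplete records, first-vehicle selection, severity recoding — into
#' one call. The composition is idempotent: running it on its own output
#' changes nothing.
#'
#' @param raw Raw crash table.
#' @param min_vehicles Passed to [filter_multivehicle()]; skipped (with all
#'   rows kept) when the table has no `numvehs` column and
#'   `min_vehicles = NULL`.
#' @param required_columns Passed to [drop_incomplete()] (default
#'   `"severity"`).
#' @param mapping Passed to [encode_severity()].
#' @param na_tokens Passed to [drop_incomplete()].
#' @return Analysis tibble with one row per crash.
#' @export
prepare_crashes <- function(raw, min_vehicles = 2,
                            required_columns = "severity",
                            mapping = default_severity_map(),
                            na_tokens = c(NA, "")) {
  out <- tibble::as_tibble(raw)
  if (!is.null(min_vehicles)) {
    if ("numvehs" %in% names(out)) {
      out <- filter_multivehicle(out, min_vehicles)
    }
  }
  out <- drop_incomplete(out, required_columns, na_tokens)
  log <- attr(out, "removal_log")
  if ("vehno" %in% names(out)) out <- select_first_vehicle(out)
  out <- encode_severity(out, mapping)
  attr(out, "removal_log") <- log
  out
}
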