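# Likelihood-ratio tests for temporal stability (parameter transferability)
# of severity models across years.

#' Confidence level of a chi-square statistic
#'
#' Returns \eqn{P(\chi^2_{df} \le x)}, the chi-square CDF at the statistic —
#' the "confidence level" convention under which a large statistic maps to a
#' value near 100% (rejecting transferability) and a small one to a value
#' near 0%.
#'
#' @param chi2 Nonnegative statistic (small negative values from numerical
#'   round-off are clipped to zero).
#' @param df Degrees of freedom (positive integer).
#' @return Probability in [0, 1].
#' @export
#' @examples
#' chi2_confidence(35.06, 9) # > 99.99%
#' chi2_confidence(7.48, 13) # 12.42%
chi2_confidence <- function(chi2, df) {
  if (any(df < 1)) abort("`df` must be a positive integer.")
  if (any(chi2 < -1e-6)) abort("`chi2` must be nonnegative.")
  pchisq(pmax(chi2, 0), df)
}

lr_result <- function(chi2, df, direction, converged = TRUE) {
  tibble::tibble(
    direction = direction,
    chi2 = chi2,
    df = as.integer(df),
    confidence = ifelse(df >= 1, chi2_confidence(pmax(chi2, 0), pmax(df, 1)), NA_real_),
    converged = converged
  )
}

#' Pairwise temporal-stability likelihood-ratio test
#'
#' For two year subsets, fits the model on each and computes, in both
#' directions, \eqn{\chi^2 = -2[LL(\beta_{y_1 y_2}) - LL(\beta_{y_1})]}:
#' the log-likelihood of year-1 data under year-2's converged parameters
#' (no re-estimation) against year 1's own fit. The statistic is
#' nonnegative by construction and is referred to a chi-square with degrees
#' of freedom equal to the number of estimated parameters. A confidence
#' level above the threshold (conventionally 95%) rejects the hypothesis
#' that the two years share one parameter vector.
#'
#' @param data_y1,data_y2 Crash tibbles for the two years.
#' @param spec A [model_spec()] (used for both years).
#' @param halton A [halton_config()]; ignored for a pure MNL spec.
#' @param labels Length-2 labels used in the `direction` column.
#' @return A tibble with one row per direction: `direction`, `chi2`, `df`,
#'   `confidence`, `converged`.
#' @export
lr_test_pairwise <- function(data_y1, data_y2, spec,
                             halton = halton_config(),
                             labels = c("y1", "y2")) {
  if (nrow(data_y1) == 0 || nrow(data_y2) == 0) abort("Both years must be nonempty.")
  fit <- function(d) {
    if (n_random_dims(spec) > 0) fit_rpl(d, spec, halton) else fit_mnl(d, spec)
  }
  f1 <- fit(data_y1)
  f2 <- fit(data_y2)
  p <- length(f1$theta)
  chi_12 <- -2 * (evaluate_fixed_params(data_y1, f2) - f1$loglik)
  chi_21 <- -2 * (evaluate_fixed_params(data_y2, f1) - f2$loglik)
  dplyr::bind_rows(
    lr_result(chi_12, p, sprintf("%s|%s", labels[1], labels[2]),
              f1$converged && f2$converged),
    lr_result(chi_21, p, sprintf("%s|%s", labels[2], labels[1]),
              f1$converged && f2$converged)
  )
}

#' Joint-versus-separate temporal-stability test
#'
#' Tests whether one pooled model suffices for all years:
#' \eqn{\chi^2 = -2[LL(\beta_{joint}) - \sum_y LL(\beta_y)]}, with degrees
#' of freedom the total separate parameter count minus the joint count. A
#' single "year" equal to the pooled data is the degenerate edge case
#' (statistic 0 on 0 degrees of freedom, confidence undefined).
#'
#' @param data_all Pooled crash tibble.
#' @param per_year Named list of per-year tibbles partitioning `data_all`.
#' @param spec A [model_spec()].
#' @param halton A [halton_config()].
#' @return A one-row tibble as in [lr_test_pairwise()], with
#'   `direction = "joint"`.
#' @export
lr_test_joint <- function(data_all, per_year, spec, halton = halton_config()) {
  if (sum(vapply(per_year, nrow, 0L)) != nrow(data_all)) {
    abort("`per_year` must partition `data_all`.")
  }
  fit <- function(d) {
    if (n_random_dims(spec) > 0) fit_rpl(d, spec, halton) else fit_mnl(d, spec)
  }
  joint <- fit(data_all)
  seps <- lapply(per_year, fit)
  ll_sep <- sum(vapply(seps, function(f) f$loglik, 0))
  p_joint <- length(joint$theta)
  df <- length(seps) * p_joint - p_joint
  chi2 <- -2 * (joint$loglik - ll_sep)
  converged <- joint$converged && all(vapply(seps, function(f) f$converged, TRUE))
  lr_result(chi2, df, "joint", converged)
}

#' Full pairwise stability matrix across years
#'
#' Fits the model once per year, then computes the transferred-parameter
#' statistic for every ordered pair of years: the cell (from, to) is
#' \eqn{-2[LL(\beta_{to \leftarrow from}) - LL(\beta_{to})]} — "to"'s data
#' under "from"'s parameters against "to"'s own fit. The matrix is
#' asymmetric. Cells whose confidence is below `threshold` are flagged as
#' not rejecting stability.
#'
#' @param data Crash tibble with a `year` column.
#' @param spec A [model_spec()].
#' @param halton A [halton_config()].
#' @param threshold Confidence level above which stability is rejected
#'   (default 0.95).
#' @return A tibble with columns `year_from`, `year_to`, `chi2`, `df`,
#'   `confidence`, `stability_rejected`, `converged`; empty for fewer than
#'   two years.
#' @export
stability_matrix <- function(data, spec, halton = halton_config(),
                             threshold = 0.95) {
  if (!"year" %in% names(data)) abort("`data` must contain a `year` column.")
  years <- sort(unique(data$year))
  if (length(years) < 2) {
    return(tibble::tibble(
      year_from = character(), year_to = character(), chi2 = numeric(),
      df = integer(), confidence = numeric(), stability_rejected = logical(),
      converged = logical()
    ))
  }
  fit <- function(d) {
    if (n_random_dims(spec) > 0) fit_rpl(d, spec, halton) else fit_mnl(d, spec)
  }
  subsets <- lapply(years, function(y) data[data$year == y, , drop = FALSE])
  fits <- lapply(subsets, fit)
  p <- length(fits[[1]]$theta)
  rows <- list()
  for (a in seq_along(years)) {
    for (b in seq_along(years)) {
      if (a == b) next
      chi2 <- -2 * (evaluate_fixed_params(subsets[[b]], fits[[a]]) -
                      fits[[b]]$loglik)
      rows[[length(rows) + 1]] <- tibble::tibble(
        year_from = as.character(years[a]),
        year_to = as.character(years[b]),
        chi2 = chi2, df = p,
        confidence = chi2_confidence(max(chi2, 0), p),
        converged = fits[[a]]$converged && fits[[b]]$converged
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$stability_rejected <- out$confidence >= threshold
  out[, c("year_from", "year_to", "chi2", "df", "confidence",
          "stability_rejected", "converged")]
}

#' Format a stability matrix in the conventional table layout
#'
#' Renders each cell as `chi2 (df)[confidence%]`, rows indexed by the
#' transferring year and columns by the evaluated year.
#'
#' @param matrix_tbl Output of [stability_matrix()].
#' @return A tibble of formatted cells (character), one row per
#'   `year_from`.
#' @export
format_stability_matrix <- function(matrix_tbl) {
  if (nrow(matrix_tbl) == 0) return(tibble::tibble())
  matrix_tbl |>
    dplyr::mutate(cell = sprintf("%.2f (%d)[%.2f%%]", .data$chi2, .data$df,
                                 100 * .data$confidence)) |>
    dplyr::select("year_from", "year_to", "cell") |>
    tidyr::pivot_wider(names_from = "year_to", values_from = "cell",
                       values_fill = "-")
}
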