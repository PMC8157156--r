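# Confusion-matrix and comprehensive-crash-cost evaluation. Accuracy treats
# every crash alike; the cost indicators weight each error by the economic
# plus quality-adjusted-life-year (QALY) cost of the severity levels
# involved, which is what matters when the classifier feeds an economic
# appraisal.

#' Build a confusion matrix from label vectors
#'
#' Counts `P[i, j]` of crashes with actual severity `i` predicted as `j`,
#' rows and columns ordered PDO, I, FI.
#'
#' @param actual,predicted Equal-length severity label vectors.
#' @return A `confusion_matrix`: a 3x3 integer matrix with `actual` /
#'   `predicted` dimnames.
#' @export
confusion_matrix <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    abort("`actual` and `predicted` must have equal length.")
  }
  a <- as_severity(actual, "actual")
  p <- as_severity(predicted, "predicted")
  m <- table(actual = a, predicted = p)
  m <- matrix(as.integer(m), 3, 3,
              dimnames = list(actual = severity_levels(),
                              predicted = severity_levels()))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Build a confusion matrix from a table of counts
#'
#' For entering published or externally computed counts directly. Rows are
#' actual levels, columns predicted levels, both in PDO, I, FI order.
#'
#' @param counts 3x3 numeric matrix or data frame of nonnegative integers.
#' @return A `confusion_matrix`.
#' @export
#' @examples
#' confusion_from_counts(rbind(c(10, 2, 0), c(3, 5, 1), c(0, 1, 2)))
confusion_from_counts <- function(counts) {
  m <- as.matrix(counts)
  if (!all(dim(m) == c(3, 3))) abort("`counts` must be 3x3 (PDO, I, FI order).")
  if (any(m < 0) || any(m != round(m))) abort("Counts must be nonnegative integers.")
  m <- matrix(as.integer(m), 3, 3,
              dimnames = list(actual = severity_levels(),
                              predicted = severity_levels()))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> actual (rows) x predicted (columns)\n")
  print(unclass(x))
  invisible(x)
}

#' Per-row prediction ratios of a confusion matrix
#'
#' `R[i, j] = P[i, j] / N_i`: within each actual level, the share predicted
#' as each level. Rows with no crashes yield `NA`.
#'
#' @param cm A [confusion_matrix()].
#' @return A tibble: `actual`, `predicted`, `count`, `ratio`.
#' @export
confusion_ratios <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n_i <- rowSums(cm)
  tibble::tibble(
    actual = rep(severity_levels(), each = 3),
    predicted = rep(severity_levels(), times = 3),
    count = as.integer(t(cm)),
    ratio = as.numeric(t(cm / ifelse(n_i > 0, n_i, NA_real_)))
  )
}

#' Overall prediction accuracy
#'
#' The share of crashes on the diagonal: correct predictions over all
#' crashes.
#'
#' @param cm A [confusion_matrix()].
#' @return Fraction in [0, 1].
#' @export
overall_accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- sum(cm)
  if (n == 0) abort("Confusion matrix is empty.")
  sum(diag(cm)) / n
}

#' Comprehensive crash cost
#'
#' The comprehensive unit cost of a severity level is the sum of its
#' economic cost (observable losses) and its QALY cost (monetised
#' quality-of-life loss).
#'
#' @param economic,qaly Nonnegative per-level unit costs (USD).
#' @return Elementwise sum.
#' @export
#' @examples
#' comprehensive_cost(46132, 97535)
comprehensive_cost <- function(economic, qaly) {
  if (any(economic < 0) || any(qaly < 0)) abort("Costs must be nonnegative.")
  economic + qaly
}

#' Build a per-severity cost table
#'
#' @param economic,qaly Length-3 nonnegative unit costs (USD), in PDO, I,
#'   FI order.
#' @return A tibble: `level`, `economic_cost`, `qaly_cost`,
#'   `comprehensive_cost`.
#' @export
cost_table <- function(economic, qaly) {
  stopifnot(length(economic) == 3, length(qaly) == 3)
  tibble::tibble(
    level = severity_levels(),
    economic_cost = as.numeric(economic),
    qaly_cost = as.numeric(qaly),
    comprehensive_cost = comprehensive_cost(as.numeric(economic), as.numeric(qaly))
  )
}

#' 2017 comprehensive crash unit costs
#'
#' The default cost table (2017 USD): PDO 12,456 economic / 0 QALY; injury
#' 46,132 / 97,535; fatal 588,738 / 3,173,900. Re-basing to another year
#' (e.g. by consumer-price-index or median-weekly-earnings multipliers) is
#' up to the user: supply a custom [cost_table()].
#'
#' @return A [cost_table()] tibble.
#' @export
#' @examples
#' cost_table_2017()
cost_table_2017 <- function() {
  cost_table(economic = c(12456, 46132, 588738),
             qaly = c(0, 97535, 3173900))
}

check_costs <- function(costs) {
  stopifnot(is.data.frame(costs),
            all(c("level", "comprehensive_cost") %in% names(costs)))
  if (!identical(as.character(costs$level), severity_levels())) {
    abort("`costs` must have rows PDO, I, FI in order.")
  }
  costs
}

#' Actual overall cost of crashes
#'
#' Total comprehensive cost of the evaluation set as it actually occurred:
#' the actual-level row totals weighted by unit costs,
#' \eqn{AOCC = \sum_i N_i \cdot CCC_i}.
#'
#' @param cm A [confusion_matrix()].
#' @param costs A [cost_table()] (default [cost_table_2017()]).
#' @return USD.
#' @export
aocc <- function(cm, costs = cost_table_2017()) {
  stopifnot(inherits(cm, "confusion_matrix"))
  costs <- check_costs(costs)
  sum(rowSums(cm) * costs$comprehensive_cost)
}

#' Predicted overall cost of crashes
#'
#' Total comprehensive cost of the predictions: predicted-level column
#' totals weighted by the predicted level's unit cost,
#' \eqn{POCC = \sum_j (\sum_i P_{ij}) \cdot CCC_j}.
#'
#' @inheritParams aocc
#' @return USD.
#' @export
pocc <- function(cm, costs = cost_table_2017()) {
  stopifnot(inherits(cm, "confusion_matrix"))
  costs <- check_costs(costs)
  sum(colSums(cm) * costs$comprehensive_cost)
}

#' Cost-based prediction-error indicators
#'
#' The three cost indicators comparing predicted with actual overall crash
#' cost over an evaluation set of \eqn{N} crashes:
#' \deqn{OPMAE = |AOCC - POCC| / N \quad (USD per crash),}
#' \deqn{OPAPE = |AOCC - POCC| / AOCC \quad (fraction),}
#' \deqn{OPRMSE = \sqrt{(AOCC - POCC)^2 / N} = |AOCC - POCC| / \sqrt{N}.}
#'
#' @inheritParams aocc
#' @return One-row tibble: `n`, `aocc`, `pocc`, `opmae`, `opape`, `oprmse`
#'   (all costs in raw USD, `opape` a fraction).
#' @export
cost_errors <- function(cm, costs = cost_table_2017()) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- sum(cm)
  if (n == 0) abort("Confusion matrix is empty.")
  a <- aocc(cm, costs)
  p <- pocc(cm, costs)
  if (a <= 0) abort("AOCC must be positive to form OPAPE.")
  gap <- abs(a - p)
  tibble::tibble(
    n = n, aocc = a, pocc = p,
    opmae = gap / n, opape = gap / a, oprmse = gap / sqrt(n)
  )
}

#' Full evaluation report for one model
#'
#' Bundles overall accuracy, the per-level correct-prediction ratios
#' \eqn{R_{ii}}, and all cost indicators, at full precision.
#'
#' @inheritParams aocc
#' @param model Label for the model being evaluated.
#' @return An `evaluation_report` (also a one-row tibble): `model`, `n`,
#'   `r_overall`, `r_PDO`, `r_I`, `r_FI`, `aocc`, `pocc`, `opmae`, `opape`,
#'   `oprmse`; the confusion matrix rides along as attribute `"confusion"`.
#' @export
evaluation_report <- function(cm, costs = cost_table_2017(), model = "model") {
  errs <- cost_errors(cm, costs)
  n_i <- rowSums(cm)
  rii <- ifelse(n_i > 0, diag(cm) / n_i, NA_real_)
  out <- dplyr::bind_cols(
    tibble::tibble(
      model = model,
      n = errs$n,
      r_overall = overall_accuracy(cm),
      r_PDO = rii[[1]], r_I = rii[[2]], r_FI = rii[[3]]
    ),
    errs[, c("aocc", "pocc", "opmae", "opape", "oprmse")]
  )
  attr(out, "confusion") <- cm
  class(out) <- c("evaluation_report", class(out))
  out
}

#' Compare evaluation reports side by side
#'
#' One column per model, one row per indicator — accuracy as a percentage,
#' overall costs in USD millions, errors in the units of
#' [cost_errors()]. With `style = "printed"`, values are rendered the way
#' such comparison tables are conventionally printed: percentages to two
#' decimals, overall costs truncated to integer USD millions, the
#' mean-absolute error truncated to integer USD, and the root-mean-squared
#' error in thousands of USD.
#'
#' @param reports List of [evaluation_report()]s.
#' @param style `"full"` (numeric, full precision) or `"printed"`.
#' @return A tibble with an `indicator` column and one column per model.
#' @export
compare_models <- function(reports, style = c("full", "printed")) {
  style <- match.arg(style)
  stopifnot(length(reports) >= 1)
  cols <- lapply(reports, function(r) {
    if (style == "full") {
      c(r_overall = r$r_overall, opmae = r$opmae, opape = r$opape,
        oprmse = r$oprmse, pocc = r$pocc, aocc = r$aocc)
    } else {
      c(
        r_overall = sprintf("%.2f%%", 100 * r$r_overall),
        opmae = format(trunc(r$opmae), big.mark = ","),
        opape = sprintf("%.2f%%", 100 * r$opape),
        oprmse_thousand_usd = format(round(r$oprmse / 1e3), big.mark = ","),
        pocc_million_usd = format(trunc(r$pocc / 1e6), big.mark = ","),
        aocc_million_usd = format(trunc(r$aocc / 1e6), big.mark = ",")
      )
    }
  })
  names(cols) <- vapply(reports, function(r) r$model, "")
  out <- tibble::tibble(indicator = names(cols[[1]]))
  for (nm in names(cols)) out[[nm]] <- unname(cols[[nm]])
  out
}

#' Published evaluation confusion matrices
#'
#' Loads the published 3x3 confusion-matrix counts shipped with the package
#' (under `inst/extdata/`) for the two models evaluated in the source
#' study: the random-parameters logit (`"rpl"`) and the random forest
#' (`"rf"`). These counts are inputs — everything derived from them
#' (ratios, costs, error indicators) is recomputed by this package's
#' functions.
#'
#' @param model `"rpl"` or `"rf"`.
#' @return A [confusion_from_counts()] matrix.
#' @export
published_confusion <- function(model = c("rpl", "rf")) {
  model <- match.arg(model)
  path <- system.file("extdata", paste0("published_confusion_", model, ".csv"),
                      package = "crashsev", mustWork = TRUE)
  tbl <- utils::read.csv(path, check.names = FALSE)
  confusion_from_counts(as.matrix(tbl[, severity_levels()]))
}
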