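#' Declare a random coefficient with heterogeneity in mean and variance
#'
#' A random coefficient on covariate `term` for severity `level` varies
#' across crashes as
#' \deqn{\beta_i = \bar\beta + \delta' Z_i + \sigma \exp(\omega' W_i)\,\nu_i,
#' \quad \nu_i \sim N(0, 1),}
#' so its mean shifts with the `mean_shifters` covariates \eqn{Z} and its
#' standard deviation scales multiplicatively with the `var_shifters`
#' covariates \eqn{W}.
#'
#' @param term Covariate name (or `"(Intercept)"`).
#' @param level Severity level the coefficient belongs to (not the base).
#' @param mean_shifters Character vector of covariates entering the mean
#'   (\eqn{Z}); may be empty.
#' @param var_shifters Character vector of covariates entering the log
#'   standard deviation (\eqn{W}); may be empty.
#' @return A `random_term` list, for use in [model_spec()].
#' @export
#' @examples
#' random_term("occ_restraints", level = "I",
#'             mean_shifters = "sudden_slowing",
#'             var_shifters = "middle_aged_driver")
random_term <- function(term, level,
                        mean_shifters = character(),
                        var_shifters = character()) {
  stopifnot(is.character(term), length(term) == 1)
  structure(
    list(
      term = term, level = level,
      mean_shifters = as.character(mean_shifters),
      var_shifters = as.character(var_shifters)
    ),
    class = "random_term"
  )
}

#' Specify a severity model
#'
#' Declares which covariates enter the propensity of which severity level,
#' which coefficients are fixed and which are random, and which level is the
#' base (all of whose parameters are normalised to zero). Constants are
#' requested with the term `"(Intercept)"`.
#'
#' @param fixed Named list: one character vector of terms per non-base
#'   severity level.
#' @param random List of [random_term()] entries (may be empty, giving a
#'   plain multinomial logit).
#' @param levels Ordered severity labels; default [severity_levels()].
#' @param base Base severity level; default `"PDO"`.
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' model_spec(
#'   fixed = list(I = c("(Intercept)", "male_driver"), FI = "(Intercept)"),
#'   random = list(random_term("occ_restraints", level = "I"))
#' )
model_spec <- function(fixed = list(), random = list(),
                       levels = severity_levels(), base = "PDO") {
  if (!base %in% levels) abort("`base` must be one of `levels`.")
  bad_lv <- setdiff(names(fixed), levels)
  if (length(bad_lv) > 0) {
    abort(paste0("Unknown severity level(s) in `fixed`: ",
                 paste(bad_lv, collapse = ", ")))
  }
  if (base %in% names(fixed) && length(fixed[[base]]) > 0) {
    abort("The base level must have no entries (its parameters are fixed at 0).")
  }
  if (length(random) > 0 && !all(vapply(random, inherits, TRUE, "random_term"))) {
    abort("`random` must be a list of random_term() objects.")
  }
  for (rt in random) {
    if (!rt$level %in% levels || rt$level == base) {
      abort(sprintf("Random term %s is on an invalid level %s.",
                    dQuote(rt$term, q = FALSE), dQuote(rt$level, q = FALSE)))
    }
  }
  pairs <- c(
    unlist(lapply(names(fixed), function(lv) paste(lv, fixed[[lv]], sep = ":"))),
    vapply(random, function(rt) paste(rt$level, rt$term, sep = ":"), "")
  )
  if (anyDuplicated(pairs)) {
    abort(paste0("Duplicate (level, term) pair(s): ",
                 paste(unique(pairs[duplicated(pairs)]), collapse = ", ")))
  }
  structure(
    list(levels = levels, base = base, fixed = fixed, random = random),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> levels:", paste(x$levels, collapse = " < "),
      " (base:", x$base, ")\n")
  for (lv in names(x$fixed)) {
    if (length(x$fixed[[lv]]) > 0)
      cat("  fixed  ", lv, ": ", paste(x$fixed[[lv]], collapse = ", "), "\n", sep = "")
  }
  for (rt in x$random) {
    cat("  random ", rt$level, ": ", rt$term, sep = "")
    if (length(rt$mean_shifters)) cat(" | mean ~ ", paste(rt$mean_shifters, collapse = " + "), sep = "")
    if (length(rt$var_shifters)) cat(" | sd ~ ", paste(rt$var_shifters, collapse = " + "), sep = "")
    cat("\n")
  }
  invisible(x)
}

n_random_dims <- function(spec) length(spec$random)

#' Parameter table of a model specification
#'
#' Enumerates, in estimation order, every free parameter of a [model_spec()]:
#' fixed coefficients first (level-major), then for each random term its
#' mean, standard deviation, mean-heterogeneity coefficients (one per Z
#' covariate) and variance-heterogeneity coefficients (one per W covariate).
#'
#' @param spec A [model_spec()].
#' @return A tibble with columns `name`, `kind` (fixed / mean / sd / delta /
#'   omega), `level`, `term`, `shifter`.
#' @export
param_template <- function(spec) {
  rows <- list()
  for (lv in names(spec$fixed)) {
    for (tm in spec$fixed[[lv]]) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        name = paste0(lv, ":", tm), kind = "fixed",
        level = lv, term = tm, shifter = NA_character_
      )
    }
  }
  for (rt in spec$random) {
    id <- paste0(rt$level, ":", rt$term)
    rows[[length(rows) + 1]] <- tibble::tibble(
      name = id, kind = "mean", level = rt$level, term = rt$term,
      shifter = NA_character_
    )
    rows[[length(rows) + 1]] <- tibble::tibble(
      name = paste0("sd(", id, ")"), kind = "sd", level = rt$level,
      term = rt$term, shifter = NA_character_
    )
    for (z in rt$mean_shifters) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        name = paste0(id, "|mean:", z), kind = "delta", level = rt$level,
        term = rt$term, shifter = z
      )
    }
    for (w in rt$var_shifters) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        name = paste0(id, "|sd:", w), kind = "omega", level = rt$level,
        term = rt$term, shifter = w
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(name = character(), kind = character(),
                          level = character(), term = character(),
                          shifter = character()))
  }
  dplyr::bind_rows(rows)
}

# Column accessor: "(Intercept)" is the all-ones column, anything else must
# exist in the data.
spec_column <- function(data, term) {
  if (term == "(Intercept)") return(rep(1, nrow(data)))
  if (!term %in% names(data)) {
    abort(sprintf("Covariate %s is missing from the data.", dQuote(term, q = FALSE)))
  }
  as.numeric(data[[term]])
}

# Precompute everything the likelihood needs from a spec + data frame.
# `require_outcome = FALSE` allows prediction on unlabelled data.
build_model_data <- function(spec, data, require_outcome = TRUE) {
  K <- length(spec$levels)
  n <- nrow(data)
  y <- NULL
  if (require_outcome) {
    if (!"severity" %in% names(data)) abort("Data must contain a `severity` column.")
    y <- match(as.character(data$severity), spec$levels)
    if (anyNA(y)) abort("`severity` contains labels outside the spec's levels.")
  }
  tpl <- param_template(spec)
  fixed_idx <- which(tpl$kind == "fixed")
  fixed <- lapply(fixed_idx, function(j) {
    list(level = match(tpl$level[j], spec$levels),
         x = spec_column(data, tpl$term[j]))
  })
  random <- lapply(spec$random, function(rt) {
    list(
      level = match(rt$level, spec$levels),
      x = spec_column(data, rt$term),
      Z = if (length(rt$mean_shifters))
        vapply(rt$mean_shifters, function(z) spec_column(data, z), numeric(n)),
      W = if (length(rt$var_shifters))
        vapply(rt$var_shifters, function(w) spec_column(data, w), numeric(n))
    )
  })
  list(spec = spec, template = tpl, n = n, K = K, y = y,
       fixed = fixed, random = random)
}

# Split a packed parameter vector into the per-block structure implied by
# the template: list(fixed = numeric, random = list of (mean, sd, delta, omega)).
unpack_params <- function(theta, md) {
  tpl <- md$template
  stopifnot(length(theta) == nrow(tpl))
  names(theta) <- tpl$name
  fixed <- unname(theta[tpl$kind == "fixed"])
  random <- vector("list", length(md$random))
  for (e in seq_along(md$spec$random)) {
    rt <- md$spec$random[[e]]
    id <- paste0(rt$level, ":", rt$term)
    random[[e]] <- list(
      mean = unname(theta[tpl$name == id & tpl$kind == "mean"]),
      sd = unname(theta[tpl$name == paste0("sd(", id, ")")]),
      delta = unname(theta[tpl$kind == "delta" & tpl$level == rt$level & tpl$term == rt$term]),
      omega = unname(theta[tpl$kind == "omega" & tpl$level == rt$level & tpl$term == rt$term])
    )
  }
  list(fixed = fixed, random = random)
}
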