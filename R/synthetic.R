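# Synthetic crash-data generation from the exact data-generating process the
# estimators assume: binary covariates, per-crash random coefficients with
# heterogeneity in means and variances, Gumbel propensity errors, severity
# recorded as the argmax propensity.

#' Declare a binary crash covariate
#'
#' @param name Column name.
#' @param group One of `"driver"`, `"roadway"`, `"crash"`, `"occupant"` —
#'   the four characteristic groups crash covariates are organised into.
#' @param prevalence Probability that the indicator equals 1.
#' @return A one-row tibble.
#' @export
#' @examples
#' covariate_spec("male_driver", "driver", 0.5)
covariate_spec <- function(name, group = c("driver", "roadway", "crash", "occupant"),
                           prevalence = 0.5) {
  group <- match.arg(group)
  if (prevalence < 0 || prevalence > 1) abort("`prevalence` must be in [0, 1].")
  tibble::tibble(name = name, group = group, prevalence = prevalence)
}

#' Configure a synthetic crash dataset
#'
#' Bundles the ground truth (a [model_spec()] plus a full parameter vector),
#' the covariate design, the sample size, the seed, and — for multi-year
#' data — per-year additive parameter perturbations.
#'
#' @param n_crashes Crashes per year (positive integer).
#' @param covariates Tibble of covariates (rows from [covariate_spec()],
#'   `dplyr::bind_rows`-ed); names must be unique.
#' @param spec The true [model_spec()].
#' @param params Named numeric vector covering `param_template(spec)`.
#' @param seed Integer seed; everything downstream is bit-reproducible given
#'   it.
#' @param years Optional list of year entries, each
#'   `list(year = <label>, shift = <named numeric>)`; `shift` is added to
#'   the named parameters for that year (and may be omitted).
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_crashes, covariates, spec, params, seed = 1L,
                       years = NULL) {
  stopifnot(n_crashes >= 1, inherits(spec, "model_spec"))
  if (anyDuplicated(covariates$name)) abort("Covariate names must be unique.")
  tpl <- param_template(spec)
  theta <- align_params(params, tpl)
  if (!is.null(years)) {
    labels <- vapply(years, function(y) as.character(y$year), "")
    if (anyDuplicated(labels)) abort("Duplicate year labels in `years`.")
    for (y in years) {
      extra <- setdiff(names(y$shift), tpl$name)
      if (length(extra)) {
        abort(paste0("Year ", y$year, " perturbs unknown parameter(s): ",
                     paste(extra, collapse = ", ")))
      }
    }
  }
  structure(
    list(n_crashes = as.integer(n_crashes), covariates = covariates,
         spec = spec, params = setNames(theta, tpl$name),
         seed = as.integer(seed), years = years),
    class = "sim_config"
  )
}

draw_covariates <- function(covariates, n) {
  cols <- lapply(seq_len(nrow(covariates)), function(j) {
    rbinom(n, 1L, covariates$prevalence[j])
  })
  names(cols) <- covariates$name
  tibble::as_tibble(cols)
}

simulate_one_block <- function(config, params, year, id_offset = 0L) {
  n <- config$n_crashes
  X <- draw_covariates(config$covariates, n)
  md <- build_model_data(config$spec, X, require_outcome = FALSE)
  dims <- n_random_dims(config$spec)
  draws <- if (dims > 0) array(rnorm(n * dims), dim = c(n, 1L, dims))
  built <- build_utilities(align_params(params, md$template), md, draws)
  K <- md$K
  V <- matrix(0, n, K)
  for (k in seq_len(K)) V[, k] <- as.numeric(built$U[[k]])
  if (any(!is.finite(V))) {
    abort("Non-finite propensity; the configured parameters are too extreme.")
  }
  gumbel <- matrix(-log(-log(runif(n * K))), n, K)
  sev <- config$spec$levels[max.col(V + gumbel, ties.method = "first")]
  out <- tibble::tibble(
    crash_id = id_offset + seq_len(n),
    year = year,
    severity = factor(sev, levels = severity_levels())
  )
  dplyr::bind_cols(out, X)
}

#' Generate a synthetic crash dataset
#'
#' Draws covariates Bernoulli(prevalence), realises per-crash coefficients
#' from the heterogeneity structure (one standard-normal disturbance per
#' crash per random coefficient), adds iid standard Gumbel errors to the
#' propensities, and records the severity level with the highest propensity.
#' Output is bit-reproducible given the config's seed.
#'
#' @param config A [sim_config()]. If it carries `years`, only the first
#'   year's truth is used; see [simulate_crashes_years()] for multi-year
#'   data.
#' @param year Year label for the `year` column (default 1).
#' @return A tibble: `crash_id`, `year`, `severity` (factor PDO/I/FI), one
#'   0/1 column per covariate.
#' @export
simulate_crashes <- function(config, year = 1L) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    simulate_one_block(config, config$params, year)
  })
}

#' Generate a multi-year synthetic crash dataset
#'
#' One block of `n_crashes` per configured year, each drawn from the truth
#' after applying that year's additive parameter shifts, on a disjoint
#' random substream (so adding a year never changes earlier years'
#' realisations).
#'
#' @param config A [sim_config()] with at least two `years` entries.
#' @return A tibble of `n_crashes * length(years)` rows with the `year`
#'   column populated.
#' @export
simulate_crashes_years <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$years) || length(config$years) < 2) {
    abort("`config` must declare at least two years.")
  }
  blocks <- vector("list", length(config$years))
  for (i in seq_along(config$years)) {
    yr <- config$years[[i]]
    params <- config$params
    if (!is.null(yr$shift)) {
      params[names(yr$shift)] <- params[names(yr$shift)] + unlist(yr$shift)
    }
    blocks[[i]] <- withr::with_seed(config$seed + 1000L * i, {
      simulate_one_block(config, params, yr$year,
                         id_offset = (i - 1L) * config$n_crashes)
    })
  }
  dplyr::bind_rows(blocks)
}

#' Population severity shares implied by a truth
#'
#' Deterministically computes the expected severity shares under a
#' specification and parameter vector: covariate patterns are enumerated
#' exactly (for up to 16 covariates) with their Bernoulli weights, and any
#' random-coefficient mixing is integrated by Halton-normal quadrature.
#' Used to calibrate constants and to test that simulated shares converge
#' to the model-implied probabilities.
#'
#' @param spec A [model_spec()].
#' @param params Named parameter vector.
#' @param covariates Covariate tibble (as in [sim_config()]).
#' @param n_nodes Quadrature draws per random dimension (default 200).
#' @return Named numeric vector of shares over the spec's levels, summing
#'   to 1.
#' @export
expected_shares <- function(spec, params, covariates, n_nodes = 200) {
  p <- nrow(covariates)
  if (p > 16) abort("Exact enumeration supported for at most 16 covariates.")
  grid <- as.matrix(expand.grid(rep(list(0:1), p)))
  colnames(grid) <- covariates$name
  w <- rep(1, nrow(grid))
  for (j in seq_len(p)) {
    pr <- covariates$prevalence[j]
    w <- w * ifelse(grid[, j] == 1, pr, 1 - pr)
  }
  X <- tibble::as_tibble(as.data.frame(grid))
  md <- build_model_data(spec, X, require_outcome = FALSE)
  dims <- n_random_dims(spec)
  draws <- if (dims > 0) {
    halton_draws(halton_config(n_draws = n_nodes), md$n, dims)
  }
  built <- build_utilities(align_params(params, md$template), md, draws)
  ue <- utility_exp(built$U, md$n, built$R)
  shares <- vapply(ue$E, function(e) {
    pk <- e / ue$denom
    if (!is.null(dim(pk))) pk <- rowMeans(pk)
    sum(w * pk)
  }, numeric(1))
  setNames(shares / sum(shares), spec$levels)
}

#' Calibrate level constants to target marginal severity shares
#'
#' Adjusts the constants (`"(Intercept)"` entries) of non-base levels so
#' that the population shares implied by [expected_shares()] match the
#' requested targets, by damped fixed-point iteration on the log share
#' ratios. Deterministic; no simulation involved.
#'
#' @param spec A [model_spec()] whose non-base levels each carry a constant.
#' @param params Named parameter vector (constants are overwritten).
#' @param covariates Covariate tibble.
#' @param targets Named shares over all levels (must sum to 1).
#' @param tol Convergence tolerance on max absolute share error.
#' @param max_iter Iteration cap.
#' @return The parameter vector with calibrated constants.
#' @export
calibrate_constants <- function(spec, params, covariates, targets,
                                tol = 1e-8, max_iter = 200) {
  stopifnot(abs(sum(targets) - 1) < 1e-8)
  targets <- targets[spec$levels]
  non_base <- setdiff(spec$levels, spec$base)
  const_names <- paste0(non_base, ":(Intercept)")
  if (!all(const_names %in% names(params))) {
    abort("Every non-base level needs an `(Intercept)` entry to calibrate.")
  }
  for (it in seq_len(max_iter)) {
    shares <- expected_shares(spec, params, covariates)
    if (max(abs(shares - targets)) < tol) break
    adj <- log(targets[non_base] / shares[non_base]) -
      log(targets[[spec$base]] / shares[[spec$base]])
    params[const_names] <- params[const_names] + adj
  }
  params
}

#' Study-scale synthetic crash configuration
#'
#' A ready-made configuration emulating the structure of a two-year,
#' multi-vehicle crash extract: roughly 13,000 crashes over the two years,
#' thirteen binary covariates in the four characteristic groups, heavy
#' class imbalance (about 68.3% PDO, 31.5% injury, 0.15% fatal), and one
#' random coefficient (an occupant-restraint indicator on the injury level)
#' whose mean shifts with a sudden-slowing indicator and whose variance
#' scales with a middle-aged-driver indicator. Constants are calibrated
#' deterministically so the population shares hit the imbalance targets.
#'
#' @param n_crashes Crashes per year (default 6500, i.e. 13,000 over two
#'   years).
#' @param seed Seed (default 1).
#' @param years Year labels (default 2017:2018); a named `shift` can be
#'   attached by editing the returned config.
#' @return A `sim_config`.
#' @export
preset_paper_like <- function(n_crashes = 6500, seed = 1L, years = 2017:2018) {
  covs <- dplyr::bind_rows(
    covariate_spec("male_driver", "driver", 0.5),
    covariate_spec("old_driver", "driver", 0.5),
    covariate_spec("middle_aged_driver", "driver", 0.5),
    covariate_spec("sudden_slowing", "driver", 0.5),
    covariate_spec("wet_surface", "roadway", 0.5),
    covariate_spec("rural_freeway", "roadway", 0.5),
    covariate_spec("straight_segment", "roadway", 0.5),
    covariate_spec("not_intersection", "crash", 0.5),
    covariate_spec("weekend", "crash", 0.5),
    covariate_spec("rear_end", "crash", 0.5),
    covariate_spec("occ_restraints", "occupant", 0.85),
    covariate_spec("male_occupant", "occupant", 0.5),
    covariate_spec("old_occupant", "occupant", 0.5)
  )
  spec <- model_spec(
    fixed = list(
      I = c("(Intercept)", "male_driver", "wet_surface", "not_intersection",
            "weekend", "rear_end", "old_occupant"),
      FI = c("(Intercept)", "rural_freeway", "old_driver", "sudden_slowing")
    ),
    random = list(
      random_term("occ_restraints", level = "I",
                  mean_shifters = "sudden_slowing",
                  var_shifters = "middle_aged_driver")
    )
  )
  params <- c(
    "I:(Intercept)" = 0,
    "I:male_driver" = -0.30,
    "I:wet_surface" = 0.40,
    "I:not_intersection" = -0.30,
    "I:weekend" = -0.20,
    "I:rear_end" = 1.50,
    "I:old_occupant" = 0.50,
    "FI:(Intercept)" = 0,
    "FI:rural_freeway" = 1.00,
    "FI:old_driver" = 0.60,
    "FI:sudden_slowing" = -0.80,
    "I:occ_restraints" = -1.50,
    "sd(I:occ_restraints)" = 1.00,
    "I:occ_restraints|mean:sudden_slowing" = -0.55,
    "I:occ_restraints|sd:middle_aged_driver" = -0.30
  )
  params <- calibrate_constants(
    spec, params, covs,
    targets = c(PDO = 0.683, I = 0.3155, FI = 0.0015)
  )
  sim_config(
    n_crashes = n_crashes, covariates = covs, spec = spec, params = params,
    seed = seed, years = lapply(years, function(y) list(year = y))
  )
}
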