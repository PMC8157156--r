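# Maximum-likelihood fitting of the severity logit models.

default_fit_control <- function(control = list()) {
  modifyList(
    list(maxit = 500L, reltol = 1e-12, grad_tol = 1e-5, start_sd = 0.1,
         restarts = 1L),
    control
  )
}

new_severity_fit <- function(md, theta, opt, halton, control) {
  grad <- loglik_engine(theta, md, attr(opt, "draws"), want_gradient = TRUE)$gradient
  gnorm <- max(abs(grad))
  H <- tryCatch(
    optimHess(theta, fn = attr(opt, "negll"), gr = attr(opt, "neggrad")),
    error = function(e) NULL
  )
  vcov <- se <- NULL
  if (!is.null(H)) {
    vcov <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vcov)) {
      d <- diag(vcov)
      se <- ifelse(d > 0, sqrt(d), NA_real_)
    }
  }
  theta <- setNames(theta, md$template$name)
  if (!is.null(se)) se <- setNames(se, md$template$name)
  boundary <- any(abs(theta) > 15)
  if (boundary) {
    warn("Coefficient(s) drifting unbounded (|estimate| > 15): likely perfect separation or an empty cell; estimates at the search boundary are unreliable.")
  }
  structure(
    list(
      spec = md$spec, template = md$template,
      theta = theta, se = se, vcov = vcov,
      loglik = -opt$value, n_obs = md$n,
      halton = halton,
      converged = opt$convergence == 0 && gnorm < control$grad_tol && !boundary,
      boundary = boundary,
      gradient_norm = gnorm,
      iterations = opt$counts[["function"]]
    ),
    class = "severity_fit"
  )
}

fit_engine <- function(md, theta0, draws, halton, control) {
  negll <- function(th) -loglik_engine(th, md, draws, want_gradient = FALSE)$loglik
  neggrad <- function(th) -loglik_engine(th, md, draws, want_gradient = TRUE)$gradient
  # BFGS, restarted (Hessian approximation reset) until the gradient
  # max-norm contract is met or the restart budget is exhausted.
  start <- theta0
  total_counts <- 0L
  for (round in seq_len(control$restarts + 1L)) {
    opt <- suppressWarnings(optim(
      start, fn = negll, gr = neggrad, method = "BFGS",
      control = list(maxit = control$maxit, reltol = control$reltol)
    ))
    total_counts <- total_counts + opt$counts[["function"]]
    if (max(abs(neggrad(opt$par))) < control$grad_tol) break
    start <- opt$par
  }
  # Newton polish: near the optimum the numerical Hessian (also used for the
  # standard errors) drives the gradient norm down quadratically where BFGS
  # line searches stall on round-off.
  for (step in 1:5) {
    g <- neggrad(opt$par)
    if (max(abs(g)) < control$grad_tol) break
    H <- tryCatch(optimHess(opt$par, fn = negll, gr = neggrad),
                  error = function(e) NULL)
    if (is.null(H)) break
    delta <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(delta)) break
    cand <- opt$par - delta
    if (!is.finite(negll(cand)) || negll(cand) > opt$value + 1e-8) break
    opt$par <- cand
    opt$value <- negll(cand)
  }
  opt$counts[["function"]] <- total_counts
  attr(opt, "negll") <- negll
  attr(opt, "neggrad") <- neggrad
  attr(opt, "draws") <- draws
  fit <- new_severity_fit(md, opt$par, opt, halton, control)
  if (!fit$converged && fit$gradient_norm >= control$grad_tol) {
    warn(sprintf(
      "Fit did not meet the convergence contract (max |gradient| = %.2e); returning partial result.",
      fit$gradient_norm
    ))
  }
  fit
}

#' Fit a multinomial logit severity model
#'
#' Maximises the closed-form multinomial-logit log-likelihood for a
#' specification with no random coefficients, by BFGS with analytic
#' gradients. Standard errors come from the inverse observed information
#' (numerical Hessian at the optimum).
#'
#' @param data Crash data with a `severity` column and the spec's covariates.
#' @param spec A [model_spec()] with no random terms.
#' @param control Optional list overriding `maxit` (500), `reltol` (1e-12)
#'   and `grad_tol` (1e-5, the max-norm gradient threshold defining
#'   convergence).
#' @return A `severity_fit` object; see [tidy.severity_fit()] and
#'   [glance.severity_fit()].
#' @export
fit_mnl <- function(data, spec, control = list()) {
  if (n_random_dims(spec) > 0) abort("`spec` has random terms; use fit_rpl().")
  control <- default_fit_control(control)
  md <- build_model_data(spec, data)
  theta0 <- numeric(nrow(md$template))
  fit_engine(md, theta0, draws = NULL, halton = NULL, control = control)
}

# Spec with every random term demoted to a fixed coefficient; used for
# starting values.
as_mnl_spec <- function(spec) {
  fixed <- spec$fixed
  for (rt in spec$random) {
    fixed[[rt$level]] <- c(fixed[[rt$level]], rt$term)
  }
  model_spec(fixed = fixed, random = list(), levels = spec$levels, base = spec$base)
}

#' Fit a random-parameters logit with heterogeneity in means and variances
#'
#' Maximises the simulated log-likelihood over Halton draws. Each random
#' coefficient varies across crashes as \eqn{\beta = \bar\beta + \delta'Z +
#' \sigma\exp(\omega'W)\nu}, \eqn{\nu \sim N(0,1)}. Starting values for the
#' fixed coefficients and random means come from a multinomial-logit fit of
#' the same mean structure; standard deviations start at a small positive
#' value and all heterogeneity terms at zero. The sign of \eqn{\sigma} is
#' not identified, so it is estimated unconstrained and reported as its
#' absolute value by [tidy.severity_fit()]. A fitted \eqn{\sigma} collapsing
#' towards zero means the coefficient is effectively fixed.
#'
#' @inheritParams fit_mnl
#' @param spec A [model_spec()] with at least one random term.
#' @param halton A [halton_config()]; 500 draws by default.
#' @param start Optional named starting vector (defaults to the MNL warm
#'   start).
#' @return A `severity_fit` object with `loglik` the simulated log-likelihood
#'   at convergence.
#' @export
fit_rpl <- function(data, spec, halton = halton_config(), start = NULL,
                    control = list()) {
  if (n_random_dims(spec) == 0) abort("`spec` has no random terms; use fit_mnl().")
  control <- default_fit_control(control)
  md <- build_model_data(spec, data)
  draws <- halton_draws(halton, md$n, n_random_dims(spec))
  if (is.null(start)) {
    mnl <- fit_mnl(data, as_mnl_spec(spec), control = control)
    theta0 <- numeric(nrow(md$template))
    for (j in seq_len(nrow(md$template))) {
      row <- md$template[j, ]
      theta0[j] <- switch(row$kind,
        fixed = ,
        mean = unname(mnl$theta[paste0(row$level, ":", row$term)]),
        sd = control$start_sd,
        0
      )
    }
  } else {
    theta0 <- align_params(start, md$template)
  }
  fit <- fit_engine(md, theta0, draws = draws, halton = halton, control = control)
  sds <- fit$theta[fit$template$kind == "sd"]
  if (any(abs(sds) < 1e-4)) {
    inform("One or more random-coefficient standard deviations collapsed towards 0; the model effectively reduces to fixed coefficients there.")
  }
  fit
}

#' Evaluate a fitted model's log-likelihood on other data
#'
#' Computes the log-likelihood of `data` under the converged parameters of
#' `fit`, with no re-estimation — the transferred-parameter quantity used by
#' the temporal-stability likelihood-ratio tests. Draws are regenerated from
#' the fit's Halton configuration to match the new data's size, so
#' evaluating a fit on its own training data reproduces its
#' `loglik` exactly.
#'
#' @param data Crash data containing `severity` and the fit's covariates.
#' @param fit A `severity_fit`.
#' @return The log-likelihood (a single number).
#' @export
evaluate_fixed_params <- function(data, fit) {
  stopifnot(inherits(fit, "severity_fit"))
  md <- build_model_data(fit$spec, data)
  draws <- if (n_random_dims(fit$spec) > 0) {
    halton_draws(fit$halton, md$n, n_random_dims(fit$spec))
  }
  loglik_engine(unname(fit$theta), md, draws, want_gradient = FALSE)$loglik
}

#' Predict severity probabilities and labels
#'
#' Per-crash severity probabilities under a fitted model — closed-form for a
#' multinomial logit, averaged over the fit's Halton draws for a
#' random-parameters fit — and the implied classification: the level with
#' the highest probability, with ties broken toward the less severe level.
#'
#' @param data Crash data containing the fit's covariates (a `severity`
#'   column is not required).
#' @param fit A `severity_fit`.
#' @return A tibble with one probability column per severity level (rows sum
#'   to 1) and `.pred_class`, a factor over [severity_levels()].
#' @export
predict_severity <- function(data, fit) {
  stopifnot(inherits(fit, "severity_fit"))
  md <- build_model_data(fit$spec, data, require_outcome = FALSE)
  draws <- if (n_random_dims(fit$spec) > 0) {
    halton_draws(fit$halton, md$n, n_random_dims(fit$spec))
  }
  built <- build_utilities(unname(fit$theta), md, draws)
  ue <- utility_exp(built$U, md$n, built$R)
  probs <- lapply(ue$E, function(e) {
    p <- e / ue$denom
    if (is.null(dim(p))) p else rowMeans(p)
  })
  names(probs) <- fit$spec$levels
  out <- tibble::as_tibble(probs)
  pm <- as.matrix(out)[, severity_levels(), drop = FALSE]
  cls <- apply(pm, 1, which.max) # first maximum = least severe on ties
  out$.pred_class <- factor(severity_levels()[cls], levels = severity_levels())
  out
}

#' Share of a normal coefficient distribution below zero
#'
#' For a random coefficient distributed \eqn{N(\mu, s^2)}, the fraction of
#' crashes for which the realised coefficient is negative is
#' \eqn{\Phi(-\mu/s)}; the complement is the positive share. This is the
#' standard interpretation aid for random parameters: e.g. a coefficient
#' with mean −1.5017 and standard deviation 4.5840 is negative for 62.84% of
#' observations.
#'
#' @param mean Mean of the coefficient distribution.
#' @param sd Standard deviation (> 0).
#' @return The probability that the coefficient is below zero.
#' @export
#' @examples
#' share_negative(-1.5017, 4.5840)
share_negative <- function(mean, sd) {
  if (any(sd <= 0)) abort("`sd` must be positive.")
  pnorm(-mean / sd)
}

#' @export
print.severity_fit <- function(x, ...) {
  kind <- if (n_random_dims(x$spec) > 0) "Random-parameters logit" else "Multinomial logit"
  cat("<severity_fit> ", kind, "\n", sep = "")
  cat("  n =", x$n_obs, "| log-likelihood =", format(x$loglik, digits = 8),
      "| converged:", x$converged, "\n")
  if (!is.null(x$halton)) {
    cat("  Halton draws:", x$halton$n_draws, "(burn", x$halton$burn, ")\n")
  }
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a fitted severity model
#'
#' One row per estimated parameter, broom-style. Random-coefficient standard
#' deviations are reported as absolute values (their sign is not
#' identified).
#'
#' @param x A `severity_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `kind`, `level`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
tidy.severity_fit <- function(x, ...) {
  est <- unname(x$theta)
  sd_rows <- x$template$kind == "sd"
  est[sd_rows] <- abs(est[sd_rows])
  se <- if (is.null(x$se)) rep(NA_real_, length(est)) else unname(x$se)
  z <- est / se
  z[sd_rows] <- abs(unname(x$theta)[sd_rows]) / se[sd_rows]
  tibble::tibble(
    term = x$template$name,
    kind = x$template$kind,
    level = x$template$level,
    estimate = est,
    std.error = se,
    statistic = z,
    p.value = 2 * pnorm(-abs(z))
  )
}

#' Model-level summary of a fitted severity model
#'
#' @param x A `severity_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `AIC`, `BIC`, `n_obs`, `n_params`,
#'   `n_draws` (NA for a pure MNL), `converged`.
#' @export
glance.severity_fit <- function(x, ...) {
  p <- length(x$theta)
  tibble::tibble(
    logLik = x$loglik,
    AIC = -2 * x$loglik + 2 * p,
    BIC = -2 * x$loglik + log(x$n_obs) * p,
    n_obs = x$n_obs,
    n_params = p,
    n_draws = if (is.null(x$halton)) NA_integer_ else x$halton$n_draws,
    converged = x$converged
  )
}

#' @export
logLik.severity_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$theta),
            nobs = object$n_obs, class = "logLik")
}
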