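# Simulated and closed-form likelihood machinery for the severity logit.
#
# The propensity of severity level k for crash i is V_ki = X_ki' beta_k + e_ki
# with iid Gumbel errors, giving multinomial-logit choice probabilities.
# Random coefficients follow beta = beta_bar + delta'Z + sigma exp(omega'W) nu,
# nu ~ N(0,1); the mixed-logit probability integrates the logit kernel over
# nu and is approximated by averaging over Halton draws.

# Probability floor applied to the simulated likelihood before taking logs.
.sim_prob_floor <- 1e-300

# Row-stable softmax over a list of K utility blocks, each either an
# n-vector (no draw variation) or an n x R matrix. Returns list(E = exp
# utilities net of rowwise max, denom).
utility_exp <- function(U, n, R) {
  M <- U[[1]]
  if (is.null(dim(M)) && R > 1) M <- matrix(M, n, R)
  for (k in seq_along(U)[-1]) M <- pmax(M, U[[k]])
  if (any(!is.finite(M))) abort("Non-finite propensity encountered; check parameters.")
  E <- lapply(U, function(u) exp(u - M))
  denom <- Reduce(`+`, E)
  list(E = E, denom = denom)
}

# Assemble the K utility blocks for parameters theta. `draws` is an
# n x R x dims array (dims = number of random terms) or NULL for a pure MNL.
build_utilities <- function(theta, md, draws) {
  p <- unpack_params(theta, md)
  n <- md$n
  K <- md$K
  U <- rep(list(rep(0, n)), K)
  fixed_theta <- p$fixed
  for (j in seq_along(md$fixed)) {
    f <- md$fixed[[j]]
    U[[f$level]] <- U[[f$level]] + fixed_theta[j] * f$x
  }
  R <- 1L
  beta_draws <- NULL
  if (length(md$random) > 0) {
    stopifnot(!is.null(draws))
    R <- dim(draws)[2]
    beta_draws <- vector("list", length(md$random))
    for (e in seq_along(md$random)) {
      re <- md$random[[e]]
      pe <- p$random[[e]]
      mu <- rep(pe$mean, n)
      if (!is.null(re$Z)) mu <- mu + drop(re$Z %*% pe$delta)
      ew <- rep(1, n)
      if (!is.null(re$W)) ew <- exp(drop(re$W %*% pe$omega))
      v <- draws[, , e]
      if (is.null(dim(v))) v <- matrix(v, n, R)
      beta <- mu + (pe$sd * ew) * v # n x R via column-wise recycling
      beta_draws[[e]] <- list(beta = beta, ew = ew, v = v)
      contrib <- re$x * beta
      if (is.null(dim(U[[re$level]]))) {
        U[[re$level]] <- matrix(U[[re$level]], n, R) + contrib
      } else {
        U[[re$level]] <- U[[re$level]] + contrib
      }
    }
  }
  list(U = U, R = R, params = p, beta_draws = beta_draws)
}

# Simulated log-likelihood with analytic gradient. Returns
# list(loglik, gradient, floored).
loglik_engine <- function(theta, md, draws, want_gradient = TRUE) {
  n <- md$n
  K <- md$K
  y <- md$y
  built <- build_utilities(theta, md, draws)
  R <- built$R
  ue <- utility_exp(built$U, n, R)
  E <- ue$E
  denom <- ue$denom
  scalar <- is.null(dim(denom))

  # P_chosen: probability of the observed level, per draw.
  if (scalar) {
    Pc <- rep(NA_real_, n)
    for (k in seq_len(K)) {
      idx <- y == k
      if (any(idx)) Pc[idx] <- E[[k]][idx] / denom[idx]
    }
    S <- Pc
  } else {
    Pc <- matrix(NA_real_, n, R)
    for (k in seq_len(K)) {
      idx <- which(y == k)
      if (length(idx)) {
        Ek <- E[[k]]
        if (is.null(dim(Ek))) Ek <- matrix(Ek, n, R)
        Pc[idx, ] <- Ek[idx, , drop = FALSE] / denom[idx, , drop = FALSE]
      }
    }
    S <- rowMeans(Pc)
  }
  floored <- S < .sim_prob_floor
  if (any(floored)) {
    warn(sprintf(
      "Simulated probability fell below %.0e for %d observation(s); floored.",
      .sim_prob_floor, sum(floored)
    ))
    S <- pmax(S, .sim_prob_floor)
  }
  ll <- sum(log(S))
  out <- list(loglik = ll, floored = any(floored))
  if (!want_gradient) return(out)

  # Weights w_ir = P_chosen(i,r) / (R * S_i); rowSums(w) == 1.
  if (scalar) {
    w <- Pc / S
    Pmat <- lapply(E, function(e) e / denom)
  } else {
    w <- Pc / (R * S)
    Pmat <- vector("list", K)
  }
  level_prob <- function(k) {
    if (scalar) return(Pmat[[k]])
    if (is.null(Pmat[[k]])) {
      Ek <- E[[k]]
      if (is.null(dim(Ek))) Ek <- matrix(Ek, n, R)
      Pmat[[k]] <<- Ek / denom
    }
    Pmat[[k]]
  }
  g <- numeric(nrow(md$template))
  pos <- 1L
  for (j in seq_along(md$fixed)) {
    f <- md$fixed[[j]]
    Pk <- level_prob(f$level)
    expected <- if (scalar) w * Pk else rowSums(w * Pk)
    g[pos] <- sum(f$x * ((y == f$level) - expected))
    pos <- pos + 1L
  }
  for (e in seq_along(md$random)) {
    re <- md$random[[e]]
    pe <- built$params$random[[e]]
    bd <- built$beta_draws[[e]]
    Pk <- level_prob(re$level)
    D <- (y == re$level) - Pk          # n-vector recycles down columns
    G <- w * D
    rs <- if (scalar) G else rowSums(G)
    rv <- if (scalar) G * bd$v else rowSums(G * bd$v)
    g[pos] <- sum(re$x * rs); pos <- pos + 1L              # mean
    g_sd <- sum(re$x * bd$ew * rv)                         # sd
    g[pos] <- g_sd; pos <- pos + 1L
    if (!is.null(re$Z)) {
      for (q in seq_len(ncol(re$Z))) {
        g[pos] <- sum(re$x * re$Z[, q] * rs); pos <- pos + 1L
      }
    }
    if (!is.null(re$W)) {
      for (q in seq_len(ncol(re$W))) {
        g[pos] <- sum(re$x * re$W[, q] * pe$sd * bd$ew * rv); pos <- pos + 1L
      }
    }
  }
  out$gradient <- g
  out
}

#' Multinomial-logit severity probabilities
#'
#' Closed-form choice probabilities for a specification with no random
#' coefficients: the softmax of the per-level linear propensities, computed
#' with row-wise max subtraction so that arbitrarily large predictors do not
#' overflow. The base level's propensity is identically zero.
#'
#' @param data Data frame with one row per crash containing the spec's
#'   covariates.
#' @param spec A [model_spec()] with no random terms.
#' @param params Named numeric vector of coefficients, one per row of
#'   `param_template(spec)` (names are matched; order is free).
#' @return A tibble with one probability column per severity level; rows sum
#'   to 1.
#' @export
#' @examples
#' spec <- model_spec(fixed = list(I = "(Intercept)", FI = "(Intercept)"))
#' mnl_probabilities(data.frame(x = 0), spec, c("I:(Intercept)" = 0, "FI:(Intercept)" = 0))
mnl_probabilities <- function(data, spec, params) {
  if (n_random_dims(spec) > 0) abort("`spec` must have no random terms; see predict_severity().")
  md <- build_model_data(spec, data, require_outcome = FALSE)
  theta <- align_params(params, md$template)
  built <- build_utilities(theta, md, draws = NULL)
  ue <- utility_exp(built$U, md$n, 1L)
  probs <- lapply(ue$E, function(e) e / ue$denom)
  names(probs) <- spec$levels
  tibble::as_tibble(probs)
}

# Match a named parameter vector against the template, erroring on missing
# or unknown names; unnamed vectors are taken in template order.
align_params <- function(params, tpl) {
  if (is.null(names(params)) || all(names(params) == "")) {
    if (length(params) != nrow(tpl)) {
      abort(sprintf("Expected %d parameters, got %d.", nrow(tpl), length(params)))
    }
    return(as.numeric(params))
  }
  missing <- setdiff(tpl$name, names(params))
  unknown <- setdiff(names(params), tpl$name)
  if (length(missing)) abort(paste0("Missing parameter(s): ", paste(missing, collapse = ", ")))
  if (length(unknown)) abort(paste0("Unknown parameter(s): ", paste(unknown, collapse = ", ")))
  as.numeric(params[tpl$name])
}

#' Simulated log-likelihood of a severity model
#'
#' Computes \eqn{\sum_i \log \frac{1}{R}\sum_r P_i(k_i \mid \beta_r)} where
#' the per-draw coefficients follow the heterogeneity-in-means-and-variances
#' structure \eqn{\beta_r = \bar\beta + \delta'Z + \sigma\exp(\omega'W)\nu_r}.
#' With no random terms (or all \eqn{\sigma = \delta = \omega = 0}) this
#' reduces exactly to the closed-form multinomial-logit log-likelihood.
#'
#' @param data Crash data with a `severity` column and the spec's covariates.
#' @param spec A [model_spec()].
#' @param params Named numeric parameter vector (see [param_template()]).
#' @param draws Either a [halton_config()] (draws are generated to match the
#'   data), a pre-built `n x R x dims` array, or `NULL` for a pure MNL spec.
#' @return The log-likelihood (a single number).
#' @export
simulated_loglik <- function(data, spec, params, draws = halton_config()) {
  md <- build_model_data(spec, data)
  theta <- align_params(params, md$template)
  dr <- resolve_draws(draws, md)
  loglik_engine(theta, md, dr, want_gradient = FALSE)$loglik
}

resolve_draws <- function(draws, md) {
  dims <- length(md$random)
  if (dims == 0) return(NULL)
  if (inherits(draws, "halton_config")) return(halton_draws(draws, md$n, dims))
  if (is.array(draws) && length(dim(draws)) == 3) {
    if (dim(draws)[1] != md$n || dim(draws)[3] != dims) {
      abort(sprintf(
        "Draw array is %d x %d x %d but the model needs n = %d, dims = %d.",
        dim(draws)[1], dim(draws)[2], dim(draws)[3], md$n, dims
      ))
    }
    return(draws)
  }
  abort("`draws` must be a halton_config or an n x n_draws x dims array.")
}
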