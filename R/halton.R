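#' Halton draw configuration
#'
#' Settings for the quasi-random draws used by simulated maximum likelihood.
#' One Halton sequence (one prime base) is used per random-coefficient
#' dimension; the raw uniform points are passed through the standard-normal
#' quantile function to obtain the mixing-distribution disturbances.
#'
#' @param n_draws Number of draws per observation (default 500, the count
#'   used for the headline model fits).
#' @param primes Prime bases, one per random dimension, in the order the
#'   random coefficients appear in the model specification. Defaults to the
#'   first ten primes.
#' @param burn Number of initial sequence points discarded (default 10);
#'   early Halton points are strongly patterned.
#' @param antithetic If `TRUE`, the second half of each observation's draws
#'   mirrors the first (`1 - u`); `n_draws` must then be even.
#' @return An object of class `halton_config`.
#' @export
#' @examples
#' halton_config(n_draws = 100)
halton_config <- function(n_draws = 500,
                          primes = c(2L, 3L, 5L, 7L, 11L, 13L, 17L, 19L, 23L, 29L),
                          burn = 10,
                          antithetic = FALSE) {
  stopifnot(n_draws >= 1, burn >= 0, length(primes) >= 1)
  if (anyDuplicated(primes)) abort("`primes` must be distinct.")
  if (antithetic && n_draws %% 2 != 0) {
    abort("`n_draws` must be even when `antithetic = TRUE`.")
  }
  structure(
    list(
      n_draws = as.integer(n_draws), primes = as.integer(primes),
      burn = as.integer(burn), antithetic = antithetic
    ),
    class = "halton_config"
  )
}

#' Halton radical-inverse sequence
#'
#' The `i`-th Halton point in base `b` reverses the base-`b` digits of `i`
#' about the radix point: index 1 in base 2 gives 1/2, index 2 gives 1/4,
#' index 3 gives 3/4, and so on. The sequence fills (0, 1) with low
#' discrepancy, so averages over it converge faster than over pseudo-random
#' uniforms.
#'
#' @param n Number of points.
#' @param base Prime base.
#' @param start Index of the first point (default 1; index 0 is the
#'   degenerate point 0 and is never emitted).
#' @return Numeric vector of `n` points in (0, 1).
#' @export
#' @examples
#' halton_sequence(4, base = 2) # 1/2, 1/4, 3/4, 1/8
halton_sequence <- function(n, base, start = 1L) {
  stopifnot(n >= 0, base >= 2, start >= 1)
  if (n == 0) return(numeric(0))
  idx <- seq.int(start, length.out = n)
  out <- numeric(n)
  f <- 1
  while (any(idx > 0)) {
    f <- f / base
    out <- out + f * (idx %% base)
    idx <- idx %/% base
  }
  out
}

#' Standard-normal Halton draws for simulated likelihood
#'
#' Generates the draw array consumed by [simulated_loglik()] and [fit_rpl()]:
#' for each random dimension, one long Halton sequence (after discarding
#' `burn` initial points) is chopped into blocks of `n_draws` per
#' observation and mapped through `qnorm()`. The result is fully
#' deterministic given the configuration — there is no pseudo-random state
#' anywhere in the draw path.
#'
#' @param config A [halton_config()].
#' @param n_obs Number of observations.
#' @param dims Number of random dimensions (must not exceed the number of
#'   primes in `config`).
#' @return A numeric array of dimension `n_obs` x `n_draws` x `dims`
#'   containing standard-normal variates.
#' @export
#' @examples
#' h <- halton_draws(halton_config(n_draws = 50), n_obs = 3, dims = 2)
#' dim(h)
halton_draws <- function(config, n_obs, dims) {
  stopifnot(inherits(config, "halton_config"), n_obs >= 1, dims >= 1)
  if (dims > length(config$primes)) {
    abort(sprintf(
      "Model has %d random dimensions but `config` supplies only %d primes.",
      dims, length(config$primes)
    ))
  }
  R <- config$n_draws
  out <- array(NA_real_, dim = c(n_obs, R, dims))
  per_dim <- if (config$antithetic) n_obs * R / 2 else n_obs * R
  for (d in seq_len(dims)) {
    u <- halton_sequence(per_dim, base = config$primes[d],
                         start = config$burn + 1L)
    if (config$antithetic) {
      m <- matrix(u, nrow = n_obs, ncol = R / 2, byrow = TRUE)
      m <- cbind(m, 1 - m)
    } else {
      m <- matrix(u, nrow = n_obs, ncol = R, byrow = TRUE)
    }
    out[, , d] <- qnorm(m)
  }
  out
}
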