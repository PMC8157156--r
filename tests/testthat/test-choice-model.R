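test_that("multinomial-logit probabilities match closed forms and stay stable", {
  spec <- model_spec(fixed = list(I = "(Intercept)", FI = "(Intercept)"))
  flat <- mnl_probabilities(data.frame(row = 1), spec,
                            c("I:(Intercept)" = 0, "FI:(Intercept)" = 0))
  expect_equal(unlist(flat), c(PDO = 1/3, I = 1/3, FI = 1/3))

  # predictors (0, ln 2, 0) -> (0.25, 0.5, 0.25)
  p <- mnl_probabilities(data.frame(row = 1), spec,
                         c("I:(Intercept)" = log(2), "FI:(Intercept)" = 0))
  expect_equal(unlist(p), c(PDO = 0.25, I = 0.5, FI = 0.25))

  # a huge predictor must not overflow
  big <- mnl_probabilities(data.frame(row = 1), spec,
                           c("I:(Intercept)" = 1000, "FI:(Intercept)" = 0))
  expect_true(all(is.finite(unlist(big))))
  expect_equal(big$I, 1, tolerance = 1e-12)
})

test_that("probability rows normalise to one and are shift-invariant", {
  set.seed(42)
  spec <- toy_mnl_spec()
  d <- simulate_crashes(toy_mnl_config(n = 50, seed = 13))
  for (rep in 1:10) {
    params <- setNames(rnorm(5, 0, 2), names(toy_mnl_params()))
    probs <- as.matrix(mnl_probabilities(d, spec, params))
    expect_true(all(abs(rowSums(probs) - 1) < 1e-10))
    expect_true(all(probs >= 0 & probs <= 1))
  }
  # adding a common constant to every level's propensity changes nothing
  md <- crashsev:::build_model_data(spec, d, require_outcome = FALSE)
  theta <- crashsev:::align_params(toy_mnl_params(), md$template)
  U <- crashsev:::build_utilities(theta, md, NULL)$U
  p1 <- crashsev:::utility_exp(U, md$n, 1L)
  U_shift <- lapply(U, function(u) u + 7.3)
  p2 <- crashsev:::utility_exp(U_shift, md$n, 1L)
  expect_equal(p1$E[[2]] / p1$denom, p2$E[[2]] / p2$denom, tolerance = 1e-12)
})

test_that("simulated log-likelihood degenerates exactly to the MNL form", {
  d <- simulate_crashes(toy_rpl_config(n = 200, seed = 14))
  spec <- toy_rpl_spec()
  params <- c("I:(Intercept)" = -0.3, "FI:(Intercept)" = -2.0,
              "I:x1" = -1.5, "sd(I:x1)" = 0)
  ll_sim <- simulated_loglik(d, spec, params, halton_config(n_draws = 25))
  mnl_params <- c("I:(Intercept)" = -0.3, "I:x1" = -1.5, "FI:(Intercept)" = -2.0)
  ll_mnl <- brute_force_mnl_loglik(d, as_mnl_spec(spec), mnl_params)
  expect_equal(ll_sim, ll_mnl, tolerance = 1e-12)

  # one crash, three levels, all parameters zero -> log(1/3)
  one <- d[1, ]
  expect_equal(
    simulated_loglik(one, spec,
                     c("I:(Intercept)" = 0, "FI:(Intercept)" = 0,
                       "I:x1" = 0, "sd(I:x1)" = 0),
                     halton_config(n_draws = 10)),
    log(1/3), tolerance = 1e-12
  )
})

test_that("simulated log-likelihood equals the brute-force draw average", {
  # 2 crashes, one random coefficient, 4 supplied draws: hand-average the
  # softmax probabilities over the draws with explicit loops.
  d <- tibble::tibble(severity = factor(c("I", "PDO"), levels = severity_levels()),
                      x1 = c(1, 1))
  spec <- toy_rpl_spec()
  params <- c("I:(Intercept)" = 0.2, "FI:(Intercept)" = -1.0,
              "I:x1" = -0.5, "sd(I:x1)" = 0.8)
  v <- matrix(c(-1.2, 0.3, 0.9, 2.0,
                -0.4, 0.0, 1.1, -2.2), nrow = 2, byrow = TRUE)
  draws <- array(v, dim = c(2, 4, 1))

  oracle <- 0
  for (i in 1:2) {
    probs <- numeric(4)
    for (r in 1:4) {
      beta <- params[["I:x1"]] + params[["sd(I:x1)"]] * v[i, r]
      u <- c(PDO = 0, I = params[["I:(Intercept)"]] + beta * d$x1[i],
             FI = params[["FI:(Intercept)"]])
      p <- exp(u) / sum(exp(u))
      probs[r] <- p[[as.character(d$severity[i])]]
    }
    oracle <- oracle + log(mean(probs))
  }
  expect_equal(simulated_loglik(d, spec, params, draws), oracle,
               tolerance = 1e-12)
})

test_that("MNL estimation recovers known parameters and closed-form intercepts", {
  cfg <- toy_mnl_config(n = 20000, seed = 15)
  d <- simulate_crashes(cfg)
  fit <- fit_mnl(d, cfg$spec)
  expect_true(fit$converged)
  z <- (fit$theta - cfg$params[names(fit$theta)]) / fit$se
  expect_true(all(abs(z) < 3))

  # intercept-only model: constants are the log share ratios vs the base
  ionly <- model_spec(fixed = list(I = "(Intercept)", FI = "(Intercept)"))
  fit0 <- fit_mnl(d, ionly)
  shares <- table(d$severity) / nrow(d)
  expect_equal(unname(fit0$theta["I:(Intercept)"]),
               log(shares[["I"]] / shares[["PDO"]]), tolerance = 1e-6)
  expect_equal(unname(fit0$theta["FI:(Intercept)"]),
               log(shares[["FI"]] / shares[["PDO"]]), tolerance = 1e-6)
})

test_that("perfect separation is flagged rather than silently accepted", {
  d <- tibble::tibble(
    severity = factor(rep(c("I", "PDO"), each = 30), levels = severity_levels()),
    x1 = rep(c(1, 0), each = 30)
  )
  spec <- model_spec(fixed = list(I = c("(Intercept)", "x1"),
                                  FI = "(Intercept)"))
  expect_warning(fit <- fit_mnl(d, spec), "separation|unbounded|converge")
  expect_false(fit$converged)
  expect_true(fit$boundary)
})

test_that("share_negative matches the normal CDF", {
  expect_equal(share_negative(-1.5017, 4.5840), pnorm(1.5017 / 4.5840))
  expect_equal(round(share_negative(-1.5017, 4.5840), 4), 0.6284)
  expect_equal(share_negative(0, 3.7), 0.5)
  expect_equal(share_negative(-1, 1), pnorm(1), tolerance = 1e-12)
  expect_equal(round(share_negative(-1, 1), 4), 0.8413)
  expect_error(share_negative(1, 0), "positive")
})

test_that("severity prediction uses argmax with ties toward the less severe", {
  spec <- model_spec(fixed = list(I = "(Intercept)", FI = "(Intercept)"))
  d <- tibble::tibble(row = 1:2)
  flat_fit <- structure(
    list(spec = spec, template = param_template(spec),
         theta = setNames(c(0, 0), param_template(spec)$name),
         halton = NULL),
    class = "severity_fit"
  )
  pred <- predict_severity(d, flat_fit)
  expect_true(all(pred$.pred_class == "PDO")) # exact three-way tie

  skewed <- structure(
    list(spec = spec, template = param_template(spec),
         theta = setNames(c(log(2), log(7)), param_template(spec)$name),
         halton = NULL),
    class = "severity_fit"
  )
  pred2 <- predict_severity(d, skewed)
  expect_true(all(pred2$.pred_class == "FI"))
  expect_equal(pred2$FI[1], 0.7)

  expect_true(all(abs(rowSums(as.matrix(pred2[, severity_levels()])) - 1) < 1e-10))
})

test_that("random-parameter recovery works at reduced scale", {
  cfg <- toy_rpl_config(n = 4000, seed = 16)
  d <- simulate_crashes(cfg)
  fit <- fit_rpl(d, cfg$spec, halton_config(n_draws = 150))
  td <- tidy(fit)
  truth <- cfg$params[td$term]
  truth[td$kind == "sd"] <- abs(truth[td$kind == "sd"])
  z <- (td$estimate - truth) / td$std.error
  expect_true(all(abs(z) < 3.5))
})

test_that("a zero-variance DGP collapses the mixed fit onto the MNL fit", {
  cfg <- toy_rpl_config(n = 2000, seed = 17, sd = 0)
  d <- simulate_crashes(cfg)
  mnl <- fit_mnl(d, as_mnl_spec(cfg$spec))
  rpl <- suppressMessages(fit_rpl(d, cfg$spec, halton_config(n_draws = 100)))
  expect_lt(abs(rpl$loglik - mnl$loglik), 0.5)
  expect_gte(rpl$loglik, mnl$loglik - 0.05) # MNL is nested in the mixture
})
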