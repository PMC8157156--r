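# Shared fixtures, built in code.

# Two-covariate MNL truth used across estimation tests.
toy_mnl_spec <- function() {
  model_spec(fixed = list(
    I = c("(Intercept)", "x1", "x2"),
    FI = c("(Intercept)", "x1")
  ))
}

toy_mnl_params <- function() {
  c("I:(Intercept)" = -0.5, "I:x1" = 0.8, "I:x2" = -0.4,
    "FI:(Intercept)" = -2.0, "FI:x1" = 0.6)
}

toy_mnl_config <- function(n = 2000, seed = 1) {
  covs <- dplyr::bind_rows(
    covariate_spec("x1", "driver", 0.5),
    covariate_spec("x2", "roadway", 0.5)
  )
  sim_config(n, covs, toy_mnl_spec(), toy_mnl_params(), seed = seed)
}

# One-random-coefficient truth for mixed-logit tests.
toy_rpl_spec <- function(mean_shifters = character(), var_shifters = character()) {
  model_spec(
    fixed = list(I = "(Intercept)", FI = "(Intercept)"),
    random = list(random_term("x1", level = "I",
                              mean_shifters = mean_shifters,
                              var_shifters = var_shifters))
  )
}

toy_rpl_config <- function(n = 2000, seed = 1, sd = 1.0) {
  covs <- dplyr::bind_rows(
    covariate_spec("x1", "occupant", 0.5),
    covariate_spec("z1", "driver", 0.5)
  )
  params <- c("I:(Intercept)" = -0.3, "FI:(Intercept)" = -2.0,
              "I:x1" = -1.5, "sd(I:x1)" = sd)
  sim_config(n, covs, toy_rpl_spec(), params, seed = seed)
}

# Independent brute-force log-likelihood for an MNL spec: explicit loops,
# no shared code with the package's engine.
brute_force_mnl_loglik <- function(data, spec, params) {
  lv <- spec$levels
  tpl <- param_template(spec)
  ll <- 0
  for (i in seq_len(nrow(data))) {
    v <- setNames(numeric(length(lv)), lv)
    for (j in seq_len(nrow(tpl))) {
      x <- if (tpl$term[j] == "(Intercept)") 1 else data[[tpl$term[j]]][i]
      v[tpl$level[j]] <- v[tpl$level[j]] + params[[tpl$name[j]]] * x
    }
    p <- exp(v) / sum(exp(v))
    ll <- ll + log(p[[as.character(data$severity[i])]])
  }
  ll
}
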