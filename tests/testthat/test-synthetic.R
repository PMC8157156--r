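test_that("null truth yields symmetric severity shares", {
  covs <- covariate_spec("x1", "driver", 0.5)
  spec <- model_spec(fixed = list(I = "(Intercept)", FI = "(Intercept)"))
  cfg <- sim_config(30000, covs, spec,
                    c("I:(Intercept)" = 0, "FI:(Intercept)" = 0), seed = 4)
  d <- simulate_crashes(cfg)
  shares <- as.numeric(table(d$severity)) / nrow(d)
  se <- sqrt((1/3) * (2/3) / nrow(d))
  expect_true(all(abs(shares - 1/3) < 3 * se))
})

test_that("a dominant constant captures essentially all crashes", {
  covs <- covariate_spec("x1", "driver", 0.5)
  spec <- model_spec(fixed = list(I = "(Intercept)", FI = "(Intercept)"))
  # +20 on both non-base levels relative to nothing: make the BASE dominant
  # by pushing the others far down instead.
  cfg <- sim_config(20000, covs, spec,
                    c("I:(Intercept)" = -20, "FI:(Intercept)" = -20), seed = 5)
  d <- simulate_crashes(cfg)
  expect_gt(mean(d$severity == "PDO"), 0.999)
})

test_that("empirical conditional shares converge to the closed-form logit", {
  # one binary covariate with coefficient 1.0 on level I only:
  # P(I | x = 1) = e / (2 + e)
  covs <- covariate_spec("x", "crash", 0.5)
  spec <- model_spec(fixed = list(I = c("(Intercept)", "x"),
                                  FI = "(Intercept)"))
  cfg <- sim_config(30000, covs, spec,
                    c("I:(Intercept)" = 0, "I:x" = 1, "FI:(Intercept)" = 0),
                    seed = 6)
  d <- simulate_crashes(cfg)
  target <- exp(1) / (2 + exp(1))
  sub <- d[d$x == 1, ]
  se <- sqrt(target * (1 - target) / nrow(sub))
  expect_lt(abs(mean(sub$severity == "I") - target), 3 * se)

  # and the analytic share calculator agrees with the closed form exactly
  shares_x1 <- mnl_probabilities(data.frame(x = 1), spec,
                                 c("I:(Intercept)" = 0, "I:x" = 1,
                                   "FI:(Intercept)" = 0))
  expect_equal(shares_x1$I, target, tolerance = 1e-12)
})

test_that("expected_shares matches enumeration and simulation for a fixed spec", {
  cfg <- toy_mnl_config(n = 20000, seed = 8)
  sh <- expected_shares(cfg$spec, cfg$params, cfg$covariates)
  expect_equal(sum(sh), 1, tolerance = 1e-12)
  d <- simulate_crashes(cfg)
  emp <- as.numeric(table(d$severity)) / nrow(d)
  se <- sqrt(sh * (1 - sh) / nrow(d))
  expect_true(all(abs(emp - sh) < 3.5 * se))
})

test_that("simulation is bit-reproducible given the seed", {
  cfg <- toy_rpl_config(n = 500, seed = 99)
  expect_identical(simulate_crashes(cfg), simulate_crashes(cfg))
  cfg2 <- toy_rpl_config(n = 500, seed = 100)
  expect_false(identical(simulate_crashes(cfg), simulate_crashes(cfg2)))
})

test_that("multi-year generation keeps years disjoint and perturbations visible", {
  covs <- covariate_spec("x", "crash", 0.5)
  spec <- model_spec(fixed = list(I = c("(Intercept)", "x"), FI = "(Intercept)"))
  params <- c("I:(Intercept)" = 0, "I:x" = 0, "FI:(Intercept)" = -1)

  base_cfg <- sim_config(1000, covs, spec, params, seed = 3,
                         years = list(list(year = 2017), list(year = 2018)))
  d <- simulate_crashes_years(base_cfg)
  expect_equal(nrow(d), 2000)
  expect_setequal(unique(d$year), c(2017, 2018))
  expect_identical(d, simulate_crashes_years(base_cfg))

  # +2 shift on I:x in year 2 moves P(I | x = 1) by a detectable margin
  shift_cfg <- sim_config(20000, covs, spec, params, seed = 3,
                          years = list(
                            list(year = 1),
                            list(year = 2, shift = c("I:x" = 2))
                          ))
  ds <- simulate_crashes_years(shift_cfg)
  p1 <- mean(ds$severity[ds$year == 1 & ds$x == 1] == "I")
  p2 <- mean(ds$severity[ds$year == 2 & ds$x == 1] == "I")
  se <- sqrt(p1 * (1 - p1) / 10000 + p2 * (1 - p2) / 10000)
  expect_gt(abs(p2 - p1), 3 * se)

  # adding a year never changes the first year's block
  expect_identical(
    ds[ds$year == 1, ],
    simulate_crashes_years(
      sim_config(20000, covs, spec, params, seed = 3,
                 years = list(list(year = 1), list(year = 99)))
    )[1:20000, ] |> dplyr::mutate(year = 1)
  )
})

test_that("config validation rejects bad years and parameters", {
  covs <- covariate_spec("x", "crash", 0.5)
  spec <- model_spec(fixed = list(I = "(Intercept)", FI = "(Intercept)"))
  params <- c("I:(Intercept)" = 0, "FI:(Intercept)" = 0)
  expect_error(
    sim_config(10, covs, spec, params,
               years = list(list(year = 1), list(year = 1))),
    "Duplicate year"
  )
  expect_error(
    sim_config(10, covs, spec, params,
               years = list(list(year = 1), list(year = 2, shift = c(nope = 1)))),
    "unknown parameter"
  )
  expect_error(covariate_spec("x", "driver", 1.3), "prevalence")
})

test_that("extreme parameters surface as an invalid-config error", {
  covs <- covariate_spec("x", "crash", 0.5)
  spec <- model_spec(fixed = list(I = "(Intercept)", FI = "(Intercept)"))
  cfg <- sim_config(50, covs, spec,
                    c("I:(Intercept)" = 1e309, "FI:(Intercept)" = 0), seed = 1)
  expect_error(simulate_crashes(cfg), "propensity|parameters")
})

test_that("the study-scale preset reproduces the class-imbalance structure", {
  cfg <- preset_paper_like(n_crashes = 6500, seed = 21)
  sh <- expected_shares(cfg$spec, cfg$params, cfg$covariates)
  expect_equal(unname(sh), c(0.683, 0.3155, 0.0015), tolerance = 1e-6)
  d <- simulate_crashes_years(cfg)
  expect_equal(nrow(d), 13000)
  emp <- as.numeric(table(d$severity)) / nrow(d)
  se <- sqrt(sh * (1 - sh) / nrow(d))
  expect_true(all(abs(emp - sh) < 3 * pmax(se, 1e-4)))
})

test_that("crash CSV round-trips losslessly and validates on read", {
  cfg <- toy_mnl_config(n = 10, seed = 2)
  d <- simulate_crashes(cfg, year = 2017)
  path <- withr::local_tempfile(fileext = ".csv")
  write_crash_csv(d, path)
  back <- read_crash_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(d))

  # missing severity column
  no_sev <- d[, setdiff(names(d), "severity")]
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(no_sev, path2)
  expect_error(read_crash_csv(path2), "severity")

  # unknown code names the accepted set
  bad <- d
  bad$severity <- as.character(bad$severity)
  bad$severity[1] <- "K"
  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, path3)
  expect_error(read_crash_csv(path3), "PDO, I, FI")
})
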