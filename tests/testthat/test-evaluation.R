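test_that("confusion matrices tabulate actual rows against predicted columns", {
  cm <- confusion_matrix(c("PDO", "I", "FI"), c("PDO", "I", "FI"))
  expect_equal(unclass(cm), diag(3L), ignore_attr = TRUE)
  expect_equal(overall_accuracy(cm), 1)

  cm2 <- confusion_matrix(c("PDO", "I"), c("I", "I"))
  expect_equal(cm2["PDO", "I"], 1L)
  expect_equal(cm2["I", "I"], 1L)
  expect_equal(sum(cm2), 2L)

  empty <- confusion_matrix(character(0), character(0))
  expect_true(all(empty == 0L))
  expect_error(overall_accuracy(empty), "empty")

  expect_error(confusion_matrix("PDO", c("PDO", "I")), "equal length")
  expect_error(confusion_matrix("K", "PDO"), "Unknown severity")
})

test_that("published confusion counts reproduce the printed row ratios", {
  rpl <- published_confusion("rpl")
  expect_equal(rowSums(rpl), c(PDO = 2802, I = 1293, FI = 6))
  expect_equal(overall_accuracy(rpl), 2321 / 4101)
  ratios <- confusion_ratios(rpl)
  expect_equal(round(ratios$ratio[ratios$actual == "PDO" & ratios$predicted == "PDO"], 4),
               0.6713)
  expect_equal(round(ratios$ratio[ratios$actual == "I" & ratios$predicted == "I"], 4),
               0.3403)
  rf <- published_confusion("rf")
  expect_lt(abs(confusion_ratios(rf)$ratio[1] - 0.8514), 1e-4)
  expect_true(all(is.na(confusion_ratios(rf)$ratio[confusion_ratios(rf)$actual == "FI"])))
})

test_that("comprehensive costs are the economic plus QALY components", {
  expect_equal(comprehensive_cost(46132, 97535), 143667)
  expect_equal(comprehensive_cost(588738, 3173900), 3762638)
  expect_equal(comprehensive_cost(12456, 0), 12456)
  expect_error(comprehensive_cost(-1, 0), "nonnegative")
  tbl <- cost_table_2017()
  expect_equal(tbl$comprehensive_cost, c(12456, 143667, 3762638))
})

test_that("actual and predicted overall costs follow the row/column totals", {
  rpl <- published_confusion("rpl")
  expect_equal(aocc(rpl), 243238971)
  expect_equal(pocc(rpl), 252030108)

  # diagonal matrix: column totals equal row totals, so AOCC == POCC
  diag_cm <- confusion_from_counts(diag(c(5, 3, 2)))
  expect_equal(aocc(diag_cm), pocc(diag_cm))
})

test_that("cost-error indicators reproduce the published percentages", {
  rpl_err <- cost_errors(published_confusion("rpl"))
  expect_equal(round(rpl_err$opape, 4), 0.0361)
  expect_equal(trunc(rpl_err$opmae), 2143)
  expect_equal(round(rpl_err$oprmse / 1e3), 137)

  rf_err <- cost_errors(published_confusion("rf"))
  expect_equal(round(rf_err$opape, 4), 0.2712)
  expect_equal(trunc(rf_err$opmae), 14076)
  expect_equal(round(rf_err$oprmse / 1e3), 895)

  perfect <- confusion_from_counts(diag(c(10, 5, 1)))
  perr <- cost_errors(perfect)
  expect_equal(perr$opmae, 0)
  expect_equal(perr$opape, 0)
  expect_equal(perr$oprmse, 0)
})

test_that("cost identities and scale invariance hold on randomised matrices", {
  set.seed(77)
  for (rep in 1:25) {
    m <- matrix(rpois(9, lambda = 40), 3, 3)
    if (sum(diag(m)) == sum(m)) m[1, 2] <- m[1, 2] + 1
    cm <- confusion_from_counts(m)
    err <- cost_errors(cm)
    gap <- abs(aocc(cm) - pocc(cm))
    expect_equal(err$opmae * err$n, gap, tolerance = 1e-9)
    expect_equal(err$oprmse * sqrt(err$n), gap, tolerance = 1e-9)

    # multiplying all unit costs by c scales the USD indicators, not OPAPE
    scaled <- cost_table(economic = cost_table_2017()$economic_cost * 3.5,
                         qaly = cost_table_2017()$qaly_cost * 3.5)
    err_s <- cost_errors(cm, scaled)
    expect_equal(err_s$opape, err$opape, tolerance = 1e-12)
    expect_equal(err_s$opmae, err$opmae * 3.5, tolerance = 1e-9)
    expect_equal(err_s$oprmse, err$oprmse * 3.5, tolerance = 1e-9)
    expect_equal(err_s$aocc, err$aocc * 3.5, tolerance = 1e-9)

    # the indicators are functions of the matrix alone: permuting the
    # underlying prediction list cannot change them (counts fixed)
    expect_equal(aocc(cm), sum(rowSums(cm) * cost_table_2017()$comprehensive_cost))
  }
})

test_that("evaluation reports and model comparison mirror the printed layout", {
  rpl_rep <- evaluation_report(published_confusion("rpl"), model = "rpl")
  rf_rep <- evaluation_report(published_confusion("rf"), model = "rf")
  expect_equal(rpl_rep$r_PDO, 1881 / 2802)
  expect_equal(rpl_rep$n, 4101L)

  cmp <- compare_models(list(rpl_rep, rf_rep), style = "printed")
  get <- function(ind, col) cmp[[col]][cmp$indicator == ind]
  expect_equal(get("opape", "rpl"), "3.61%")
  expect_equal(get("opape", "rf"), "27.12%")
  expect_equal(get("opmae", "rpl"), "2,143")
  expect_equal(get("opmae", "rf"), "14,076")
  expect_equal(get("oprmse_thousand_usd", "rpl"), "137")
  expect_equal(get("oprmse_thousand_usd", "rf"), "895")
  expect_equal(get("pocc_million_usd", "rpl"), "252")
  expect_equal(get("pocc_million_usd", "rf"), "153")
  expect_equal(get("aocc_million_usd", "rpl"), "243")
  expect_equal(get("aocc_million_usd", "rf"), "209")

  # the qualitative comparison: the logit wins on cost error, the forest on
  # raw accuracy
  expect_lt(rpl_rep$opape, rf_rep$opape)
  expect_gt(rf_rep$r_overall, rpl_rep$r_overall)

  # identical inputs give identical columns
  twin <- evaluation_report(published_confusion("rpl"), model = "twin")
  cmp2 <- compare_models(list(rpl_rep, twin), style = "full")
  expect_equal(cmp2$rpl, cmp2$twin)

  # serialisation round trip
  json <- jsonlite::toJSON(as.list(rpl_rep[, -1]), auto_unbox = TRUE, digits = NA)
  back <- jsonlite::fromJSON(json)
  expect_equal(back$opape, rpl_rep$opape)
  expect_equal(back$aocc, rpl_rep$aocc)

  p <- autoplot(published_confusion("rpl"))
  expect_s3_class(p, "ggplot")
})
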