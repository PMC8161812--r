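test_that("expected arm cost is cost_bta + p * cost_sse", {
  expect_equal(expected_arm_cost(arm_parameters("FOUR_WEEKLY", 0.203,
                                                5642.07, 16369.25)),
               5642.07 + 0.203 * 16369.25)
  expect_equal(expected_arm_cost(arm_parameters("TWELVE_WEEKLY", 0.223,
                                                1826.73, 17234.19)),
               1826.73 + 0.223 * 17234.19)
  expect_equal(expected_arm_cost(arm_parameters("FOUR_WEEKLY", 0,
                                                1234.5, 99999)),
               1234.5)
})

test_that("expected arm QALY is the probability-weighted branch mean", {
  expect_equal(expected_arm_qaly(0.5, 0.4, 0.8), 0.6)
  expect_equal(expected_arm_qaly(0, 0.123, 0.9), 0.9)
  # calibrated branches reproduce the arm mean by construction
  tr <- small_trial()
  cal <- calibrate_branch_qalys(tr)
  for (a in c("arm_4wk", "arm_12wk")) {
    expect_equal(expected_arm_qaly(cal[[a]]$p_hat, cal[[a]]$qaly_sse,
                                   cal[[a]]$qaly_no_sse),
                 cal[[a]]$mean_qaly)
  }
})

test_that("comparison classifies dominance and computes INB by definition", {
  res <- compare_strategies(base_inputs(),
                            c(arm_4wk = 0.605, arm_12wk = 0.612))
  expect_lt(res$delta_cost, 0)
  expect_gt(res$delta_qaly, 0)
  expect_equal(res$icer_class, "DOMINANT")
  expect_true(is.na(res$icer))
  expect_equal(res$inb, res$wtp * res$delta_qaly - res$delta_cost)
  expect_equal(res$delta_cost,
               res$strategies$expected_cost[2] -
                 res$strategies$expected_cost[1])

  # identical arms: all deltas zero
  a <- arm_parameters("FOUR_WEEKLY", 0.2, 1000, 5000)
  b <- arm_parameters("TWELVE_WEEKLY", 0.2, 1000, 5000)
  eq <- compare_strategies(model_inputs(a, b, 1), c(0.6, 0.6))
  expect_equal(eq$delta_cost, 0)
  expect_equal(eq$delta_qaly, 0)
  expect_equal(eq$inb, 0)
  expect_equal(eq$icer_class, "EQUIVALENT")

  # equal QALYs with a cost difference avoids an infinite ICER
  b2 <- arm_parameters("TWELVE_WEEKLY", 0.2, 900, 5000)
  co <- compare_strategies(model_inputs(a, b2, 1), c(0.6, 0.6))
  expect_equal(co$icer_class, "COST_ONLY")
  expect_true(is.na(co$icer))
})

test_that("INB matches hand arithmetic for a rounded-delta scenario", {
  # Delta cost -3293.75, delta QALY 0.008, lambda 50000 -> INB 3693.75
  a <- arm_parameters("FOUR_WEEKLY", 0, 5000, 0)
  b <- arm_parameters("TWELVE_WEEKLY", 0, 5000 - 3293.75, 0)
  res <- compare_strategies(model_inputs(a, b, 1, wtp = 50000),
                            c(arm_4wk = 0.605, arm_12wk = 0.613))
  expect_equal(res$delta_cost, -3293.75)
  expect_equal(res$delta_qaly, 0.008)
  expect_equal(res$inb, 3693.75)
})

test_that("swapping strategy labels negates the incremental quantities", {
  inputs <- base_inputs()
  res <- compare_strategies(inputs, c(arm_4wk = 0.605, arm_12wk = 0.612))
  swapped_inputs <- model_inputs(
    arm_parameters("FOUR_WEEKLY", inputs$arm_12wk$p_sse,
                   inputs$arm_12wk$cost_bta, inputs$arm_12wk$cost_sse),
    arm_parameters("TWELVE_WEEKLY", inputs$arm_4wk$p_sse,
                   inputs$arm_4wk$cost_bta, inputs$arm_4wk$cost_sse),
    inputs$relative_risk, wtp = inputs$wtp)
  swapped <- compare_strategies(swapped_inputs,
                                c(arm_4wk = 0.612, arm_12wk = 0.605))
  expect_equal(swapped$delta_cost, -res$delta_cost)
  expect_equal(swapped$delta_qaly, -res$delta_qaly)
  expect_equal(swapped$inb, -res$inb)
  expect_equal(swapped$icer_class, "DOMINATED")
})

test_that("DOMINANT implies positive INB at every non-negative WTP", {
  for (wtp in c(0, 1000, 50000, 1e6)) {
    res <- compare_strategies(base_inputs(wtp = wtp),
                              c(arm_4wk = 0.605, arm_12wk = 0.612))
    expect_equal(res$icer_class, "DOMINANT")
    expect_gt(res$inb, 0)
  }
})

test_that("closed-form expectations agree with the branch-lottery simulation", {
  inputs <- base_inputs()
  branches <- list(arm_4wk = list(qaly_sse = 0.55, qaly_no_sse = 0.62),
                   arm_12wk = list(qaly_sse = 0.56, qaly_no_sse = 0.63))
  sim <- simulate_tree_lottery(inputs, branches, n_draws = 1e5, seed = 9)
  for (i in 1:2) {
    arm <- list(inputs$arm_4wk, inputs$arm_12wk)[[i]]
    br <- branches[[i]]
    expect_lt(abs(sim$mean_cost[i] - expected_arm_cost(arm)),
              3 * sim$se_cost[i])
    expect_lt(abs(sim$mean_qaly[i] -
                    expected_arm_qaly(arm$p_sse, br$qaly_sse,
                                      br$qaly_no_sse)),
              3 * sim$se_qaly[i])
  }
})

test_that("the published results table shape is emitted with rounded display", {
  res <- compare_strategies(base_inputs(),
                            c(arm_4wk = 0.605, arm_12wk = 0.612))
  tab <- as.data.frame(res)
  expect_equal(tab$cost[1], "8965.03")
  expect_equal(tab$cost[2], "5669.95")
  expect_match(tab$qaly[4], "dominates")
  path <- tempfile(fileext = ".json")
  write_ce_result(res, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$delta_cost, res$delta_cost)
  expect_equal(back$icer_class, "DOMINANT")
})
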