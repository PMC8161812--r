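test_that("normal and lognormal fits follow the closed forms", {
  d <- fit_distribution(list(name = "p", baseline = 0.203,
                             lower = 0.1338, upper = 0.2954), "NORMAL")
  expect_equal(d$params[["mean"]], 0.203)
  expect_equal(d$params[["sd"]], 0.04122, tolerance = 1e-3)

  sym <- fit_distribution(list(name = "x", baseline = 1,
                               lower = 0.5, upper = 1.5), "NORMAL")
  expect_equal(sym$params[["mean"]], 1)
  expect_equal(sym$params[["sd"]], 0.2551, tolerance = 1e-3)

  ln <- fit_distribution(list(name = "rr", baseline = 1.099,
                              lower = 0.6902, upper = 1.7496),
                         "LOGNORMAL")
  expect_equal(qlnorm(c(0.025, 0.975), ln$params[["meanlog"]],
                      ln$params[["sdlog"]]),
               c(0.6902, 1.7496), tolerance = 1e-10)
})

test_that("beta and gamma CI-matching recovers the stated limits", {
  b <- fit_distribution(list(name = "p", baseline = 0.203,
                             lower = 0.1338, upper = 0.2954), "BETA")
  q <- qbeta(c(0.025, 0.975), b$params[["shape1"]], b$params[["shape2"]])
  expect_equal(q, c(0.1338, 0.2954), tolerance = 1e-4 / 0.2954)

  g <- fit_distribution(list(name = "c", baseline = 5642.07,
                             lower = 4513.66, upper = 6770.48), "GAMMA")
  qg <- qgamma(c(0.025, 0.975), shape = g$params[["shape"]],
               scale = g$params[["scale"]])
  expect_equal(qg, c(4513.66, 6770.48), tolerance = 1e-8)
  # near-symmetric interval: the fitted mean recovers the baseline
  expect_equal(g$params[["shape"]] * g$params[["scale"]], 5642.07,
               tolerance = 0.01)

  expect_error(fit_distribution(list(name = "p", baseline = 1.5,
                                     lower = 1.2, upper = 1.8), "BETA"),
               "inside \\(0, 1\\)")
})

test_that("degenerate ranges collapse to point masses in any family", {
  d <- fit_distribution(list(name = "x", baseline = 3, lower = 3,
                             upper = 3))
  expect_equal(d$family, "POINT")
  expect_equal(dist_sample(d, 5), rep(3, 5))
})

test_that("one-way analysis with degenerate ranges gives zero-width bars", {
  inputs <- base_inputs()
  ranges <- data.frame(
    name = c("p_sse_4wk", "cost_bta_4wk", "qaly_no_sse_12wk"),
    baseline = c(0.203, 5642.07, 0.62),
    lower = c(0.203, 5642.07, 0.62),
    upper = c(0.203, 5642.07, 0.62))
  tor <- one_way_dsa(inputs, ranges,
                     c(arm_4wk = 0.605, arm_12wk = 0.612))
  expect_true(all(tor$width == 0))
})

test_that("relative-risk endpoints match hand evaluations of the tree", {
  inputs <- base_inputs()
  branches <- list(arm_4wk = list(qaly_sse = 0.56, qaly_no_sse = 0.615),
                   arm_12wk = list(qaly_sse = 0.57, qaly_no_sse = 0.625))
  ranges <- data.frame(name = "relative_risk", baseline = 1.099,
                       lower = 0.6902, upper = 1.7496)
  tor <- one_way_dsa(inputs, ranges, branches)
  hand <- function(rr) {
    p12 <- 0.203 * rr
    c4 <- 5642.07 + 0.203 * 16369.25
    c12 <- 1826.73 + p12 * 17234.19
    e4 <- 0.203 * 0.56 + 0.797 * 0.615
    e12 <- p12 * 0.57 + (1 - p12) * 0.625
    50000 * (e12 - e4) - (c12 - c4)
  }
  expect_equal(tor$low_outcome, hand(0.6902))
  expect_equal(tor$high_outcome, hand(1.7496))
})

test_that("tornado ordering is by width and invariant to input order", {
  inputs <- base_inputs()
  tr <- small_trial(seed = 12)
  cal <- calibrate_branch_qalys(tr)
  ranges <- default_dsa_ranges(inputs, cal)
  br <- branches_from_calibration(cal)
  tor <- one_way_dsa(inputs, ranges, br)
  expect_true(all(diff(tor$width) <= 0))
  set.seed(4)
  tor2 <- one_way_dsa(inputs, ranges[sample(nrow(ranges)), ], br)
  expect_equal(tor$parameter, tor2$parameter)
  expect_equal(tor$width, tor2$width)
  expect_error(one_way_dsa(inputs,
                           data.frame(name = "nope", baseline = 1,
                                      lower = 0, upper = 2), br),
               "unknown model parameter")
})

test_that("PSA draws are seed-reproducible and mean-consistent", {
  inputs <- base_inputs()
  tr <- small_trial(seed = 21)
  cal <- calibrate_branch_qalys(tr)
  dists <- default_psa_distributions(inputs, cal)
  p1 <- run_psa(inputs, dists, n_sims = 5000, seed = 99)
  p2 <- run_psa(inputs, dists, n_sims = 5000, seed = 99)
  expect_identical(p1, p2)

  # law of large numbers on the beta-distributed probability
  b <- dists$p_sse_4wk$params
  se <- sqrt(b[["shape1"]] * b[["shape2"]] /
               ((b[["shape1"]] + b[["shape2"]])^2 *
                  (b[["shape1"]] + b[["shape2"]] + 1))) / sqrt(5000)
  mean_fit <- b[["shape1"]] / (b[["shape1"]] + b[["shape2"]])
  expect_lt(abs(mean(p1$p_sse_4wk) - mean_fit), 3 * se)
  # no negative costs can be sampled under gamma families
  expect_true(all(p1[, grep("^cost", names(p1))] >= 0))
})

test_that("degenerate distributions reproduce the base-case deltas in every draw", {
  inputs <- base_inputs(p12_mode = "VIA_RR")
  branches <- list(arm_4wk = list(qaly_sse = 0.56, qaly_no_sse = 0.615),
                   arm_12wk = list(qaly_sse = 0.57, qaly_no_sse = 0.625))
  dists <- point_distributions(inputs, branches)
  psa <- run_psa(inputs, dists, n_sims = 50, seed = 1)
  base <- compare_strategies(inputs, branches)
  expect_equal(psa$delta_cost, rep(base$delta_cost, 50))
  expect_equal(psa$delta_qaly, rep(base$delta_qaly, 50))
})

test_that("CEAC follows its definition and is a step function when degenerate", {
  inputs <- base_inputs()
  tr <- small_trial(seed = 31)
  cal <- calibrate_branch_qalys(tr)
  dists <- default_psa_distributions(inputs, cal)
  psa <- run_psa(inputs, dists, n_sims = 2000, seed = 5)
  grid <- c(0, 25000, 50000, 100000)
  cc <- ceac(psa, grid)
  expect_true(all(cc$prob_cost_effective >= 0 &
                    cc$prob_cost_effective <= 1))
  expect_equal(cc$prob_cost_effective[1], mean(psa$delta_cost < 0))
  # large-WTP limit: fraction of draws gaining QALYs
  far <- ceac(psa, 1e12)$prob_cost_effective
  expect_equal(far, mean(psa$delta_qaly > 0))

  # degenerate distributions with positive deltas: step at dC/dE
  a <- arm_parameters("FOUR_WEEKLY", 0.2, 1000, 5000)
  b <- arm_parameters("TWELVE_WEEKLY", 0.2, 3000, 5000)
  ins <- model_inputs(a, b, 1)
  branches <- list(arm_4wk = list(qaly_sse = 0.55, qaly_no_sse = 0.60),
                   arm_12wk = list(qaly_sse = 0.56, qaly_no_sse = 0.61))
  dpsa <- run_psa(ins, point_distributions(ins, branches),
                  n_sims = 10, seed = 2)
  lam_star <- dpsa$delta_cost[1] / dpsa$delta_qaly[1]
  step <- ceac(dpsa, c(lam_star * 0.99, lam_star, lam_star * 1.01))
  expect_equal(step$prob_cost_effective, c(0, 0, 1))

  expect_error(ceac(psa, numeric(0)), "empty")
})
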