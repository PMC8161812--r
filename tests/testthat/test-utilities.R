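test_that("mapping anchors: best and worst responses hit levels 1 and 4", {
  st_best <- map_qlq_to_c10d(c(rep(1, 28), 7, 7))
  expect_true(all(unclass(st_best) == 1L))
  expect_equal(utility(st_best), 1.0)

  st_worst <- map_qlq_to_c10d(c(rep(4, 28), 1, 1))
  expect_true(all(unclass(st_worst) == 4L))
  vs <- fixture_valueset()
  expect_equal(utility(st_worst, vs), 1 - sum(vs$decrements[, 4]))
})

test_that("a mixed response maps by the shipped table (worst item per dimension)", {
  items <- rep(1, 30)
  items[c(29, 30)] <- 7
  items[2] <- 2; items[3] <- 3    # physical -> 3
  items[26] <- 4                  # social -> 4
  items[24] <- 2                  # emotional -> 2
  items[19] <- 2                  # pain (q9 = 1, q19 = 2) -> 2
  items[18] <- 3                  # fatigue -> 3
  items[11] <- 4                  # sleep -> 4
  items[14] <- 2                  # nausea -> 2
  items[16] <- 3                  # bowel (q16 = 3, q17 = 1) -> 3
  st <- map_qlq_to_c10d(items)
  expect_equal(unname(unclass(st)),
               c(3L, 1L, 4L, 2L, 2L, 3L, 4L, 1L, 2L, 3L))
  # hand sum over the fixture value set:
  # physical L3 .12 + social L4 .10 + emotional L2 .03 + pain L2 .045 +
  # fatigue L3 .055 + sleep L4 .06 + nausea L2 .02 + bowel L3 .035
  expect_equal(utility(st, fixture_valueset()), 1 - 0.465)
})

test_that("missing items fall back to the worst present item, or a missing state", {
  items <- rep(1, 30)
  items[2] <- NA; items[3] <- 3
  expect_equal(unclass(map_qlq_to_c10d(items))[["physical"]], 3L)
  items[3] <- NA
  expect_true(is.na(unclass(map_qlq_to_c10d(items))[["physical"]]))
})

test_that("utility never increases when any single item worsens", {
  vs <- fixture_valueset()
  mp <- fixture_mapping()
  set.seed(42)
  for (rep in 1:25) {
    items <- c(sample(1:4, 28, replace = TRUE), sample(1:7, 2, TRUE))
    u0 <- utility(map_qlq_to_c10d(items, mp), vs)
    for (it in mp$c30_item) {
      if (items[it] < 4) {
        worse <- items
        worse[it] <- worse[it] + 1
        u1 <- utility(map_qlq_to_c10d(worse, mp), vs)
        expect_lte(u1, u0)
      }
    }
  }
})

test_that("QALY is the trapezoidal area with weeks converted to years", {
  expect_equal(qaly(data.frame(visit_week = c(0, 48), utility = c(1, 1))),
               48 / 52.1775)
  expect_equal(qaly(data.frame(visit_week = c(0, 48), utility = c(0, 0))),
               0)
  expect_equal(qaly(data.frame(visit_week = c(0, 48),
                               utility = c(0.8, 0.6))),
               0.7 * 48 / 52.1775)
  expect_error(qaly(data.frame(visit_week = 0, utility = 1)),
               "at least two")
})

test_that("QALY is additive over adjacent visit intervals", {
  set.seed(3)
  for (i in 1:10) {
    u <- runif(5, 0, 1)
    w <- c(0, 12, 24, 36, 48)
    whole <- qaly(data.frame(visit_week = w, utility = u))
    parts <- sum(vapply(1:4, function(k) {
      qaly(data.frame(visit_week = w[k:(k + 1)], utility = u[k:(k + 1)]))
    }, numeric(1)))
    expect_equal(whole, parts)
  }
})

test_that("missing-visit policy interpolates interior and carries the last forward", {
  resp <- rbind(uniform_response("A", "FOUR_WEEKLY", 0, 1),
                uniform_response("A", "FOUR_WEEKLY", 24, 3),
                uniform_response("A", "FOUR_WEEKLY", 36, 3))
  traj <- build_utility_trajectories(resp)
  ua <- traj$utility[traj$patient_id == "A"]
  expect_equal(length(ua), 5)
  expect_equal(ua[2], (ua[1] + ua[3]) / 2)   # week 12 interpolated
  expect_equal(ua[5], ua[4])                 # week 48 carried forward

  # a patient missing baseline is excluded
  resp2 <- rbind(resp, uniform_response("B", "FOUR_WEEKLY", 24, 2))
  traj2 <- build_utility_trajectories(resp2)
  expect_false("B" %in% traj2$patient_id)
  expect_true("B" %in% attr(traj2, "excluded"))
})

test_that("arm means are plain averages of per-patient QALYs", {
  resp <- rbind(uniform_response("A", "FOUR_WEEKLY", 0, 1),
                uniform_response("A", "FOUR_WEEKLY", 48, 1),
                uniform_response("B", "FOUR_WEEKLY", 0, 1),
                uniform_response("B", "FOUR_WEEKLY", 48, 1))
  trial <- list(responses = resp,
                patients = data.frame(patient_id = c("A", "B"),
                                      arm = "FOUR_WEEKLY",
                                      sse_indicator = c(1L, 0L)))
  s <- arm_mean_qaly(trial)
  expect_equal(s$mean_qaly, 48 / 52.1775)   # constant full health
  expect_equal(s$qaly_sse, s$qaly_no_sse)
  expect_equal(s$p_sse_observed, 0.5)
})
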