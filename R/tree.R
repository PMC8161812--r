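#' Expected per-patient cost of one strategy
#'
#' The decision tree has a single chance node per strategy: with
#' probability `p_sse` the patient experiences at least one symptomatic
#' skeletal event and incurs the arm's weighted SSE cost on top of BTA
#' treatment; otherwise only the treatment cost accrues. The expectation
#' is therefore `cost_bta + p_sse * cost_sse`.
#'
#' @param arm An [arm_parameters()] object.
#' @return Expected cost in CAD.
#' @export
#' @examples
#' expected_arm_cost(arm_parameters("FOUR_WEEKLY", 0.203,
#'                                  5642.07, 16369.25))  # 8965.03
expected_arm_cost <- function(arm) {
  stopifnot(inherits(arm, "bta_arm"))
  arm$cost_bta + arm$p_sse * arm$cost_sse
}

#' Expected per-patient QALY of one strategy
#'
#' `p_sse * qaly_sse + (1 - p_sse) * qaly_no_sse`, the probability-
#' weighted combination of the SSE and no-SSE branch QALYs.
#'
#' @param p_sse Probability of an SSE over the horizon.
#' @param qaly_sse,qaly_no_sse Branch QALY values.
#' @return Expected QALY.
#' @export
expected_arm_qaly <- function(p_sse, qaly_sse, qaly_no_sse) {
  stopifnot(is.finite(p_sse), is.finite(qaly_sse), is.finite(qaly_no_sse))
  p_sse * qaly_sse + (1 - p_sse) * qaly_no_sse
}

normalise_branches <- function(qaly_branches) {
  if (is.numeric(qaly_branches) && length(qaly_branches) == 2) {
    # arm means supplied directly: both branches equal the mean
    nm <- names(qaly_branches)
    if (is.null(nm)) nm <- c("arm_4wk", "arm_12wk")
    qaly_branches <- list(
      arm_4wk = list(qaly_sse = unname(qaly_branches[[which(nm %in%
        c("arm_4wk", "FOUR_WEEKLY"))[1]]]),
        qaly_no_sse = NULL),
      arm_12wk = list(qaly_sse = unname(qaly_branches[[which(nm %in%
        c("arm_12wk", "TWELVE_WEEKLY"))[1]]]),
        qaly_no_sse = NULL))
    qaly_branches$arm_4wk$qaly_no_sse <- qaly_branches$arm_4wk$qaly_sse
    qaly_branches$arm_12wk$qaly_no_sse <- qaly_branches$arm_12wk$qaly_sse
  }
  stopifnot(is.list(qaly_branches),
            all(c("arm_4wk", "arm_12wk") %in% names(qaly_branches)))
  for (a in c("arm_4wk", "arm_12wk")) {
    stopifnot(all(c("qaly_sse", "qaly_no_sse") %in%
                    names(qaly_branches[[a]])))
  }
  qaly_branches
}

#' Compare the two dosing strategies
#'
#' Evaluates the decision tree for both arms and assembles the full
#' cost-effectiveness result: per-strategy expected cost and QALY,
#' incremental cost and QALY (12-weekly minus 4-weekly), the ICER with a
#' dominance classification, and the incremental net benefit
#' `INB = wtp * delta_qaly - delta_cost`. A negative ICER is never
#' reported: when the incremental cost and QALY disagree in sign the
#' result is classified `DOMINANT` (cheaper and more effective) or
#' `DOMINATED`; when the QALY difference is exactly zero with a cost
#' difference the class is `COST_ONLY`; identical arms are `EQUIVALENT`.
#'
#' @param inputs A [model_inputs()] object.
#' @param qaly_branches Either a list
#'   `list(arm_4wk = list(qaly_sse=, qaly_no_sse=), arm_12wk = ...)` of
#'   branch QALYs (e.g. from [calibrate_branch_qalys()]), or a length-2
#'   numeric vector of arm mean QALYs `c(arm_4wk=, arm_12wk=)`.
#' @return An object of class `bta_ce_result`.
#' @export
#' @examples
#' res <- compare_strategies(default_model_inputs(),
#'                           c(arm_4wk = 0.605, arm_12wk = 0.612))
#' res$icer_class  # "DOMINANT"
compare_strategies <- function(inputs, qaly_branches) {
  stopifnot(inherits(inputs, "bta_inputs"))
  qb <- normalise_branches(qaly_branches)
  c4 <- expected_arm_cost(inputs$arm_4wk)
  c12 <- expected_arm_cost(inputs$arm_12wk)
  e4 <- expected_arm_qaly(inputs$arm_4wk$p_sse,
                          qb$arm_4wk$qaly_sse, qb$arm_4wk$qaly_no_sse)
  e12 <- expected_arm_qaly(inputs$arm_12wk$p_sse,
                           qb$arm_12wk$qaly_sse, qb$arm_12wk$qaly_no_sse)
  dc <- c12 - c4
  de <- e12 - e4
  inb <- inputs$wtp * de - dc
  if (dc < 0 && de > 0) {
    icer <- NA_real_; cls <- "DOMINANT"
  } else if (dc > 0 && de < 0) {
    icer <- NA_real_; cls <- "DOMINATED"
  } else if (de == 0 && dc != 0) {
    icer <- NA_real_; cls <- "COST_ONLY"
  } else if (de == 0 && dc == 0) {
    icer <- NA_real_; cls <- "EQUIVALENT"
  } else {
    icer <- dc / de; cls <- "ICER"
  }
  structure(
    list(strategies = data.frame(
           arm = c("FOUR_WEEKLY", "TWELVE_WEEKLY"),
           expected_cost = c(c4, c12),
           expected_qaly = c(e4, e12)),
         delta_cost = dc, delta_qaly = de,
         icer = icer, icer_class = cls,
         inb = inb, wtp = inputs$wtp),
    class = "bta_ce_result"
  )
}

#' @export
print.bta_ce_result <- function(x, ...) {
  s <- x$strategies
  cat("Cost-effectiveness result (reported to cents / 3 dp; internal\n")
  cat("values unrounded)\n")
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-14s cost C$%9.2f   QALY %.3f\n",
                s$arm[i], s$expected_cost[i], s$expected_qaly[i]))
  }
  cat(sprintf("  incremental    cost C$%9.2f   QALY %.3f\n",
              x$delta_cost, x$delta_qaly))
  icer_txt <- switch(x$icer_class,
    DOMINANT = "12-weekly dominates 4-weekly",
    DOMINATED = "12-weekly dominated by 4-weekly",
    COST_ONLY = "equal QALYs; decided on cost alone",
    EQUIVALENT = "strategies equivalent",
    sprintf("C$%.2f per QALY", x$icer))
  cat("  ICER:", icer_txt, "\n")
  cat(sprintf("  INB at C$%s/QALY: C$%.2f\n",
              format(x$wtp, big.mark = ","), x$inb))
  invisible(x)
}

#' Results table in the published layout
#'
#' @param x A `bta_ce_result`.
#' @param ... Unused.
#' @return Data frame shaped like the published cost-effectiveness
#'   results table (costs to cents, QALYs to 3 dp; derived from
#'   unrounded internals).
#' @export
as.data.frame.bta_ce_result <- function(x, ...) {
  s <- x$strategies
  icer_txt <- switch(x$icer_class,
    DOMINANT = "12-weekly dominates 4-weekly",
    DOMINATED = "12-weekly dominated by 4-weekly",
    COST_ONLY = "equal QALYs",
    EQUIVALENT = "equivalent",
    sprintf("%.2f", x$icer))
  data.frame(
    row = c("4-weekly BTA", "12-weekly BTA", "Incremental", "ICER", "INB"),
    cost = c(sprintf("%.2f", s$expected_cost),
             sprintf("%.2f", x$delta_cost), "", sprintf("%.2f", x$inb)),
    qaly = c(sprintf("%.3f", s$expected_qaly),
             sprintf("%.3f", x$delta_qaly), icer_txt, ""),
    stringsAsFactors = FALSE
  )
}

#' Serialise a cost-effectiveness result to JSON
#'
#' @param x A `bta_ce_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ce_result <- function(x, path) {
  stopifnot(inherits(x, "bta_ce_result"))
  jsonlite::write_json(
    list(strategies = x$strategies, delta_cost = x$delta_cost,
         delta_qaly = x$delta_qaly, icer = x$icer,
         icer_class = x$icer_class, inb = x$inb, wtp = x$wtp),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Monte Carlo oracle for the tree expectations
#'
#' Simulates the tree's branch lottery directly (Bernoulli SSE draws)
#' and returns the empirical mean cost and QALY per arm with standard
#' errors. Used as an independent cross-check of the closed-form
#' expectations; not part of the analysis pipeline.
#'
#' @param inputs A [model_inputs()] object.
#' @param qaly_branches As in [compare_strategies()].
#' @param n_draws Number of simulated patients per arm.
#' @param seed RNG seed.
#' @return Data frame `arm`, `mean_cost`, `se_cost`, `mean_qaly`,
#'   `se_qaly`.
#' @export
simulate_tree_lottery <- function(inputs, qaly_branches,
                                  n_draws = 1e6, seed = 1L) {
  stopifnot(inherits(inputs, "bta_inputs"))
  qb <- normalise_branches(qaly_branches)
  set.seed(seed)
  one <- function(arm, br) {
    sse <- stats::rbinom(n_draws, 1L, arm$p_sse)
    cost <- arm$cost_bta + sse * arm$cost_sse
    q <- ifelse(sse == 1L, br$qaly_sse, br$qaly_no_sse)
    data.frame(arm = arm$arm_label,
               mean_cost = mean(cost),
               se_cost = stats::sd(cost) / sqrt(n_draws),
               mean_qaly = mean(q),
               se_qaly = stats::sd(q) / sqrt(n_draws))
  }
  rbind(one(inputs$arm_4wk, qb$arm_4wk),
        one(inputs$arm_12wk, qb$arm_12wk))
}
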