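DIST_FAMILIES <- c("BETA", "GAMMA", "LOGNORMAL", "NORMAL", "POINT")

utils::globalVariables(c("parameter", "lo", "hi", "wtp",
                         "prob_cost_effective"))

#' Fit a sampling distribution to a point estimate with 95% limits
#'
#' Builds the parameter distribution used by the probabilistic
#' sensitivity analysis from a baseline value and its 95% interval.
#' `BETA`, `GAMMA` and `LOGNORMAL` are CI-matched: parameters are chosen
#' so the 2.5th and 97.5th percentiles equal the stated limits (gamma by
#' root-finding on the shape via the scale-free quantile ratio, beta by
#' two-dimensional minimisation from a moment-based start, lognormal in
#' closed form). `NORMAL` uses `mean = baseline` and
#' `sd = (upper - lower) / (2 * qnorm(0.975))`. A degenerate range
#' (`lower == upper`) yields a `POINT` mass regardless of family. The
#' fitted mean is compared with the baseline; if it deviates by more
#' than 1% relative the distribution is flagged `ci_matched` rather than
#' mean-matched in its `note` field.
#'
#' @param range One row of a ranges table (`name`, `baseline`, `lower`,
#'   `upper`) or a list with those elements.
#' @param family One of `"BETA"`, `"GAMMA"`, `"LOGNORMAL"`, `"NORMAL"`.
#' @param upper_bound Optional truncation bound (used for QALY branch
#'   values, which cannot exceed the horizon maximum).
#' @return An object of class `param_dist`.
#' @export
#' @examples
#' d <- fit_distribution(list(name = "p", baseline = 0.203,
#'                            lower = 0.1338, upper = 0.2954), "BETA")
#' qbeta(c(.025, .975), d$params[["shape1"]], d$params[["shape2"]])
fit_distribution <- function(range,
                             family = c("BETA", "GAMMA", "LOGNORMAL",
                                        "NORMAL"),
                             upper_bound = NULL) {
  b <- range$baseline; l <- range$lower; u <- range$upper
  stopifnot(is.finite(b))
  if (!is.na(l) && !is.na(u) && l == u) {
    return(structure(list(name = range$name, family = "POINT",
                          params = c(value = b), source = range,
                          note = "degenerate range"),
                     class = "param_dist"))
  }
  family <- match.arg(family)
  if (is.na(l) || is.na(u) || l >= u) {
    stop("fitting error: need finite lower < upper limits for ",
         range$name, call. = FALSE)
  }
  z <- stats::qnorm(0.975)
  params <- switch(family,
    NORMAL = c(mean = b, sd = (u - l) / (2 * z)),
    LOGNORMAL = {
      if (l <= 0) stop("fitting error: lognormal needs positive limits",
                       call. = FALSE)
      c(meanlog = (log(l) + log(u)) / 2,
        sdlog = (log(u) - log(l)) / (2 * z))
    },
    GAMMA = {
      if (l <= 0) stop("fitting error: gamma needs positive limits",
                       call. = FALSE)
      # quantile ratio q975/q025 is scale-free and decreasing in shape
      ratio <- u / l
      f <- function(lsh) {
        sh <- exp(lsh)
        stats::qgamma(0.975, sh) / stats::qgamma(0.025, sh) - ratio
      }
      lo <- -5; hi <- 15
      if (f(lo) < 0 || f(hi) > 0) {
        stop("fitting error: gamma CI-matching infeasible for ",
             range$name, call. = FALSE)
      }
      sh <- exp(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root)
      sc <- l / stats::qgamma(0.025, sh)
      c(shape = sh, scale = sc)
    },
    BETA = {
      if (l <= 0 || u >= 1) {
        stop("fitting error: beta limits must lie inside (0, 1) for ",
             range$name, call. = FALSE)
      }
      m <- (l + u) / 2
      s <- (u - l) / (2 * z)
      v0 <- max(m * (1 - m) / s^2 - 1, 2)
      start <- log(c(m * v0, (1 - m) * v0))
      obj <- function(p) {
        a <- exp(p[1]); bb <- exp(p[2])
        (stats::qbeta(0.025, a, bb) - l)^2 +
          (stats::qbeta(0.975, a, bb) - u)^2
      }
      fit <- stats::optim(start, obj, method = "Nelder-Mead",
                          control = list(reltol = 1e-14, maxit = 5000))
      if (sqrt(fit$value) > 1e-6) {
        stop("fitting error: beta CI-matching did not converge for ",
             range$name, call. = FALSE)
      }
      c(shape1 = exp(fit$par[1]), shape2 = exp(fit$par[2]))
    })
  mean_fitted <- switch(family,
    NORMAL = params[["mean"]],
    LOGNORMAL = exp(params[["meanlog"]] + params[["sdlog"]]^2 / 2),
    GAMMA = params[["shape"]] * params[["scale"]],
    BETA = params[["shape1"]] / (params[["shape1"]] + params[["shape2"]]))
  note <- if (abs(mean_fitted - b) <= 0.01 * abs(b)) "mean_matched"
    else "ci_matched"
  structure(list(name = range$name, family = family, params = params,
                 source = range, upper_bound = upper_bound, note = note),
            class = "param_dist")
}

#' Draw from a fitted parameter distribution
#'
#' @param dist A [fit_distribution()] object.
#' @param n Number of draws.
#' @return Numeric vector of length `n`. Truncation (for `NORMAL` with
#'   an `upper_bound`) is applied by inverse-CDF sampling so the stream
#'   stays reproducible.
#' @export
dist_sample <- function(dist, n) {
  stopifnot(inherits(dist, "param_dist"))
  p <- dist$params
  x <- switch(dist$family,
    POINT = rep(p[["value"]], n),
    NORMAL = {
      if (!is.null(dist$upper_bound)) {
        pmax_u <- stats::pnorm(dist$upper_bound, p[["mean"]], p[["sd"]])
        stats::qnorm(stats::runif(n, 0, pmax_u), p[["mean"]], p[["sd"]])
      } else {
        stats::rnorm(n, p[["mean"]], p[["sd"]])
      }
    },
    LOGNORMAL = stats::rlnorm(n, p[["meanlog"]], p[["sdlog"]]),
    GAMMA = stats::rgamma(n, shape = p[["shape"]], scale = p[["scale"]]),
    BETA = stats::rbeta(n, p[["shape1"]], p[["shape2"]]))
  x
}

# Apply a single parameter override to (inputs, branches); returns both.
# In the one-way analysis the relative risk propagates to the 12-weekly
# SSE probability (p12 = p4 * RR, capped at 1); probability parameters
# for the 4-weekly arm leave p12 at its baseline value.
apply_override <- function(inputs, branches, name, value) {
  b <- branches
  i <- inputs
  switch(name,
    p_sse_4wk = { i$arm_4wk$p_sse <- value },
    p_no_sse_4wk = { i$arm_4wk$p_sse <- 1 - value },
    p_sse_12wk = { i$arm_12wk$p_sse <- value },
    p_no_sse_12wk = { i$arm_12wk$p_sse <- 1 - value },
    relative_risk = {
      i$relative_risk <- value
      i$arm_12wk$p_sse <- min(1, i$arm_4wk$p_sse * value)
    },
    cost_bta_4wk = { i$arm_4wk$cost_bta <- value },
    cost_bta_12wk = { i$arm_12wk$cost_bta <- value },
    cost_sse_4wk = { i$arm_4wk$cost_sse <- value },
    cost_sse_12wk = { i$arm_12wk$cost_sse <- value },
    qaly_sse_4wk = { b$arm_4wk$qaly_sse <- value },
    qaly_no_sse_4wk = { b$arm_4wk$qaly_no_sse <- value },
    qaly_sse_12wk = { b$arm_12wk$qaly_sse <- value },
    qaly_no_sse_12wk = { b$arm_12wk$qaly_no_sse <- value },
    stop("validation error: unknown model parameter '", name, "'",
         call. = FALSE)
  )
  list(inputs = i, branches = b)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-evaluates the strategy comparison with each parameter set to its
#' lower and then its upper limit, all others held at baseline, and
#' reports the two outcome endpoints per parameter sorted by descending
#' bar width. The default outcome is the incremental net benefit, which
#' stays defined under dominance (the ICER does not); `outcome = "ICER"`
#' is available and yields `NA` endpoints for dominated/dominant runs.
#'
#' @param inputs A [model_inputs()] object (baseline).
#' @param ranges Ranges table (`name`, `baseline`, `lower`, `upper`);
#'   rows with missing limits are skipped. See [default_dsa_ranges()].
#' @param qaly_branches Baseline branch QALYs, as in
#'   [compare_strategies()].
#' @param outcome `"INB"` or `"ICER"`.
#' @return Data frame of class `bta_tornado`: `parameter`,
#'   `low_outcome`, `high_outcome`, `width`, sorted by descending
#'   `width`; attribute `"baseline_outcome"` carries the base-case value.
#' @export
one_way_dsa <- function(inputs, ranges, qaly_branches,
                        outcome = c("INB", "ICER")) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(inputs, "bta_inputs"))
  qb <- normalise_branches(qaly_branches)
  ranges <- validate_ranges(ranges)
  pick <- function(res) if (outcome == "INB") res$inb else res$icer
  eval_at <- function(name, value) {
    mod <- apply_override(inputs, qb, name, value)
    pick(compare_strategies(mod$inputs, mod$branches))
  }
  use <- !is.na(ranges$lower) & !is.na(ranges$upper)
  rows <- lapply(which(use), function(k) {
    lo <- eval_at(ranges$name[k], ranges$lower[k])
    hi <- eval_at(ranges$name[k], ranges$upper[k])
    data.frame(parameter = ranges$name[k], low_outcome = lo,
               high_outcome = hi,
               width = abs(hi - lo), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  attr(out, "baseline_outcome") <- pick(compare_strategies(inputs, qb))
  attr(out, "outcome") <- outcome
  class(out) <- c("bta_tornado", "data.frame")
  out
}

#' Default one-way sensitivity ranges
#'
#' Combines the base-case parameter table's published limits (the
#' 4-weekly no-SSE probability, the relative risk, and the four weighted
#' costs) with 95% intervals for the four QALY branch values taken as
#' `mean +/- 1.96 * SE` from patient-level data (see
#' [calibrate_branch_qalys()]).
#'
#' @param inputs A `bta_inputs` object carrying a `"ranges"` attribute
#'   (e.g. from [default_model_inputs()]).
#' @param branch_calibration Output of [calibrate_branch_qalys()].
#' @return Ranges data frame for [one_way_dsa()].
#' @export
default_dsa_ranges <- function(inputs, branch_calibration) {
  tab <- attr(inputs, "ranges")
  if (is.null(tab)) {
    stop("configuration error: inputs carry no ranges attribute",
         call. = FALSE)
  }
  keep <- c("p_no_sse_4wk", "relative_risk", "cost_bta_4wk",
            "cost_bta_12wk", "cost_sse_4wk", "cost_sse_12wk")
  tab <- tab[tab$name %in% keep, c("name", "baseline", "lower", "upper")]
  bc <- branch_calibration
  z <- stats::qnorm(0.975)
  qrow <- function(name, mean, se) {
    data.frame(name = name, baseline = mean,
               lower = mean - z * se, upper = mean + z * se)
  }
  rbind(tab,
        qrow("qaly_no_sse_4wk", bc$arm_4wk$qaly_no_sse,
             bc$arm_4wk$se_no_sse),
        qrow("qaly_sse_4wk", bc$arm_4wk$qaly_sse, bc$arm_4wk$se_sse),
        qrow("qaly_no_sse_12wk", bc$arm_12wk$qaly_no_sse,
             bc$arm_12wk$se_no_sse),
        qrow("qaly_sse_12wk", bc$arm_12wk$qaly_sse, bc$arm_12wk$se_sse))
}

#' Default probabilistic sensitivity analysis distributions
#'
#' Standard decision-modelling families: beta for the 4-weekly SSE
#' probability, lognormal for the relative risk, gamma for the four
#' weighted costs (all CI-matched to the published 95% limits), and
#' normal for the four QALY branch values with standard errors from
#' patient-level data, truncated above at the horizon maximum
#' (`horizon_weeks / 52.1775`). Within a draw the 12-weekly SSE
#' probability is derived as `min(1, p4 * RR)` so the sampled relative
#' risk and baseline probability stay coherent; all parameters are
#' sampled independently (no correlation structure is published).
#'
#' @inheritParams default_dsa_ranges
#' @return Named list of [fit_distribution()] objects.
#' @export
default_psa_distributions <- function(inputs, branch_calibration) {
  tab <- attr(inputs, "ranges")
  if (is.null(tab)) {
    stop("configuration error: inputs carry no ranges attribute",
         call. = FALSE)
  }
  row_of <- function(nm) as.list(tab[match(nm, tab$name), ])
  bc <- branch_calibration
  qmax <- inputs$horizon_weeks / WEEKS_PER_YEAR
  z <- stats::qnorm(0.975)
  qdist <- function(nm, mean, se) {
    fit_distribution(list(name = nm, baseline = mean,
                          lower = mean - z * se, upper = mean + z * se),
                     "NORMAL", upper_bound = qmax)
  }
  dists <- list(
    p_sse_4wk = fit_distribution(row_of("p_sse_4wk"), "BETA"),
    relative_risk = fit_distribution(row_of("relative_risk"), "LOGNORMAL"),
    cost_bta_4wk = fit_distribution(row_of("cost_bta_4wk"), "GAMMA"),
    cost_bta_12wk = fit_distribution(row_of("cost_bta_12wk"), "GAMMA"),
    cost_sse_4wk = fit_distribution(row_of("cost_sse_4wk"), "GAMMA"),
    cost_sse_12wk = fit_distribution(row_of("cost_sse_12wk"), "GAMMA"),
    qaly_sse_4wk = qdist("qaly_sse_4wk", bc$arm_4wk$qaly_sse,
                         bc$arm_4wk$se_sse),
    qaly_no_sse_4wk = qdist("qaly_no_sse_4wk", bc$arm_4wk$qaly_no_sse,
                            bc$arm_4wk$se_no_sse),
    qaly_sse_12wk = qdist("qaly_sse_12wk", bc$arm_12wk$qaly_sse,
                          bc$arm_12wk$se_sse),
    qaly_no_sse_12wk = qdist("qaly_no_sse_12wk", bc$arm_12wk$qaly_no_sse,
                             bc$arm_12wk$se_no_sse))
  dists
}

PSA_PARAM_ORDER <- c("p_sse_4wk", "relative_risk", "cost_bta_4wk",
                     "cost_bta_12wk", "cost_sse_4wk", "cost_sse_12wk",
                     "qaly_sse_4wk", "qaly_no_sse_4wk",
                     "qaly_sse_12wk", "qaly_no_sse_12wk")

#' Probabilistic sensitivity analysis by Monte Carlo
#'
#' Draws `n_sims` independent parameter vectors from the supplied
#' distributions, evaluates the decision tree for each, and returns the
#' per-draw incremental cost and QALY (12-weekly minus 4-weekly). The
#' draw stream is fully determined by `seed`: parameters are sampled in
#' a fixed order, so identical seeds give bit-identical output.
#'
#' @param inputs A [model_inputs()] object (supplies the WTP and
#'   horizon; sampled parameters override the rest).
#' @param distributions Named list of [fit_distribution()] objects
#'   covering the ten model parameters (see
#'   [default_psa_distributions()]).
#' @param n_sims Number of Monte Carlo draws (default 5000).
#' @param seed RNG seed, recorded in the output.
#' @return Data frame of class `bta_psa` with one row per draw: `draw`,
#'   the sampled parameters, `delta_cost`, `delta_qaly`, `inb`.
#' @export
run_psa <- function(inputs, distributions, n_sims = 5000, seed = 1L) {
  stopifnot(inherits(inputs, "bta_inputs"), n_sims >= 1)
  missing <- setdiff(PSA_PARAM_ORDER, names(distributions))
  if (length(missing)) {
    stop("configuration error: no distribution for parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  draws <- sapply(PSA_PARAM_ORDER,
                  function(nm) dist_sample(distributions[[nm]], n_sims))
  draws <- matrix(draws, nrow = n_sims,
                  dimnames = list(NULL, PSA_PARAM_ORDER))
  if (any(draws[, grep("^cost", colnames(draws))] < 0)) {
    stop("defensive error: sampled a negative cost; check the cost ",
         "distribution families", call. = FALSE)
  }
  p4 <- draws[, "p_sse_4wk"]
  p12 <- pmin(1, p4 * draws[, "relative_risk"])
  c4 <- draws[, "cost_bta_4wk"] + p4 * draws[, "cost_sse_4wk"]
  c12 <- draws[, "cost_bta_12wk"] + p12 * draws[, "cost_sse_12wk"]
  e4 <- p4 * draws[, "qaly_sse_4wk"] +
    (1 - p4) * draws[, "qaly_no_sse_4wk"]
  e12 <- p12 * draws[, "qaly_sse_12wk"] +
    (1 - p12) * draws[, "qaly_no_sse_12wk"]
  out <- data.frame(draw = seq_len(n_sims), draws,
                    p_sse_12wk = p12,
                    delta_cost = c12 - c4, delta_qaly = e12 - e4)
  out$inb <- inputs$wtp * out$delta_qaly - out$delta_cost
  attr(out, "seed") <- seed
  attr(out, "wtp") <- inputs$wtp
  class(out) <- c("bta_psa", "data.frame")
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws in which
#' the 12-weekly strategy has positive net benefit
#' (`wtp * delta_qaly - delta_cost > 0`).
#'
#' @param samples A [run_psa()] result.
#' @param wtp_grid Vector of willingness-to-pay thresholds (CAD/QALY).
#' @return Data frame `wtp`, `prob_cost_effective`.
#' @export
ceac <- function(samples, wtp_grid = seq(0, 150000, by = 5000)) {
  stopifnot(nrow(samples) > 0)
  if (length(wtp_grid) == 0) {
    stop("validation error: empty willingness-to-pay grid", call. = FALSE)
  }
  prob <- vapply(wtp_grid, function(l) {
    mean(l * samples$delta_qaly - samples$delta_cost > 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, prob_cost_effective = prob)
}

#' Tornado diagram
#'
#' @param entries A [one_way_dsa()] result.
#' @return A ggplot object: horizontal bars from the low- to the
#'   high-limit outcome per parameter, widest on top, with the baseline
#'   outcome as a reference line.
#' @export
plot_tornado <- function(entries) {
  stopifnot(inherits(entries, "bta_tornado"))
  df <- as.data.frame(entries)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  df$lo <- pmin(df$low_outcome, df$high_outcome)
  df$hi <- pmax(df$low_outcome, df$high_outcome)
  base <- attr(entries, "baseline_outcome")
  ggplot2::ggplot(df, ggplot2::aes(y = parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = lo, xend = hi,
                                       yend = parameter),
                          linewidth = 5, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = 2) +
    ggplot2::labs(x = paste0(attr(entries, "outcome"),
                             " (CAD)"), y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param ceac_df A [ceac()] result.
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_df) {
  ggplot2::ggplot(ceac_df,
                  ggplot2::aes(x = wtp, y = prob_cost_effective)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Willingness to pay (CAD per QALY)",
                  y = "P(12-weekly cost-effective)",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}
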