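#' Configuration for the synthetic two-arm trial generator
#'
#' Defaults emulate the study conditions of the trial the model is built
#' around: 133 patients on 4-weekly and 130 on 12-weekly dosing, SSE
#' probabilities 0.203 / 0.223, and arm mean QALYs 0.605 / 0.612 over a
#' 48-week horizon. The SSE type mix, the post-event utility decrement,
#' the patient-level utility spread, and the visit missingness rate are
#' assumptions (the trial's per-type counts and SSE-conditional
#' utilities are not published); they are plain configuration fields.
#'
#' Patient-level utility is modelled as `u = 1 - X` with
#' `X ~ Gamma(shape, scale)` (a right-skewed decrement, so utilities are
#' left-skewed and never exceed 1), multiplicative lognormal visit noise
#' with unit mean, and an additive utility decrement from a uniformly
#' timed SSE. The gamma mean is solved in closed form so the expected
#' arm mean QALY equals the target.
#'
#' @param n_4wk,n_12wk Arm sizes.
#' @param p_sse_4wk,p_sse_12wk Per-arm SSE probabilities.
#' @param target_qaly_4wk,target_qaly_12wk Target arm mean QALYs.
#' @param sse_type_mix Named proportion vector over the five SSE types
#'   (must sum to 1); the default is radiotherapy-dominant.
#' @param sse_decrement Utility decrement applied from the event week
#'   onwards.
#' @param utility_sd Between-patient SD of baseline utility.
#' @param noise_sdlog SD (log scale) of the visit-level multiplicative
#'   noise on the utility decrement.
#' @param missing_rate Probability that a non-baseline visit is missing.
#' @param horizon_weeks Trial horizon; visits at 0, 12, 24, 36, 48.
#' @param seed RNG seed.
#' @return An object of class `bta_gen_config`.
#' @export
generator_config <- function(n_4wk = 133L, n_12wk = 130L,
                             p_sse_4wk = 0.203, p_sse_12wk = 0.223,
                             target_qaly_4wk = 0.605,
                             target_qaly_12wk = 0.612,
                             sse_type_mix = c(radiotherapy = 0.50,
                                              fracture = 0.16,
                                              cord_compression = 0.08,
                                              surgery = 0.12,
                                              hypercalcemia = 0.14),
                             sse_decrement = 0.10,
                             utility_sd = 0.22,
                             noise_sdlog = 0.15,
                             missing_rate = 0.05,
                             horizon_weeks = 48L,
                             seed = 1L) {
  stopifnot(n_4wk >= 1, n_12wk >= 1,
            p_sse_4wk >= 0, p_sse_4wk <= 1,
            p_sse_12wk >= 0, p_sse_12wk <= 1,
            sse_decrement >= 0, utility_sd > 0,
            missing_rate >= 0, missing_rate < 1)
  if (abs(sum(sse_type_mix) - 1) > 1e-9) {
    stop("validation error: sse_type_mix must sum to 1", call. = FALSE)
  }
  yrs <- horizon_weeks / WEEKS_PER_YEAR
  if (1 - target_qaly_4wk / yrs - p_sse_4wk * sse_decrement / 2 <= 0 ||
      1 - target_qaly_12wk / yrs - p_sse_12wk * sse_decrement / 2 <= 0) {
    stop("configuration error: target QALY is unreachable given the ",
         "decrement and horizon (implied mean utility > 1)",
         call. = FALSE)
  }
  structure(
    list(n_4wk = as.integer(n_4wk), n_12wk = as.integer(n_12wk),
         p_sse = c(FOUR_WEEKLY = p_sse_4wk, TWELVE_WEEKLY = p_sse_12wk),
         target_qaly = c(FOUR_WEEKLY = target_qaly_4wk,
                         TWELVE_WEEKLY = target_qaly_12wk),
         sse_type_mix = sse_type_mix,
         sse_decrement = sse_decrement,
         utility_sd = utility_sd, noise_sdlog = noise_sdlog,
         missing_rate = missing_rate,
         horizon_weeks = as.integer(horizon_weeks),
         visits = seq(0L, as.integer(horizon_weeks), by = 12L),
         seed = as.integer(seed)),
    class = "bta_gen_config"
  )
}

# The descriptive system censors the latent utility decrement at the
# worst achievable state (sum of the maximum decrements). The gamma mean
# of the latent decrement is therefore solved so that the expected
# *emitted* (censored) utility matches the target arm mean QALY:
#   E[min(Y, cmax)] with Y = X * exp(eps), X ~ Gamma, eps ~ N(-s^2/2, s),
# plus the SSE decrement applied (on average) to half the horizon.
expected_censored_dec <- function(mean_x, sd_u, sdlog, shift, cmax) {
  shape <- (mean_x / sd_u)^2
  scale <- sd_u^2 / mean_x
  outer_f <- function(x) {
    vapply(x, function(xx) {
      g <- function(e) {
        pmin(xx * exp(e) + shift, cmax) *
          stats::dnorm(e, -sdlog^2 / 2, sdlog)
      }
      stats::integrate(g, -6 * sdlog, 6 * sdlog)$value *
        stats::dgamma(xx, shape, scale = scale)
    }, numeric(1))
  }
  stats::integrate(outer_f, 0, Inf)$value
}

.calibration_cache <- new.env(parent = emptyenv())

calibrate_generator <- function(config, valueset) {
  cmax <- sum(valueset$decrements[, 4])
  key <- paste(format(c(cmax, config$target_qaly, config$p_sse,
                        config$sse_decrement, config$utility_sd,
                        config$noise_sdlog, config$horizon_weeks),
                      digits = 17), collapse = "|")
  cached <- .calibration_cache[[key]]
  if (!is.null(cached)) return(cached)
  yrs <- config$horizon_weeks / WEEKS_PER_YEAR
  d <- config$sse_decrement
  solve_arm <- function(arm) {
    target_dec <- 1 - config$target_qaly[[arm]] / yrs
    p <- config$p_sse[[arm]]
    f <- function(mx) {
      a <- expected_censored_dec(mx, config$utility_sd,
                                 config$noise_sdlog, 0, cmax)
      b <- expected_censored_dec(mx, config$utility_sd,
                                 config$noise_sdlog, d, cmax)
      (1 - p) * a + p * (a + b) / 2 - target_dec
    }
    lo <- 1e-4
    hi <- cmax
    if (f(lo) > 0 || f(hi) < 0) {
      stop("configuration error: target QALY for arm ", arm,
           " is unreachable under the value set's ceiling", call. = FALSE)
    }
    mx <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
    list(shape = (mx / config$utility_sd)^2,
         scale = config$utility_sd^2 / mx)
  }
  out <- list(FOUR_WEEKLY = solve_arm("FOUR_WEEKLY"),
              TWELVE_WEEKLY = solve_arm("TWELVE_WEEKLY"))
  .calibration_cache[[key]] <- out
  out
}

# Ordered decrement chain over the value set: all dimensions to level 2
# (in fixed dimension order), then to 3, then to 4. Prefix m of the
# chain is an achievable state; precomputing all 31 prefixes gives an
# increasing ladder of achievable utility decrements used to emit item
# responses by randomised rounding.
decrement_chain <- function(valueset) {
  dec <- valueset$decrements
  inc <- dec[, 2:4, drop = FALSE] - dec[, 1:3, drop = FALSE]
  steps_dim <- rep(seq_len(nrow(dec)), times = 3)
  cum <- cumsum(as.vector(inc))
  n_steps <- length(steps_dim)
  states <- matrix(1L, nrow = n_steps + 1, ncol = nrow(dec),
                   dimnames = list(NULL, rownames(dec)))
  for (m in seq_len(n_steps)) {
    states[m + 1, ] <- states[m, ]
    states[m + 1, steps_dim[m]] <- states[m, steps_dim[m]] + 1L
  }
  list(achievable = c(0, cum), states = states)
}

# Randomised rounding of target decrements onto the chain: the emitted
# state's expected decrement equals the target exactly for targets
# within the achievable range (targets outside are clamped).
emit_states <- function(target_dec, chain) {
  a <- chain$achievable
  d <- pmin(pmax(target_dec, 0), a[length(a)])
  j <- findInterval(d, a, rightmost.closed = TRUE)
  gap <- a[pmin(j + 1, length(a))] - a[j]
  frac <- ifelse(gap > 0, (d - a[j]) / gap, 0)
  bump <- stats::runif(length(d)) < frac
  chain$states[j + as.integer(bump), , drop = FALSE]
}

# QLU-C10D state levels -> 30-item QLQ-C30 response matrix. Mapped items
# echo their dimension level; unmapped 1-4 items carry the rounded mean
# level (cosmetic only, they feed nothing); items 29-30 are on the 1-7
# global scale.
states_to_items <- function(states, mapping) {
  n <- nrow(states)
  resp <- matrix(NA_integer_, nrow = n, ncol = 30,
                 dimnames = list(NULL, paste0("q", 1:30)))
  for (k in seq_len(nrow(mapping))) {
    resp[, mapping$c30_item[k]] <- states[, mapping$dimension[k]]
  }
  meanlev <- rowMeans(states)
  filler <- as.integer(pmin(4, pmax(1, round(meanlev))))
  unmapped <- setdiff(1:28, mapping$c30_item)
  resp[, unmapped] <- filler
  global <- as.integer(pmin(7, pmax(1, round(8 - 1.5 * meanlev))))
  resp[, 29] <- global
  resp[, 30] <- global
  resp
}

#' Generate a synthetic two-arm trial dataset
#'
#' Draws SSE indicators and event types, builds latent per-visit
#' utilities from a patient-level gamma decrement plus multiplicative
#' visit noise and a post-event decrement, then emits QLQ-C30 item
#' responses whose mapped QLU-C10D utility equals the latent utility in
#' expectation (randomised rounding onto the value set's achievable
#' states; the discrete descriptive system cannot hit arbitrary reals
#' exactly). Latent utilities are stored alongside the responses for
#' oracle tests. Fully reproducible from the config seed.
#'
#' @param config A [generator_config()].
#' @param valueset A [load_value_set()] object.
#' @param mapping Item mapping from [qlu_mapping()].
#' @return An object of class `bta_trial`: list with data frames
#'   `patients` (`patient_id`, `arm`, `sse_indicator`, `sse_type`,
#'   `sse_week`) and `responses` (`patient_id`, `arm`, `visit_week`,
#'   `latent_utility`, `q1`..`q30`), plus the `config`.
#' @export
generate_trial <- function(config = generator_config(),
                           valueset = load_value_set(),
                           mapping = qlu_mapping()) {
  stopifnot(inherits(config, "bta_gen_config"))
  gamma_pars <- calibrate_generator(config, valueset)
  set.seed(config$seed)
  chain <- decrement_chain(valueset)
  arms <- c(rep("FOUR_WEEKLY", config$n_4wk),
            rep("TWELVE_WEEKLY", config$n_12wk))
  n <- length(arms)
  ids <- sprintf("P%04d", seq_len(n))
  sse <- stats::rbinom(n, 1L, config$p_sse[arms])
  types <- rep(NA_character_, n)
  n_events <- sum(sse)
  if (n_events > 0) {
    types[sse == 1L] <- sample(names(config$sse_type_mix), n_events,
                               replace = TRUE, prob = config$sse_type_mix)
  }
  event_week <- rep(NA_real_, n)
  event_week[sse == 1L] <- stats::runif(n_events, 0, config$horizon_weeks)

  shapes <- vapply(gamma_pars, `[[`, numeric(1), "shape")[arms]
  scales <- vapply(gamma_pars, `[[`, numeric(1), "scale")[arms]
  x_patient <- stats::rgamma(n, shape = shapes, scale = scales)

  visits <- config$visits
  nv <- length(visits)
  pid <- rep(ids, each = nv)
  varm <- rep(arms, each = nv)
  vweek <- rep(visits, times = n)
  sdl <- config$noise_sdlog
  noise <- exp(stats::rnorm(n * nv, -sdl^2 / 2, sdl))
  x_visit <- rep(x_patient, each = nv) * noise
  hit <- !is.na(rep(event_week, each = nv)) &
    vweek >= rep(event_week, each = nv)
  latent <- 1 - x_visit - config$sse_decrement * as.numeric(hit)

  states <- emit_states(1 - latent, chain)
  items <- states_to_items(states, mapping)

  keep <- vweek == 0 | stats::runif(n * nv) >= config$missing_rate
  responses <- data.frame(patient_id = pid[keep], arm = varm[keep],
                          visit_week = vweek[keep],
                          latent_utility = latent[keep],
                          stringsAsFactors = FALSE)
  responses <- cbind(responses, as.data.frame(items[keep, , drop = FALSE]))
  patients <- data.frame(patient_id = ids, arm = arms,
                         sse_indicator = sse, sse_type = types,
                         sse_week = event_week, stringsAsFactors = FALSE)
  structure(list(patients = patients, responses = responses,
                 config = config),
            class = "bta_trial")
}

#' @export
print.bta_trial <- function(x, ...) {
  tab <- table(x$patients$arm)
  cat("Synthetic BTA trial:", nrow(x$patients), "patients (",
      paste(names(tab), tab, sep = " = ", collapse = ", "), ")\n")
  cat("  SSE events:", sum(x$patients$sse_indicator), "|",
      nrow(x$responses), "patient-visit records\n")
  invisible(x)
}

#' Write a trial dataset to CSV/JSON files
#'
#' Emits `patients.csv`, `responses.csv` and `generator_config.json`
#' into a directory. Byte-identical for identical config and seed.
#'
#' @param trial A `bta_trial` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "bta_trial"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(trial$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE, na = "")
  resp <- trial$responses
  resp$latent_utility <- format(resp$latent_utility, digits = 17,
                                trim = TRUE)
  utils::write.csv(resp, file.path(dir, "responses.csv"),
                   row.names = FALSE, na = "")
  cfg <- unclass(trial$config)
  jsonlite::write_json(cfg, file.path(dir, "generator_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a trial dataset written by [write_trial()]
#'
#' @param dir Directory containing `patients.csv` and `responses.csv`.
#' @return A `bta_trial` object (without the generator config).
#' @export
read_trial <- function(dir) {
  patients <- utils::read.csv(file.path(dir, "patients.csv"),
                              stringsAsFactors = FALSE, na.strings = "")
  responses <- utils::read.csv(file.path(dir, "responses.csv"),
                               stringsAsFactors = FALSE, na.strings = "")
  structure(list(patients = patients, responses = responses,
                 config = NULL),
            class = "bta_trial")
}

#' Calibrate decision-tree branch QALYs from patient-level data
#'
#' Stratifies per-patient QALYs by SSE status within each arm; the
#' stratified means are the tree's branch values, and by the law of
#' total expectation the observed-proportion-weighted recombination
#' `p_hat * qaly_sse + (1 - p_hat) * qaly_no_sse` reproduces the arm
#' mean exactly.
#'
#' @param trial A `bta_trial` object.
#' @param valueset A [load_value_set()] object.
#' @param mapping Item mapping from [qlu_mapping()].
#' @param ... Passed to [build_utility_trajectories()].
#' @return List with elements `arm_4wk` and `arm_12wk`, each carrying
#'   `p_hat`, `qaly_sse`, `qaly_no_sse`, `se_sse`, `se_no_sse`,
#'   `mean_qaly`, `n`.
#' @export
calibrate_branch_qalys <- function(trial, valueset = load_value_set(),
                                   mapping = qlu_mapping(), ...) {
  summ <- arm_mean_qaly(trial, valueset, mapping, ...)
  pick <- function(label) {
    r <- summ[summ$arm == label, ]
    if (nrow(r) != 1) {
      stop("validation error: arm ", label, " absent from the dataset",
           call. = FALSE)
    }
    if (is.na(r$qaly_sse) || is.na(r$qaly_no_sse)) {
      stop("validation error: empty SSE stratum in arm ", label,
           "; increase the sample size or the SSE probability",
           call. = FALSE)
    }
    list(p_hat = r$p_sse_observed, qaly_sse = r$qaly_sse,
         qaly_no_sse = r$qaly_no_sse, se_sse = r$se_sse,
         se_no_sse = r$se_no_sse, mean_qaly = r$mean_qaly, n = r$n)
  }
  list(arm_4wk = pick("FOUR_WEEKLY"), arm_12wk = pick("TWELVE_WEEKLY"))
}

#' Branch list for [compare_strategies()] from a calibration
#'
#' @param calibration Output of [calibrate_branch_qalys()].
#' @return Branch QALY list in the layout [compare_strategies()] expects.
#' @export
branches_from_calibration <- function(calibration) {
  list(arm_4wk = list(qaly_sse = calibration$arm_4wk$qaly_sse,
                      qaly_no_sse = calibration$arm_4wk$qaly_no_sse),
       arm_12wk = list(qaly_sse = calibration$arm_12wk$qaly_sse,
                       qaly_no_sse = calibration$arm_12wk$qaly_no_sse))
}
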