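C10D_DIMENSIONS <- c("physical", "role", "social", "emotional", "pain",
                     "fatigue", "sleep", "appetite", "nausea", "bowel")

WEEKS_PER_YEAR <- 52.1775

#' Item-to-dimension mapping for the QLU-C10D descriptive system
#'
#' Loads the mapping from QLQ-C30 item numbers to the ten QLU-C10D
#' dimensions (physical, role, social and emotional functioning, pain,
#' fatigue, sleep, appetite, nausea, bowel problems). Thirteen of the
#' thirty QLQ-C30 items feed the ten dimensions; for a multi-item
#' dimension the level is the worst (highest) response among its items.
#' The packaged file approximates the published descriptive system and
#' is a replaceable data fixture, not a reproduction of it.
#'
#' @param path Mapping CSV (`c30_item,dimension,level_rule`); defaults to
#'   the packaged file.
#' @return Data frame with one row per contributing item.
#' @export
qlu_mapping <- function(path = bta_extdata("qlu_c10d_mapping.csv")) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("c30_item", "dimension") %in% names(map)))
  bad <- setdiff(unique(map$dimension), C10D_DIMENSIONS)
  if (length(bad)) {
    stop("configuration error: unknown QLU-C10D dimension(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  map
}

#' Load a QLU-C10D value set
#'
#' A value set assigns a utility decrement to each (dimension, level)
#' pair; the utility of a state is 1 minus the sum of its decrements, so
#' the all-level-1 state is anchored at 1 (full health) and the worst
#' state may fall below 0 (worse than dead). The packaged default is a
#' synthetic Canadian-style value set constructed for this package (the
#' published national coefficients are an external resource); any CSV in
#' the same layout can be substituted.
#'
#' @param path Value-set CSV (`dimension,level,decrement`).
#' @param name Identifier stored with the value set.
#' @return An object of class `qlu_valueset`: the decrement table plus a
#'   10 x 4 decrement matrix used for fast lookup.
#' @export
load_value_set <- function(path = bta_extdata("valueset_ca_synthetic.csv"),
                           name = "CA-synthetic") {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("dimension", "level", "decrement") %in% names(tab)))
  dec <- matrix(NA_real_, nrow = length(C10D_DIMENSIONS), ncol = 4,
                dimnames = list(C10D_DIMENSIONS, paste0("L", 1:4)))
  idx <- cbind(match(tab$dimension, C10D_DIMENSIONS), tab$level)
  if (anyNA(idx)) {
    stop("configuration error: value set contains unknown dimension or ",
         "level", call. = FALSE)
  }
  dec[idx] <- tab$decrement
  if (anyNA(dec)) {
    stop("configuration error: value set must cover every ",
         "(dimension, level) pair", call. = FALSE)
  }
  if (any(dec[, 1] != 0)) {
    stop("validation error: level-1 decrements must be 0 (utility anchor)",
         call. = FALSE)
  }
  if (any(dec < 0)) {
    stop("validation error: decrements must be non-negative", call. = FALSE)
  }
  structure(list(name = name, table = tab, decrements = dec),
            class = "qlu_valueset")
}

# Vectorised mapping: n x 30 response matrix -> n x 10 level matrix.
# Missing-item policy: a dimension level is the worst response among its
# present items; if every item of a dimension is missing the level is NA
# (a missing-state marker, handled downstream by the trajectory policy).
map_qlq_matrix <- function(resp, mapping) {
  stopifnot(ncol(resp) == 30)
  out <- matrix(NA_integer_, nrow = nrow(resp),
                ncol = length(C10D_DIMENSIONS),
                dimnames = list(NULL, C10D_DIMENSIONS))
  for (dim in C10D_DIMENSIONS) {
    items <- mapping$c30_item[mapping$dimension == dim]
    sub <- resp[, items, drop = FALSE]
    lev <- suppressWarnings(
      apply(sub, 1L, function(r) if (all(is.na(r))) NA_integer_
            else as.integer(max(r, na.rm = TRUE))))
    out[, dim] <- lev
  }
  bad <- !is.na(out) & (out < 1 | out > 4)
  if (any(bad)) {
    stop("validation error: mapped levels outside 1..4; check item ",
         "responses", call. = FALSE)
  }
  out
}

#' Map one QLQ-C30 response to a QLU-C10D state
#'
#' @param items Numeric vector of the 30 item responses (items 1-28 on a
#'   1-4 scale, items 29-30 on 1-7; `NA` = missing). Only the mapped
#'   items are used.
#' @param mapping Item mapping from [qlu_mapping()].
#' @return Named integer vector of the ten dimension levels (class
#'   `c10d_state`); `NA` for a dimension whose items are all missing.
#' @export
#' @examples
#' st <- map_qlq_to_c10d(rep(1, 30))
#' all(st == 1)
map_qlq_to_c10d <- function(items, mapping = qlu_mapping()) {
  stopifnot(length(items) == 30)
  lev <- map_qlq_matrix(matrix(as.numeric(items), nrow = 1), mapping)[1, ]
  structure(lev, class = "c10d_state")
}

# n x 10 level matrix -> utility vector (NA where any level is NA)
utility_from_levels <- function(levels, valueset) {
  dec <- valueset$decrements
  tot <- rep(0, nrow(levels))
  for (j in seq_along(C10D_DIMENSIONS)) {
    tot <- tot + unname(dec[j, ][levels[, j]])
  }
  1 - tot
}

#' Utility of a QLU-C10D state
#'
#' `1 - sum of decrements` under the given value set.
#'
#' @param state Named integer vector of ten levels (see
#'   [map_qlq_to_c10d()]).
#' @param valueset A [load_value_set()] object.
#' @return Utility value (at most 1; may be negative for severe states).
#' @export
utility <- function(state, valueset = load_value_set()) {
  stopifnot(inherits(valueset, "qlu_valueset"))
  lev <- as.integer(unclass(state)[C10D_DIMENSIONS])
  if (anyNA(lev)) return(NA_real_)
  if (any(lev < 1 | lev > 4)) {
    stop("validation error: state levels must lie in 1..4", call. = FALSE)
  }
  utility_from_levels(matrix(lev, nrow = 1), valueset)
}

#' QALY by trapezoidal area under a utility trajectory
#'
#' Integrates utility against time (weeks converted to years at
#' `52.1775` weeks/year) by the trapezoid rule over the observed visits.
#'
#' @param trajectory Data frame with columns `visit_week` (strictly
#'   increasing) and `utility`, at least two rows.
#' @param weeks_per_year Week-to-year conversion factor.
#' @return QALYs accrued between the first and last visit.
#' @export
#' @examples
#' qaly(data.frame(visit_week = c(0, 48), utility = c(1, 1)))  # ~0.92
qaly <- function(trajectory, weeks_per_year = WEEKS_PER_YEAR) {
  w <- trajectory$visit_week
  u <- trajectory$utility
  if (length(w) < 2) {
    stop("validation error: a trajectory needs at least two visits to ",
         "integrate", call. = FALSE)
  }
  if (any(diff(w) <= 0)) {
    stop("validation error: visit weeks must be strictly increasing",
         call. = FALSE)
  }
  if (anyNA(u)) {
    stop("validation error: trajectory contains missing utilities; apply ",
         "the missing-visit policy first", call. = FALSE)
  }
  n <- length(w)
  sum(diff(w) / weeks_per_year * (u[-1] + u[-n]) / 2)
}

#' Build complete utility trajectories from patient-visit responses
#'
#' Maps each patient-visit QLQ-C30 response to a QLU-C10D utility and
#' applies the missing-visit policy: interior missing visits are linearly
#' interpolated between flanking visits, a missing terminal visit carries
#' the last observation forward, and patients missing the baseline visit
#' are excluded (the policy choices are configurable).
#'
#' @param responses Data frame with columns `patient_id`, `arm`,
#'   `visit_week`, `q1`..`q30`.
#' @param valueset A [load_value_set()] object.
#' @param mapping Item mapping from [qlu_mapping()].
#' @param visits Scheduled visit weeks.
#' @param interior `"interpolate"` (default) or `"drop_patient"`.
#' @param terminal `"locf"` (default) or `"drop_patient"`.
#' @return Data frame `patient_id`, `arm`, `visit_week`, `utility` with a
#'   complete grid for every retained patient, plus attribute
#'   `"excluded"` listing patients dropped by the policy.
#' @export
build_utility_trajectories <- function(responses,
                                       valueset = load_value_set(),
                                       mapping = qlu_mapping(),
                                       visits = c(0, 12, 24, 36, 48),
                                       interior = c("interpolate",
                                                    "drop_patient"),
                                       terminal = c("locf",
                                                    "drop_patient")) {
  interior <- match.arg(interior)
  terminal <- match.arg(terminal)
  qcols <- paste0("q", 1:30)
  stopifnot(all(c("patient_id", "arm", "visit_week") %in% names(responses)),
            all(qcols %in% names(responses)))
  resp <- as.matrix(responses[, qcols])
  levels <- map_qlq_matrix(resp, mapping)
  u <- utility_from_levels(levels, valueset)

  ids <- unique(responses$patient_id)
  arm_of <- responses$arm[match(ids, responses$patient_id)]
  # patients x visits utility matrix (NA = missing visit or missing state)
  m <- matrix(NA_real_, nrow = length(ids), ncol = length(visits),
              dimnames = list(ids, visits))
  ri <- match(responses$patient_id, ids)
  ci <- match(responses$visit_week, visits)
  if (anyNA(ci)) {
    stop("validation error: visit weeks outside the scheduled grid: ",
         paste(unique(responses$visit_week[is.na(ci)]), collapse = ", "),
         call. = FALSE)
  }
  m[cbind(ri, ci)] <- u

  excluded <- character(0)
  keep <- !is.na(m[, 1])
  excluded <- c(excluded, ids[!keep])
  if (interior == "drop_patient" || terminal == "drop_patient") {
    full <- rowSums(is.na(m)) == 0
    if (interior == "drop_patient") keep <- keep & full
    if (terminal == "drop_patient") keep <- keep & !is.na(m[, ncol(m)])
    excluded <- unique(c(excluded, ids[!keep]))
  }
  m <- m[keep, , drop = FALSE]
  ids <- ids[keep]
  arm_of <- arm_of[keep]
  if (nrow(m) == 0) {
    stop("validation error: no patients left after the missing-data policy",
         call. = FALSE)
  }
  if (interior == "interpolate" && any(is.na(m))) {
    # zoo works column-wise, so interpolate with patients as columns
    tm <- zoo::na.approx(t(m), x = visits, na.rm = FALSE)
    tm <- zoo::na.locf(tm, na.rm = FALSE)  # terminal LOCF
    m <- t(tm)
  }
  if (any(is.na(m))) {
    stop("internal error: missing utilities survived the policy",
         call. = FALSE)
  }
  data.frame(
    patient_id = rep(ids, each = length(visits)),
    arm = rep(arm_of, each = length(visits)),
    visit_week = rep(visits, times = length(ids)),
    utility = as.vector(t(m)),
    stringsAsFactors = FALSE
  ) -> out
  attr(out, "excluded") <- excluded
  out
}

#' Per-patient QALYs from a trajectory table
#'
#' @param trajectories Output of [build_utility_trajectories()].
#' @param weeks_per_year Week-to-year conversion factor.
#' @return Data frame `patient_id`, `arm`, `qaly`.
#' @export
patient_qalys <- function(trajectories, weeks_per_year = WEEKS_PER_YEAR) {
  visits <- sort(unique(trajectories$visit_week))
  ids <- unique(trajectories$patient_id)
  m <- matrix(trajectories$utility[order(match(trajectories$patient_id, ids),
                                         trajectories$visit_week)],
              nrow = length(ids), byrow = TRUE)
  dw <- diff(visits) / weeks_per_year
  mid <- (m[, -1, drop = FALSE] + m[, -ncol(m), drop = FALSE]) / 2
  q <- as.vector(mid %*% dw)
  data.frame(patient_id = ids,
             arm = trajectories$arm[match(ids, trajectories$patient_id)],
             qaly = q, stringsAsFactors = FALSE)
}

#' Arm-level mean QALYs, overall and by SSE status
#'
#' Runs the full utility pipeline on a trial dataset (observed or
#' synthetic) and summarises per-patient QALYs by arm, including the
#' SSE-conditional means needed as decision-tree branch values and by the
#' deterministic sensitivity analysis.
#'
#' @param trial A `bta_trial` object (see [generate_trial()]) or a list
#'   with elements `responses` and `patients` in the same layout.
#' @param valueset A [load_value_set()] object.
#' @param mapping Item mapping from [qlu_mapping()].
#' @param ... Passed to [build_utility_trajectories()].
#' @return Data frame with one row per arm: `arm`, `n`, `mean_qaly`,
#'   `se`, `p_sse_observed`, `qaly_sse`, `qaly_no_sse`, `se_sse`,
#'   `se_no_sse`.
#' @export
arm_mean_qaly <- function(trial, valueset = load_value_set(),
                          mapping = qlu_mapping(), ...) {
  stopifnot(is.list(trial), !is.null(trial$responses),
            !is.null(trial$patients))
  traj <- build_utility_trajectories(trial$responses, valueset, mapping, ...)
  pq <- patient_qalys(traj)
  pq$sse <- trial$patients$sse_indicator[
    match(pq$patient_id, trial$patients$patient_id)]
  arms <- unique(trial$patients$arm)
  out <- do.call(rbind, lapply(arms, function(a) {
    qa <- pq[pq$arm == a, ]
    if (nrow(qa) == 0) {
      stop("validation error: arm ", a, " has no evaluable patients",
           call. = FALSE)
    }
    s1 <- qa$qaly[qa$sse == 1]
    s0 <- qa$qaly[qa$sse == 0]
    sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x))
      else NA_real_
    data.frame(arm = a, n = nrow(qa), mean_qaly = mean(qa$qaly),
               se = sem(qa$qaly),
               p_sse_observed = mean(qa$sse),
               qaly_sse = if (length(s1)) mean(s1) else NA_real_,
               qaly_no_sse = if (length(s0)) mean(s0) else NA_real_,
               se_sse = sem(s1), se_no_sse = sem(s0),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
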