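#' Dosing schedule over the model horizon
#'
#' Doses are given at weeks 0, `interval`, `2 * interval`, ... strictly
#' below the horizon, so a 4-weekly schedule over 48 weeks delivers 12
#' doses (weeks 0-44) and a 12-weekly schedule delivers 4 (weeks 0-36).
#'
#' @param interval_weeks Weeks between doses.
#' @param horizon_weeks Model horizon in weeks.
#' @return An object of class `bta_schedule` with element `doses`.
#' @export
#' @examples
#' bta_schedule(4)$doses   # 12
#' bta_schedule(12)$doses  # 4
bta_schedule <- function(interval_weeks, horizon_weeks = 48L) {
  stopifnot(interval_weeks >= 1, horizon_weeks >= 1)
  doses <- horizon_weeks %/% interval_weeks
  if (doses < 1) {
    stop("validation error: schedule delivers no doses within the horizon",
         call. = FALSE)
  }
  structure(list(interval_weeks = as.integer(interval_weeks),
                 horizon_weeks = as.integer(horizon_weeks),
                 doses = as.integer(doses)),
            class = "bta_schedule")
}

#' Weighted bone-targeted agent treatment cost
#'
#' The weighted per-horizon BTA cost for one arm:
#' `sum over drugs of weight * doses * (drug_cost + administration_cost)`,
#' where weights are the arm's drug-mix shares. Every drug in the mix
#' must carry both a `DRUG` and an `ADMINISTRATION` row.
#'
#' @param unit_costs A `bta_unit_costs` table (see [read_unit_costs()]).
#' @param schedule A [bta_schedule()].
#' @param arm `"FOUR_WEEKLY"` or `"TWELVE_WEEKLY"`.
#' @return Cost in CAD.
#' @export
weighted_bta_cost <- function(unit_costs, schedule,
                              arm = c("FOUR_WEEKLY", "TWELVE_WEEKLY")) {
  arm <- match.arg(arm)
  stopifnot(inherits(schedule, "bta_schedule"))
  unit_costs <- validate_unit_costs(unit_costs)
  drugs <- unit_costs[unit_costs$arm == arm &
                        unit_costs$category == "DRUG", ]
  admin <- unit_costs[unit_costs$arm == arm &
                        unit_costs$category == "ADMINISTRATION", ]
  if (nrow(drugs) == 0) {
    stop("configuration error: no DRUG rows for arm ", arm, call. = FALSE)
  }
  idx <- match(drugs$item, admin$item)
  if (anyNA(idx)) {
    stop("configuration error: drug(s) without an administration cost: ",
         paste(drugs$item[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  per_dose <- drugs$unit_cost + admin$unit_cost[idx]
  sum(drugs$weight * schedule$doses * per_dose)
}

#' Weighted symptomatic skeletal event cost
#'
#' The arm's event-type-mix-weighted SSE cost:
#' `sum over event types of weight * event_cost`. Weights are the
#' proportion of event-experiencing patients in that arm with each event
#' type and must sum to 1.
#'
#' @param event_costs A `bta_unit_costs` table containing `SSE_EVENT`
#'   rows (other categories are ignored).
#' @param arm `"FOUR_WEEKLY"` or `"TWELVE_WEEKLY"`.
#' @return Cost in CAD.
#' @export
weighted_sse_cost <- function(event_costs,
                              arm = c("FOUR_WEEKLY", "TWELVE_WEEKLY")) {
  arm <- match.arg(arm)
  need <- c("item", "category", "arm", "unit_cost", "weight")
  stopifnot(all(need %in% names(event_costs)))
  rows <- event_costs[event_costs$arm == arm &
                        event_costs$category == "SSE_EVENT", ]
  if (nrow(rows) == 0) {
    stop("configuration error: no SSE_EVENT rows for arm ", arm,
         call. = FALSE)
  }
  if (abs(sum(rows$weight) - 1) > 1e-9) {
    stop("validation error: SSE-type weights for arm ", arm,
         " sum to ", sum(rows$weight), ", not 1", call. = FALSE)
  }
  if (any(rows$unit_cost < 0)) {
    stop("validation error: negative SSE event cost", call. = FALSE)
  }
  sum(rows$weight * rows$unit_cost)
}

#' Per-arm weighted cost summary
#'
#' Convenience wrapper computing both weighted costs for both arms from
#' one unit-cost table, using the standard 4- and 12-weekly schedules.
#'
#' @param unit_costs A `bta_unit_costs` table.
#' @param horizon_weeks Model horizon in weeks.
#' @return Data frame with columns `arm`, `doses`, `cost_bta`, `cost_sse`.
#' @export
arm_cost_summary <- function(unit_costs, horizon_weeks = 48L) {
  sched <- list(FOUR_WEEKLY = bta_schedule(4, horizon_weeks),
                TWELVE_WEEKLY = bta_schedule(12, horizon_weeks))
  do.call(rbind, lapply(names(sched), function(arm) {
    data.frame(arm = arm,
               doses = sched[[arm]]$doses,
               cost_bta = weighted_bta_cost(unit_costs, sched[[arm]], arm),
               cost_sse = weighted_sse_cost(unit_costs, arm))
  }))
}
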