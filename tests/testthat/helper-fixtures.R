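# Shared fixtures: everything is built in code at test time.

base_inputs <- function(...) default_model_inputs(...)

fixture_valueset <- function() load_value_set()
fixture_mapping <- function() qlu_mapping()

# Small, fast synthetic trial for unit tests (acceptance tests use the
# default study-sized configuration).
small_trial <- function(seed = 7L, ...) {
  generate_trial(generator_config(n_4wk = 60L, n_12wk = 60L,
                                  seed = seed, ...))
}

# Point-mass distributions at the base-case values, for degenerate-PSA
# checks.
point_distributions <- function(inputs, branches) {
  vals <- c(
    p_sse_4wk = inputs$arm_4wk$p_sse,
    relative_risk = inputs$relative_risk,
    cost_bta_4wk = inputs$arm_4wk$cost_bta,
    cost_bta_12wk = inputs$arm_12wk$cost_bta,
    cost_sse_4wk = inputs$arm_4wk$cost_sse,
    cost_sse_12wk = inputs$arm_12wk$cost_sse,
    qaly_sse_4wk = branches$arm_4wk$qaly_sse,
    qaly_no_sse_4wk = branches$arm_4wk$qaly_no_sse,
    qaly_sse_12wk = branches$arm_12wk$qaly_sse,
    qaly_no_sse_12wk = branches$arm_12wk$qaly_no_sse)
  lapply(setNames(names(vals), names(vals)), function(nm) {
    fit_distribution(list(name = nm, baseline = vals[[nm]],
                          lower = vals[[nm]], upper = vals[[nm]]))
  })
}

# A response row with all 30 items set to one value (1-4 scale items;
# the two global items get a consistent 1-7 value).
uniform_response <- function(patient_id, arm, visit_week, level,
                             global = NULL) {
  if (is.null(global)) global <- c(7, 5, 3, 1)[level]
  items <- as.list(c(rep(level, 28), global, global))
  names(items) <- paste0("q", 1:30)
  cbind(data.frame(patient_id = patient_id, arm = arm,
                   visit_week = visit_week, stringsAsFactors = FALSE),
        as.data.frame(items))
}
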