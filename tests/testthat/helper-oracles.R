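# Shared fixtures and independent oracles.

base_params <- default_parameters()

# Independently coded transition-row builder: enumerates the ordered
# event paths (background death first, then recurrence among survivors,
# then severity) and accumulates destination mass via a "states only
# worsen" rule. Used to cross-check build_transition_row().
oracle_transition_row <- function(state, age, p_rec, params) {
  tr <- params$transitions
  severity <- c(
    minor = tr$prop_minor,
    moderate = tr$prop_moderate,
    fatal = tr$prop_fatal
  )
  rank <- c(stable = 1, post_minor = 2, post_moderate = 3, dead = 4)
  worsen <- function(from, event_state) {
    names(rank)[max(rank[from], rank[event_state])]
  }
  dest <- c(stable = 0, post_minor = 0, post_moderate = 0, dead = 0)
  if (state == "dead") {
    dest["dead"] <- 1
    return(dest)
  }
  q <- background_mortality(age, tr$mortality)
  if (state == "post_moderate") q <- min(1, tr$rr_moderate_nonstroke_death * q)
  dest["dead"] <- dest["dead"] + q
  dest[state] <- dest[state] + (1 - q) * (1 - p_rec)
  event_state <- c(minor = "post_minor", moderate = "post_moderate", fatal = "dead")
  for (sev in names(severity)) {
    to <- worsen(state, event_state[[sev]])
    dest[to] <- dest[to] + (1 - q) * p_rec * severity[[sev]]
  }
  dest
}

# Degenerate parameter helpers used by the closed-form engine checks.
# These bypass load_parameters() validation deliberately (e.g. zero or
# unit mortality in every band) to pin down engine edge cases.
flat_mortality_params <- function(params, q3m) {
  params$transitions$mortality$q3m <- rep(q3m, nrow(params$transitions$mortality))
  params
}

unit_utility_params <- function(params) {
  for (k in names(params$utilities)) params$utilities[[k]] <- 1
  params
}

zero_recurrence_params <- function(params) {
  params$transitions$p_rec_closure <- 0
  params$transitions$p_rec_medical <- 0
  params
}

# Collapse every sensitivity range onto the base value (degenerate
# distributions: the PSA then has nothing to sample).
degenerate_ranges_params <- function(params) {
  params$ranges$low <- params$ranges$base
  params$ranges$high <- params$ranges$base
  params
}

run_base_pair <- function(params) {
  cl <- run_cohort(closure_strategy(params), params, keep_trace = FALSE)
  me <- run_cohort(medical_strategy(params), params, keep_trace = FALSE)
  cea_compare(cl, me, params = params)
}
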