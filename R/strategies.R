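# Treatment strategies: an arm is an upfront cost, a per-cycle
# antithrombotic cost applied to stable-state occupancy, and a
# stable-state utility profile. Post-stroke drug costs are considered
# part of the quarterly post-stroke maintenance costs, so per-cycle
# medication accrues in the stable state only (and never in Dead).

.regimen_ids <- c("aspirin", "warfarin", "clopidogrel",
                  "aspirin_dipyridamole", "aspirin_clopidogrel",
                  "dabigatran", "rivaroxaban")

# Quarterly cost of one antithrombotic regimen. Pack drugs (aspirin 30 x
# 100 mg, clopidogrel 28 x 75 mg) are costed as one pack per month, three
# packs per quarter; per-tablet drugs use 91.25 days per quarter.
# Warfarin adds INR monitoring at its annual frequency / 4.
.regimen_cost <- function(regimen, costs) {
  switch(regimen,
    aspirin = 3 * costs$aspirin_pack,
    clopidogrel = 3 * costs$clopidogrel_pack,
    aspirin_clopidogrel = 3 * (costs$aspirin_pack + costs$clopidogrel_pack),
    # dipyridamole has no unit price; the combination is costed as aspirin
    aspirin_dipyridamole = 3 * costs$aspirin_pack,
    warfarin = QUARTER_DAYS * costs$warfarin_tablet +
      costs$inr_test * costs$inr_tests_per_year / 4,
    dabigatran = 2 * QUARTER_DAYS * costs$dabigatran_tablet, # 110 mg twice daily
    rivaroxaban = QUARTER_DAYS * costs$rivaroxaban_tablet,   # 20 mg once daily
    abort(sprintf("Unknown medication regimen `%s`.", regimen))
  )
}

.new_strategy <- function(name, arm, upfront, med_cost, stable_utility, medication) {
  structure(
    list(name = name, arm = arm, upfront_cost = upfront,
         medication = medication, medication_cost = med_cost,
         stable_utility = stable_utility),
    class = "pfo_strategy"
  )
}

#' Define the PFO-closure strategy
#'
#' The closure arm pays the device, procedure and other hospital costs
#' upfront at cycle 0, takes aspirin plus clopidogrel for the first month
#' followed by aspirin monotherapy through month 6 (one clopidogrel pack
#' plus three aspirin packs in cycle 1, three aspirin packs in cycle 2,
#' nothing thereafter), and carries the post-procedure stable-state
#' utility: the "early" value during the first two cycles, the "late"
#' value afterwards.
#'
#' @param params A `pfo_params` object.
#' @return A `pfo_strategy` object with fields `upfront_cost`,
#'   `medication_cost(cycle)` (USD per cycle, stable state) and
#'   `stable_utility(cycle)`.
#' @examples
#' s <- closure_strategy(default_parameters())
#' s$upfront_cost # 6635
#' s$medication_cost(1) # 21.5
#' @export
closure_strategy <- function(params) {
  co <- params$costs
  u <- params$utilities
  med <- function(cycle) {
    ifelse(cycle == 1, co$clopidogrel_pack + 3 * co$aspirin_pack,
      ifelse(cycle == 2, 3 * co$aspirin_pack, 0)
    )
  }
  ustable <- function(cycle) {
    ifelse(cycle <= 2, u$u_stable_closure_early, u$u_stable_closure_late)
  }
  .new_strategy("PFO closure", "closure",
    upfront = co$device + co$procedure + co$other_closure,
    med_cost = med, stable_utility = ustable, medication = "post-procedure antiplatelet course"
  )
}

#' Define the medical-therapy strategy
#'
#' Medical therapy has no upfront cost; patients take a lifelong
#' antithrombotic while in the stable state and carry the medical-arm
#' stable utility in every cycle. The default `"trial_mix"` medication
#' costs each cycle as the weighted average of the regimens reported for
#' the source trial's medical arm (`params$regimen_mix`); single-regimen
#' alternatives (`"aspirin"`, `"warfarin"` with INR monitoring,
#' `"dabigatran"`, `"rivaroxaban"`) support the scenario analyses.
#'
#' @param params A `pfo_params` object.
#' @param medication `"trial_mix"` or one of the regimen identifiers above.
#' @return A `pfo_strategy` object.
#' @examples
#' medical_strategy(default_parameters(), "aspirin")$medication_cost(10) # 6.9
#' @export
medical_strategy <- function(params, medication = "trial_mix") {
  co <- params$costs
  u <- params$utilities
  per_cycle <- if (identical(medication, "trial_mix")) {
    mix <- params$regimen_mix
    sum(mix * vapply(names(mix), .regimen_cost, numeric(1), costs = co))
  } else {
    if (!medication %in% .regimen_ids) {
      abort(sprintf(
        "Unknown medication `%s`; use \"trial_mix\" or one of: %s.",
        medication, paste(.regimen_ids, collapse = ", ")
      ))
    }
    .regimen_cost(medication, co)
  }
  .new_strategy("Medical therapy", "medical",
    upfront = 0,
    med_cost = function(cycle) rep(per_cycle, length(cycle)),
    stable_utility = function(cycle) rep(u$u_stable_medical, length(cycle)),
    medication = medication
  )
}

#' @export
print.pfo_strategy <- function(x, ...) {
  cat(sprintf(
    "<pfo_strategy> %s (arm: %s)\n  upfront %.0f USD; medication: %s; cycle-1 medication %.2f USD\n",
    x$name, x$arm, x$upfront_cost, x$medication, x$medication_cost(1)
  ))
  invisible(x)
}

.scenario_ids <- c("base", "warfarin", "dabigatran", "rivaroxaban", "sf6d", "eq5d")

#' Build the arm pair for a named scenario
#'
#' `"base"` returns the base-case arms. The medication scenarios
#' (`"warfarin"`, `"dabigatran"`, `"rivaroxaban"`) replace the medical
#' arm's antithrombotic and leave everything else unchanged. The utility
#' scenarios (`"sf6d"`, `"eq5d"`) override the stable-state and
#' post-stroke utilities in both arms with the alternative instrument's
#' values from the configuration.
#'
#' @param params A `pfo_params` object.
#' @param scenario One of `"base"`, `"warfarin"`, `"dabigatran"`,
#'   `"rivaroxaban"`, `"sf6d"`, `"eq5d"`.
#' @return A list with elements `params` (possibly modified), `closure`
#'   and `medical` (the two `pfo_strategy` objects), and `scenario`.
#' @examples
#' sc <- apply_scenario(default_parameters(), "warfarin")
#' sc$medical$medication_cost(1) # 70.3
#' @export
apply_scenario <- function(params, scenario = "base") {
  scenario <- match.arg(scenario, .scenario_ids)
  if (scenario %in% c("sf6d", "eq5d")) {
    ov <- params$scenarios[[scenario]]$utilities
    if (is.null(ov)) {
      abort(sprintf("Scenario `%s` has no utility overrides in the configuration.", scenario))
    }
    for (k in names(ov)) params$utilities[[paste0("u_", k)]] <- ov[[k]]
    validate_parameters(params)
  }
  medication <- if (scenario %in% c("warfarin", "dabigatran", "rivaroxaban")) {
    scenario
  } else {
    "trial_mix"
  }
  list(
    params = params,
    closure = closure_strategy(params),
    medical = medical_strategy(params, medication),
    scenario = scenario
  )
}
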