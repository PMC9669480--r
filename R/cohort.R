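# Markov cohort engine. Four states: stable, post-minor stroke,
# post-moderate stroke, dead. Competing risks are ordered: background
# (non-stroke) death first, then recurrent stroke among its survivors,
# split minor/moderate/fatal. States only worsen: a minor recurrence in
# the post-moderate state leaves occupancy in post-moderate.

#' One row of the per-cycle transition matrix
#'
#' Destination probabilities for a cohort fraction occupying `state` at
#' the start of a cycle. With background mortality `q` (multiplied by the
#' non-stroke-death relative risk in the post-moderate state, capped at
#' 1) and per-cycle recurrence probability `p_rec`, survivors of
#' background death suffer a recurrent stroke with probability `p_rec`,
#' split into minor/moderate/fatal by the severity proportions.
#'
#' @param state One of `"stable"`, `"post_minor"`, `"post_moderate"`, `"dead"`.
#' @param age Age in years at the start of the cycle.
#' @param p_rec Per-cycle recurrent-stroke probability of the arm.
#' @param params A `pfo_params` object.
#' @return Named numeric vector of destination probabilities over the four
#'   states (sums to 1).
#' @examples
#' build_transition_row("stable", 46, 0.00145316446292076, default_parameters())
#' @export
build_transition_row <- function(state, age, p_rec, params) {
  tr <- params$transitions
  q <- background_mortality(age, tr$mortality)
  pm <- tr$prop_minor
  pmo <- tr$prop_moderate
  pf <- tr$prop_fatal
  row <- switch(state,
    stable = c(
      stable = (1 - q) * (1 - p_rec),
      post_minor = (1 - q) * p_rec * pm,
      post_moderate = (1 - q) * p_rec * pmo,
      dead = q + (1 - q) * p_rec * pf
    ),
    post_minor = c(
      stable = 0,
      post_minor = (1 - q) * (1 - p_rec) + (1 - q) * p_rec * pm,
      post_moderate = (1 - q) * p_rec * pmo,
      dead = q + (1 - q) * p_rec * pf
    ),
    post_moderate = {
      q2 <- min(1, tr$rr_moderate_nonstroke_death * q)
      c(
        stable = 0,
        post_minor = 0,
        post_moderate = (1 - q2) * (1 - p_rec * pf),
        dead = q2 + (1 - q2) * p_rec * pf
      )
    },
    dead = c(stable = 0, post_minor = 0, post_moderate = 0, dead = 1),
    abort(sprintf("Unknown state `%s`.", state))
  )
  row
}

# Per-cycle discount factors for cycles 1..n (rewards accrue within the
# cycle). "annual": discrete annual compounding, rewards in completed
# year y = floor((k-1) * cycle_length) discounted by (1+r)^-y (the
# default; matches discrete-time decision-tree software). "midcycle":
# continuous annual-equivalent discounting at the cycle midpoint.
.discount_factors <- function(n, rate, cycle_length, discounting) {
  k <- seq_len(n)
  switch(discounting,
    annual = (1 + rate)^(-floor((k - 1) * cycle_length)),
    midcycle = (1 + rate)^(-(k - 0.5) * cycle_length),
    abort("`discounting` must be \"annual\" or \"midcycle\".")
  )
}

#' Run the half-cycle-corrected Markov cohort simulation for one arm
#'
#' Starts a cohort 100% stable at the model start age and iterates the
#' quarterly transition rows over the horizon. State rewards (utility,
#' quarterly post-stroke maintenance costs, stable-state medication
#' costs) accrue on trapezoidal occupancy (the mean of the cycle-start
#' and cycle-end state vectors, the half-cycle correction); one-time
#' rewards (stroke event costs, the stroke-death cost, and the
#' recurrent-event utility that replaces the destination-state utility
#' for the transitioning fraction during its event cycle) accrue on the
#' cycle's event flows. The upfront procedure bundle is charged at time
#' zero, undiscounted.
#'
#' @param strategy A `pfo_strategy` from [closure_strategy()] or
#'   [medical_strategy()].
#' @param params A `pfo_params` object.
#' @param horizon Time horizon in years; defaults to the configured 30.
#' @param discounting `"annual"` (discrete annual compounding, default) or
#'   `"midcycle"` (continuous discounting at cycle midpoints).
#' @param keep_trace If `FALSE`, skip building the per-cycle trace tibble
#'   (used by the sensitivity analyses for speed).
#' @return A `pfo_cohort` object: list with `outcome` (discounted and
#'   undiscounted total cost, QALY and life-years), `trace` (per-cycle
#'   occupancy, event flows and discounted cycle rewards) and run
#'   metadata. `glance()` returns the outcome as a one-row tibble;
#'   `tidy()` returns the trace.
#' @examples
#' p <- default_parameters()
#' run_cohort(closure_strategy(p), p)
#' @export
run_cohort <- function(strategy, params,
                       horizon = params$model$horizon,
                       discounting = params$model$discounting,
                       keep_trace = TRUE) {
  m <- params$model
  tr <- params$transitions
  u <- params$utilities
  co <- params$costs
  cl <- m$cycle_length
  n <- horizon / cl
  if (n <= 0 || abs(n - round(n)) > 1e-9) {
    abort("`horizon` must be a positive multiple of the cycle length.")
  }
  n <- as.integer(round(n))
  if (m$start_age + horizon > max(tr$mortality$age_high)) {
    abort("`horizon` exceeds mortality table coverage for this start age.")
  }

  p <- switch(strategy$arm,
    closure = tr$p_rec_closure,
    medical = tr$p_rec_medical,
    abort("`strategy$arm` must be \"closure\" or \"medical\".")
  )
  pm <- tr$prop_minor; pmo <- tr$prop_moderate; pf <- tr$prop_fatal
  k <- seq_len(n)
  ages <- m$start_age + cl * (k - 1)
  q <- background_mortality(ages, tr$mortality)
  q2 <- pmin(1, tr$rr_moderate_nonstroke_death * q)
  med <- strategy$medication_cost(k)
  u_stable <- strategy$stable_utility(k)
  disc <- .discount_factors(n, m$discount_rate, cl, discounting)

  # occupancy at cycle boundaries 0..n and flows within each cycle
  occ <- matrix(0, n + 1L, 4L, dimnames = list(NULL, STATES))
  occ[1L, "stable"] <- 1
  f_minor <- f_moderate <- f_stroke_death <- f_other_death <- numeric(n)
  f_minor_to_minor <- f_nonfatal_in_moderate <- numeric(n)
  for (i in k) {
    s <- occ[i, 1L]; mi <- occ[i, 2L]; mo <- occ[i, 3L]
    sv <- (1 - q[i]) # background-death survival, stable/post-minor
    sv2 <- (1 - q2[i]) # post-moderate
    f_minor_to_minor[i] <- sv * p * pm * (s + mi)
    f_nonfatal_in_moderate[i] <- sv2 * p * (pm + pmo) * mo
    f_minor[i] <- sv * p * pm * (s + mi) + sv2 * p * pm * mo
    f_moderate[i] <- sv * p * pmo * (s + mi) + sv2 * p * pmo * mo
    f_stroke_death[i] <- sv * p * pf * (s + mi) + sv2 * p * pf * mo
    f_other_death[i] <- q[i] * (s + mi) + q2[i] * mo
    occ[i + 1L, 1L] <- s * sv * (1 - p)
    occ[i + 1L, 2L] <- mi * sv * (1 - p) + f_minor_to_minor[i]
    occ[i + 1L, 3L] <- mo * sv2 * (1 - p) + f_nonfatal_in_moderate[i] +
      sv * p * pmo * (s + mi)
    occ[i + 1L, 4L] <- occ[i, 4L] + f_stroke_death[i] + f_other_death[i]
  }

  start <- occ[k, , drop = FALSE]
  end <- occ[k + 1L, , drop = FALSE]
  trap <- 0.5 * (start + end) # half-cycle corrected occupancy

  # utility: trapezoidal state occupancy, with the recurrent-event
  # utility replacing the destination utility for the half cycle the
  # transitioning fraction spends in its destination state
  qaly_k <- cl * (trap[, 1L] * u_stable + trap[, 2L] * u$u_post_minor +
    trap[, 3L] * u$u_post_moderate)
  # flows by destination utility: minor recurrences from stable/post-minor
  # land on the post-minor utility, everything non-fatal else on post-moderate
  adj <- f_minor_to_minor * (u$u_recurrent_event - u$u_post_minor) +
    (f_moderate + (f_minor - f_minor_to_minor)) *
      (u$u_recurrent_event - u$u_post_moderate)
  qaly_k <- qaly_k + cl * 0.5 * adj
  alive <- trap[, 1L] + trap[, 2L] + trap[, 3L]
  ly_k <- cl * alive
  cost_k <- trap[, 2L] * co$q_post_minor + trap[, 3L] * co$q_post_moderate +
    med * trap[, 1L] +
    f_minor * co$minor_event + f_moderate * co$moderate_event +
    f_stroke_death * co$stroke_death

  outcome <- list(
    cost_discounted = strategy$upfront_cost + sum(disc * cost_k),
    qaly_discounted = sum(disc * qaly_k),
    ly_discounted = sum(disc * ly_k),
    cost_undiscounted = strategy$upfront_cost + sum(cost_k),
    qaly_undiscounted = sum(qaly_k),
    ly_undiscounted = sum(ly_k)
  )

  trace <- NULL
  if (keep_trace) {
    trace <- tibble::tibble(
      cycle = 0:n,
      age = m$start_age + cl * (0:n),
      stable = occ[, 1L], post_minor = occ[, 2L],
      post_moderate = occ[, 3L], dead = occ[, 4L],
      flow_minor = c(NA_real_, f_minor),
      flow_moderate = c(NA_real_, f_moderate),
      flow_stroke_death = c(NA_real_, f_stroke_death),
      flow_other_death = c(NA_real_, f_other_death),
      cycle_cost_discounted = c(strategy$upfront_cost, disc * cost_k),
      cycle_qaly_discounted = c(0, disc * qaly_k)
    )
  }

  structure(
    list(
      strategy = strategy$name, arm = strategy$arm,
      medication = strategy$medication,
      outcome = outcome, trace = trace,
      horizon = horizon, discounting = discounting,
      discount_rate = m$discount_rate, n_cycles = n
    ),
    class = "pfo_cohort"
  )
}

#' @export
print.pfo_cohort <- function(x, ...) {
  o <- x$outcome
  cat(sprintf(
    "<pfo_cohort> %s, %g-year horizon (%d cycles), %s discounting at %.0f%%\n",
    x$strategy, x$horizon, x$n_cycles, x$discounting, 100 * x$discount_rate
  ))
  cat(sprintf(
    "  discounted:   cost %8.0f USD  QALY %6.2f  LY %6.2f\n",
    o$cost_discounted, o$qaly_discounted, o$ly_discounted
  ))
  cat(sprintf(
    "  undiscounted: cost %8.0f USD  QALY %6.2f  LY %6.2f\n",
    o$cost_undiscounted, o$qaly_undiscounted, o$ly_undiscounted
  ))
  invisible(x)
}

#' @rdname run_cohort
#' @param x A `pfo_cohort` object.
#' @param ... Unused.
#' @method glance pfo_cohort
#' @export
glance.pfo_cohort <- function(x, ...) {
  tibble::as_tibble(c(list(strategy = x$strategy), x$outcome))
}

#' @rdname run_cohort
#' @method tidy pfo_cohort
#' @export
tidy.pfo_cohort <- function(x, ...) {
  if (is.null(x$trace)) abort("Cohort was run with `keep_trace = FALSE`.")
  x$trace
}

#' Export a cohort trace to CSV
#'
#' Writes the per-cycle trace (occupancy, event flows, discounted cycle
#' rewards) at full precision.
#'
#' @param cohort A `pfo_cohort` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(cohort, path) {
  write.csv(tidy(cohort), path, row.names = FALSE)
  invisible(path)
}
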