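# Individual-level Monte Carlo simulator. Walks patients through the
# same per-cycle transition rules as the cohort engine, with identical
# reward, half-cycle and discounting conventions, so that mean outcomes
# converge to the cohort expectation. Serves as a brute-force validation
# oracle for run_cohort().

#' Simulate individual patient trajectories
#'
#' Each patient starts stable at the model start age and walks the
#' quarterly transition rows: background (non-stroke) death first
#' (risk-ratio-adjusted in the post-moderate state), then recurrent
#' stroke among survivors, severity drawn minor/moderate/fatal. Rewards
#' follow the cohort engine's conventions exactly: utilities and
#' state costs on the trapezoid of cycle-start and cycle-end states,
#' recurrent-event utility replacing the destination utility for the
#' event half-cycle, event costs on transitions, medication on
#' stable-state occupancy, and the same discount factors.
#'
#' @param n Number of patients.
#' @param strategy A `pfo_strategy`.
#' @param params A `pfo_params` object.
#' @param seed Integer seed; reproducible and RNG-state preserving.
#' @param horizon,discounting As in [run_cohort()].
#' @param keep_states If `TRUE`, keep the full patient-by-cycle state
#'   matrix (memory: `n * (cycles + 1)` integers).
#' @return A `pfo_microsim` object: per-patient discounted outcomes
#'   (`patients` tibble), per-cycle occupancy proportions
#'   (`occupancy`), event counts, and mean/SE summaries.
#' @export
simulate_patients <- function(n, strategy, params, seed = 1,
                              horizon = params$model$horizon,
                              discounting = params$model$discounting,
                              keep_states = FALSE) {
  if (n < 1) abort("`n` must be >= 1.")
  m <- params$model
  tr <- params$transitions
  u <- params$utilities
  co <- params$costs
  cl <- m$cycle_length
  n_cycles <- as.integer(round(horizon / cl))
  if (abs(horizon / cl - n_cycles) > 1e-9 || n_cycles <= 0) {
    abort("`horizon` must be a positive multiple of the cycle length.")
  }

  p <- switch(strategy$arm, closure = tr$p_rec_closure, medical = tr$p_rec_medical)
  pm <- tr$prop_minor; pmo <- tr$prop_moderate; pf <- tr$prop_fatal
  k <- seq_len(n_cycles)
  ages <- m$start_age + cl * (k - 1)
  qk <- background_mortality(ages, tr$mortality)
  med <- strategy$medication_cost(k)
  u_stable <- strategy$stable_utility(k)
  disc <- .discount_factors(n_cycles, m$discount_rate, cl, discounting)
  rr <- tr$rr_moderate_nonstroke_death

  S <- 1L; MI <- 2L; MO <- 3L; DE <- 4L
  u_state <- function(i) c(0, u$u_post_minor, u$u_post_moderate, 0)[i]
  maint <- c(0, co$q_post_minor, co$q_post_moderate, 0)

  state <- rep(S, n)
  cost <- rep(strategy$upfront_cost, n)
  qaly <- numeric(n)
  ly <- numeric(n)
  occupancy <- matrix(0L, n_cycles + 1L, 4L, dimnames = list(NULL, STATES))
  occupancy[1L, S] <- n
  events <- c(minor = 0, moderate = 0, stroke_death = 0, other_death = 0)
  states_mat <- if (keep_states) matrix(S, n, n_cycles + 1L) else NULL

  .with_seed(seed, {
    for (i in k) {
      alive <- state != DE
      q_i <- ifelse(state == MO, pmin(1, rr * qk[i]), qk[i])
      die_bg <- runif(n) < q_i & alive
      rec <- runif(n) < p & alive & !die_bg
      sev <- runif(n)
      rec_minor <- rec & sev < pm
      rec_moderate <- rec & sev >= pm & sev < pm + pmo
      rec_fatal <- rec & sev >= pm + pmo

      new_state <- state
      new_state[die_bg | rec_fatal] <- DE
      new_state[rec_minor & state == S] <- MI
      new_state[rec_moderate & (state == S | state == MI)] <- MO
      # recurrences in post-stroke states otherwise stay put (states only worsen)

      events["minor"] <- events["minor"] + sum(rec_minor)
      events["moderate"] <- events["moderate"] + sum(rec_moderate)
      events["stroke_death"] <- events["stroke_death"] + sum(rec_fatal)
      events["other_death"] <- events["other_death"] + sum(die_bg)

      # trapezoid utility with event-cycle replacement for non-fatal recurrences
      u_start <- ifelse(state == S, u_stable[i], u_state(state))
      u_end <- ifelse(new_state == S, u_stable[i], u_state(new_state))
      nonfatal <- rec_minor | rec_moderate
      u_end[nonfatal] <- u$u_recurrent_event
      qaly <- qaly + disc[i] * cl * 0.5 * (u_start * alive + u_end * (new_state != DE))
      ly <- ly + disc[i] * cl * 0.5 * (alive + (new_state != DE))

      c_state <- 0.5 * (maint[state] + maint[new_state]) +
        med[i] * 0.5 * ((state == S) + (new_state == S))
      c_event <- rec_minor * co$minor_event + rec_moderate * co$moderate_event +
        rec_fatal * co$stroke_death
      cost <- cost + disc[i] * (c_state + c_event)

      state <- new_state
      occupancy[i + 1L, ] <- tabulate(state, 4L)
      if (keep_states) states_mat[, i + 1L] <- state
    }
  })

  structure(
    list(
      n = n, arm = strategy$arm, strategy = strategy$name, seed = seed,
      horizon = horizon, discounting = discounting,
      patients = tibble::tibble(cost = cost, qaly = qaly, ly = ly),
      occupancy = occupancy / n,
      events = events / n,
      summary = tibble::tibble(
        outcome = c("cost", "qaly", "ly"),
        mean = c(mean(cost), mean(qaly), mean(ly)),
        se = c(stats::sd(cost), stats::sd(qaly), stats::sd(ly)) / sqrt(n)
      ),
      states = states_mat
    ),
    class = "pfo_microsim"
  )
}

#' @export
print.pfo_microsim <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<pfo_microsim> %s, %d patients (seed %s)\n", x$strategy, x$n, format(x$seed)
  ))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  mean %-5s %10.2f (SE %.3g)\n", s$outcome[i], s$mean[i], s$se[i]))
  }
  invisible(x)
}

#' Compare microsimulation results to a cohort trace
#'
#' Checks that the microsimulated occupancy stays within a binomial
#' standard-error envelope of the cohort trace at every cycle, and that
#' mean discounted cost/QALY/LY lie within `tol_se` standard errors of
#' the cohort outcome. `tol_se` is interpreted family-wise: the
#' occupancy envelope is checked over every (cycle, state) cell, so the
#' per-cell threshold is Sidak-adjusted to give the whole comparison the
#' same false-alarm probability as a single `tol_se`-standard-error
#' check (a literal per-cell rule would flag noise with near certainty
#' over ~500 cells). The adjusted per-cell threshold is returned as
#' `cell_threshold`. The three outcome means use `tol_se` directly.
#'
#' @param sim A `pfo_microsim` object.
#' @param cohort The matching `pfo_cohort` (same arm, parameters,
#'   horizon and discounting), run with `keep_trace = TRUE`.
#' @param tol_se Tolerance in standard-error units (default 3).
#' @return A list with `occupancy` (per-cycle max |deviation| and its SE
#'   bound), `outcomes` (deviations in SE units), `cell_threshold`, and `ok`.
#' @export
compare_to_cohort <- function(sim, cohort, tol_se = 3) {
  if (is.null(cohort$trace)) abort("`cohort` must be run with `keep_trace = TRUE`.")
  expected <- as.matrix(cohort$trace[, STATES])
  if (nrow(expected) != nrow(sim$occupancy)) {
    abort("Mismatched horizons between microsimulation and cohort trace.")
  }
  dev <- sim$occupancy - expected
  se <- sqrt(pmax(expected * (1 - expected), 1e-12) / sim$n)
  alpha_single <- 2 * stats::pnorm(-tol_se)
  z_cell <- stats::qnorm(1 - alpha_single / (2 * length(expected)))
  occ_ok <- abs(dev) <= z_cell * se | abs(dev) < 1e-12
  occ_tbl <- tibble::tibble(
    cycle = cohort$trace$cycle,
    max_abs_deviation = apply(abs(dev), 1, max),
    max_se_units = apply(abs(dev) / pmax(se, 1e-15), 1, max)
  )

  o <- cohort$outcome
  s <- sim$summary
  target <- c(cost = o$cost_discounted, qaly = o$qaly_discounted, ly = o$ly_discounted)
  z <- (s$mean - target[s$outcome]) / pmax(s$se, 1e-15)
  out_tbl <- tibble::tibble(
    outcome = s$outcome, microsim_mean = s$mean,
    cohort_value = unname(target[s$outcome]), se = s$se, z = unname(z)
  )
  list(
    occupancy = occ_tbl,
    outcomes = out_tbl,
    ok = all(occ_ok) && all(abs(z) <= tol_se),
    tol_se = tol_se,
    cell_threshold = z_cell
  )
}
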