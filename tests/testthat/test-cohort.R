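test_that("an immortal event-free cohort accrues exactly one QALY per year", {
  p <- zero_recurrence_params(flat_mortality_params(unit_utility_params(base_params), 0))
  p$model$discount_rate <- 0
  res <- run_cohort(medical_strategy(p), p, horizon = 1)
  expect_equal(res$outcome$qaly_discounted, 1, tolerance = 1e-12)
  expect_equal(res$outcome$ly_discounted, 1, tolerance = 1e-12)
  expect_equal(res$outcome$qaly_undiscounted, 1, tolerance = 1e-12)
  # occupancy never leaves the stable state
  tr <- tidy(res)
  expect_true(all(tr$stable == 1))
})

test_that("immediate death yields the half-cycle-corrected eighth of a year", {
  # unit background mortality: full occupancy at cycle start, zero at end;
  # the trapezoid credits half of one 0.25-year cycle
  p <- flat_mortality_params(unit_utility_params(base_params), 1)
  p$model$discount_rate <- 0
  res <- run_cohort(medical_strategy(p), p, horizon = 0.25)
  expect_equal(res$outcome$ly_discounted, 0.125, tolerance = 1e-12)
  expect_equal(res$outcome$qaly_discounted, 0.125, tolerance = 1e-12)
})

test_that("traces conserve occupancy, keep dead monotone and survival non-increasing", {
  for (p in list(base_params, make_fixture_parameters(7, 1))) {
    for (make in list(closure_strategy, medical_strategy)) {
      tr <- tidy(run_cohort(make(p), p))
      occ <- as.matrix(tr[, c("stable", "post_minor", "post_moderate", "dead")])
      expect_equal(rowSums(occ), rep(1, nrow(occ)), tolerance = 1e-12)
      expect_true(all(occ >= -1e-15))
      expect_true(all(diff(tr$dead) >= 0))
      alive <- 1 - tr$dead
      expect_true(all(diff(alive) <= 1e-15))
      flows <- as.matrix(tr[-1, c("flow_minor", "flow_moderate",
                                  "flow_stroke_death", "flow_other_death")])
      expect_true(all(flows >= 0))
      # deaths flowing in reconcile with the dead-state increments
      expect_equal(diff(tr$dead),
                   flows[, "flow_stroke_death"] + flows[, "flow_other_death"],
                   tolerance = 1e-12)
    }
  }
})

test_that("occupancy propagation agrees with the exported transition rows", {
  p <- base_params
  res <- run_cohort(closure_strategy(p), p)
  tr <- tidy(res)
  states <- c("stable", "post_minor", "post_moderate", "dead")
  occ <- as.matrix(tr[, states])
  for (i in c(1, 10, 60, 119)) {
    age <- p$model$start_age + 0.25 * (i - 1)
    rows <- t(vapply(states, function(s) {
      build_transition_row(s, age, p$transitions$p_rec_closure, p)
    }, numeric(4)))
    expect_equal(as.numeric(occ[i, ] %*% rows), unname(occ[i + 1, ]),
                 tolerance = 1e-12)
  }
})

test_that("discounting can only shrink totals, and QALY <= LY", {
  for (make in list(closure_strategy, medical_strategy)) {
    o <- run_cohort(make(base_params), base_params, keep_trace = FALSE)$outcome
    expect_lt(o$cost_discounted, o$cost_undiscounted)
    expect_lt(o$qaly_discounted, o$qaly_undiscounted)
    expect_lt(o$ly_discounted, o$ly_undiscounted)
    expect_lt(o$qaly_discounted, o$ly_discounted)
    expect_lt(o$qaly_undiscounted, o$ly_undiscounted)
  }
})

test_that("discounted QALYs fall monotonically in the discount rate", {
  qalys <- vapply(c(0, 0.05, 0.08), function(r) {
    p <- base_params
    p$model$discount_rate <- r
    run_cohort(medical_strategy(p), p, keep_trace = FALSE)$outcome$qaly_discounted
  }, numeric(1))
  expect_true(all(diff(qalys) < 0))
})

test_that("with unit utilities and no discounting, QALY equals LY exactly", {
  p <- unit_utility_params(base_params)
  p$model$discount_rate <- 0
  for (make in list(closure_strategy, medical_strategy)) {
    o <- run_cohort(make(p), p, keep_trace = FALSE)$outcome
    expect_equal(o$qaly_discounted, o$ly_discounted, tolerance = 1e-12)
    expect_equal(o$qaly_undiscounted, o$ly_undiscounted, tolerance = 1e-12)
  }
})

test_that("equalising the arms isolates the upfront-plus-medication cost gap", {
  p <- base_params
  p$transitions$p_rec_closure <- p$transitions$p_rec_medical
  p$utilities$u_stable_closure_early <- p$utilities$u_stable_medical
  p$utilities$u_stable_closure_late <- p$utilities$u_stable_medical
  cl <- run_cohort(closure_strategy(p), p)
  me <- run_cohort(medical_strategy(p), p)
  expect_equal(cl$outcome$qaly_discounted, me$outcome$qaly_discounted, tolerance = 1e-12)
  expect_equal(cl$outcome$ly_discounted, me$outcome$ly_discounted, tolerance = 1e-12)
  # incremental cost = upfront difference + discounted medication-schedule
  # difference on the (identical) stable-state trapezoid occupancy
  trc <- tidy(cl)
  stable_trap <- 0.5 * (trc$stable[-nrow(trc)] + trc$stable[-1])
  k <- seq_len(nrow(trc) - 1)
  disc <- (1 + p$model$discount_rate)^(-floor((k - 1) * 0.25))
  med_diff <- closure_strategy(p)$medication_cost(k) -
    medical_strategy(p)$medication_cost(k)
  expected <- closure_strategy(p)$upfront_cost + sum(disc * med_diff * stable_trap)
  expect_equal(cl$outcome$cost_discounted - me$outcome$cost_discounted,
               expected, tolerance = 1e-9)
})

test_that("the mid-cycle discounting variant is available and discounts harder", {
  res_a <- run_cohort(medical_strategy(base_params), base_params, keep_trace = FALSE)
  res_m <- run_cohort(medical_strategy(base_params), base_params,
                      discounting = "midcycle", keep_trace = FALSE)
  expect_lt(res_m$outcome$qaly_discounted, res_a$outcome$qaly_discounted)
  expect_identical(res_m$outcome$qaly_undiscounted, res_a$outcome$qaly_undiscounted)
  expect_error(
    run_cohort(medical_strategy(base_params), base_params, discounting = "qualy"),
    "discounting"
  )
})

test_that("horizon validation rejects broken inputs", {
  s <- medical_strategy(base_params)
  expect_error(run_cohort(s, base_params, horizon = 0.3), "multiple")
  expect_error(run_cohort(s, base_params, horizon = 0), "multiple")
  expect_error(run_cohort(s, base_params, horizon = 35), "coverage")
})

test_that("trace CSV export round-trips at full precision", {
  res <- run_cohort(closure_strategy(base_params), base_params)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_trace_csv(res, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), 121)
  expect_equal(back$stable, tidy(res)$stable, tolerance = 1e-12)
  expect_equal(back$cycle_cost_discounted[1], closure_strategy(base_params)$upfront_cost)
})
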