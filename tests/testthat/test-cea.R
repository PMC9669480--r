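mk_outcome <- function(cost, qaly, ly) {
  list(cost_discounted = cost, qaly_discounted = qaly, ly_discounted = ly,
       cost_undiscounted = cost, qaly_undiscounted = qaly, ly_undiscounted = ly)
}

test_that("incremental comparisons follow the dominance taxonomy", {
  wtp <- 37654

  # plain ratio, cost-effective
  cmp <- cea_compare(mk_outcome(8131, 13.15, 15.26), mk_outcome(4186, 11.74, 15.14), wtp)
  expect_equal(cmp$d_cost, 3945)
  expect_equal(cmp$icer_per_qaly, 3945 / 1.41, tolerance = 1e-9)
  expect_identical(cmp$dominance, "none")
  expect_identical(cmp$decision, "cost-effective")

  # identical arms
  same <- cea_compare(mk_outcome(100, 1, 1.2), mk_outcome(100, 1, 1.2), wtp)
  expect_identical(same$d_cost, 0)
  expect_true(is.na(same$icer_per_qaly))
  expect_identical(same$decision, "equivalent")

  # cheaper and more effective: dominant, negative ratio still reported
  dom <- cea_compare(mk_outcome(8131, 13.15, 15.26), mk_outcome(24085, 11.73, 15.14), wtp)
  expect_identical(dom$dominance, "dominant")
  expect_lt(dom$icer_per_qaly, 0)
  expect_identical(dom$decision, "cost-effective (dominant)")

  # dearer and less effective: dominated
  bad <- cea_compare(mk_outcome(9000, 11, 14), mk_outcome(4000, 12, 15), wtp)
  expect_identical(bad$dominance, "dominated")
  expect_identical(bad$decision, "not cost-effective (dominated)")

  # above threshold
  exp_cmp <- cea_compare(mk_outcome(100000, 2, 2), mk_outcome(0, 0.5, 0.5), wtp)
  expect_gt(exp_cmp$icer_per_qaly, wtp)
  expect_identical(exp_cmp$decision, "not cost-effective")

  # zero effect difference with a cost difference: undefined ICER label
  undef <- cea_compare(mk_outcome(200, 1, 1), mk_outcome(100, 1, 1), wtp)
  expect_true(is.na(undef$icer_per_qaly))
  expect_identical(undef$decision, "ICER undefined")
})

test_that("comparison is antisymmetric under arm swap", {
  a <- mk_outcome(8131, 13.15, 15.26)
  b <- mk_outcome(4186, 11.74, 15.14)
  ab <- cea_compare(a, b, 37654)
  ba <- cea_compare(b, a, 37654)
  expect_equal(ab$d_cost, -ba$d_cost)
  expect_equal(ab$d_qaly, -ba$d_qaly)
  expect_equal(ab$icer_per_qaly, ba$icer_per_qaly) # ratio of two negations
  expect_equal(ab$inmb, -ba$inmb)
  expect_identical(ba$dominance, "none")
})

test_that("net monetary benefit matches its definition and the ICER decision rule", {
  expect_equal(nmb(mk_outcome(0, 1, 1), 37654), 37654)
  expect_equal(nmb(mk_outcome(37654, 1, 1), 37654), 0)
  expect_error(nmb(mk_outcome(0, 1, 1), -1), "non-negative")

  # incremental NMB > 0 <=> ICER < WTP whenever the QALY gain is positive
  set.seed(11)
  for (i in 1:50) {
    a <- mk_outcome(runif(1, 0, 2e4), runif(1, 5, 15), runif(1, 5, 15))
    b <- mk_outcome(runif(1, 0, 2e4), runif(1, 5, 15), runif(1, 5, 15))
    if (a$qaly_discounted <= b$qaly_discounted) next
    wtp <- runif(1, 0, 5e4)
    cmp <- cea_compare(a, b, wtp)
    inmb <- nmb(a, wtp) - nmb(b, wtp)
    expect_identical(inmb > 0, cmp$icer_per_qaly < wtp)
    expect_equal(inmb, cmp$inmb, tolerance = 1e-9)
  }
})

test_that("the horizon sweep is consistent with single comparisons", {
  sweep <- horizon_sweep(base_params, horizons = c(5, 10, 30))
  expect_identical(nrow(sweep), 3L)
  full <- run_base_pair(base_params)
  expect_equal(sweep$icer_per_qaly[3], full$icer_per_qaly, tolerance = 1e-12)
  expect_equal(sweep$icer_per_ly[3], full$icer_per_ly, tolerance = 1e-12)
  # quality weighting always improves the ICER: per-LY exceeds per-QALY
  expect_true(all(sweep$icer_per_ly > sweep$icer_per_qaly))
  expect_error(horizon_sweep(base_params, horizons = c(10, 40)), "coverage")
})

test_that("the results table renders with publication rounding and dominance notes", {
  base <- cea_compare(mk_outcome(8131.4, 13.152, 15.259),
                      mk_outcome(4186.2, 11.737, 15.136), 37654)
  dom <- cea_compare(mk_outcome(8131.4, 13.152, 15.259),
                     mk_outcome(24085.0, 11.737, 15.136), 37654)
  tab <- render_table3(base, list(dabigatran = dom))
  expect_identical(nrow(tab), 4L)
  expect_identical(tab$strategy, rep(c("Medical therapy", "PFO closure"), 2))
  expect_identical(tab$cost[1:2], c(4186, 8131))
  expect_identical(tab$eff_qaly[1:2], c(11.74, 13.15))
  expect_identical(tab$note[4], "dominant")
  expect_match(tab$icer_per_qaly[4], "^-")
  # base-case-only table
  expect_identical(nrow(render_table3(base)), 2L)
})
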