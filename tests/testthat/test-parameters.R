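test_that("the packaged default reproduces every base input exactly", {
  p <- base_params
  expect_equal(p$transitions$p_rec_closure, 0.00145316446292076, tolerance = 1e-12)
  expect_equal(p$transitions$p_rec_medical, 0.0026858009288564, tolerance = 1e-12)
  expect_identical(
    p$transitions$prop_minor + p$transitions$prop_moderate + p$transitions$prop_fatal,
    1
  )
  expect_identical(p$transitions$rr_moderate_nonstroke_death, 1.68)
  expect_identical(p$transitions$mortality$q3m,
                   c(0.00048, 0.00076, 0.00121, 0.00193, 0.00325, 0.00565, 0.00991))
  expect_identical(p$model$start_age, 46)
  expect_identical(p$model$horizon, 30)
  expect_identical(p$model$discount_rate, 0.05)
  expect_equal(p$model$wtp, 37653.9)
  expect_identical(
    unlist(p$utilities),
    c(u_post_minor = 0.76, u_post_moderate = 0.21, u_recurrent_event = 0.2,
      u_stable_medical = 0.80, u_stable_closure_early = 0.84,
      u_stable_closure_late = 0.88)
  )
  expect_identical(p$costs$device, 4938)
  expect_identical(p$costs$stroke_death, 2154)
  expect_identical(p$costs$q_post_moderate, 514)
  # CNY-sourced costs come out of the CPI chain at full precision
  expect_equal(round(p$costs$minor_event), 1901)
  expect_equal(round(p$costs$moderate_event), 2513)
  expect_equal(round(p$costs$q_post_minor), 338)
  expect_identical(p$costs$aspirin_pack, 2.3)
  expect_identical(p$costs$clopidogrel_pack, 14.6)
  expect_identical(p$costs$inr_tests_per_year, 21L)
})

test_that("distribution families follow the input table", {
  rng <- base_params$ranges
  fam <- setNames(rng$distribution, rng$parameter)
  expect_identical(unname(fam[c("p_rec_closure", "p_rec_medical", "u_post_minor",
                                "u_stable_closure_late")]),
                   rep("beta", 4))
  expect_identical(unname(fam[c("device", "minor_event", "aspirin_pack")]),
                   rep("gamma", 3))
  # "/" rows: severity split, relative risk, discount rate stay fixed
  expect_identical(unname(fam[c("prop_minor", "prop_moderate", "prop_fatal",
                                "rr_moderate_nonstroke_death", "discount_rate")]),
                   rep("fixed", 5))
  expect_true(all(rng$low <= rng$base & rng$base <= rng$high))
})

test_that("invalid configurations fail with errors naming the offender", {
  cfg <- yaml::read_yaml(pfo_config_path())

  bad <- cfg
  bad$transitions$proportion_minor$base <- 0.6
  bad$transitions$proportion_moderate$base <- 0.6
  expect_error(load_parameters(bad), "prop")

  bad <- cfg
  bad$model$discount_rate$base <- -0.1
  expect_error(load_parameters(bad), "discount_rate")

  bad <- cfg
  bad$utilities$post_minor <- NULL
  expect_error(load_parameters(bad), "post_minor")

  bad <- cfg
  bad$utilities$post_minor$distribution <- "lognormal"
  expect_error(load_parameters(bad), "lognormal")

  bad <- cfg
  bad$costs$device$value <- -5
  expect_error(load_parameters(bad), "device")

  bad <- cfg
  bad$model$horizon_years <- 40 # exceeds mortality coverage from age 46
  expect_error(load_parameters(bad), "mortality")
})

test_that("fixture parameter sets are seed-stable, in-range and valid", {
  p0 <- make_fixture_parameters(1, 0)
  expect_identical(unlist(p0$utilities), unlist(base_params$utilities))
  expect_identical(unlist(p0$costs), unlist(base_params$costs))
  expect_identical(p0$transitions$p_rec_closure, base_params$transitions$p_rec_closure)

  a <- make_fixture_parameters(1, 1)
  b <- make_fixture_parameters(1, 1)
  expect_identical(unlist(a$costs), unlist(b$costs))
  expect_identical(unlist(a$utilities), unlist(b$utilities))

  for (seed in 2:5) {
    f <- make_fixture_parameters(seed, 1)
    expect_no_error(validate_parameters(f))
    tr <- f$transitions
    expect_equal(tr$prop_minor + tr$prop_moderate + tr$prop_fatal, 1, tolerance = 1e-12)
    expect_true(tr$p_rec_closure >= 0 && tr$p_rec_closure <= 1)
    expect_true(all(unlist(f$utilities) >= 0 & unlist(f$utilities) <= 1))
    expect_false(identical(unlist(f$costs), unlist(base_params$costs)))
  }
})

test_that("fixture generation leaves the global RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(make_fixture_parameters(3, 1))
  expect_identical(.Random.seed, before)
})
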