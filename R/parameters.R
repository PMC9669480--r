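#' Path to the packaged base-case configuration
#'
#' @return Path to the YAML file encoding every base-case model input.
#' @export
pfo_config_path <- function() {
  system.file("extdata", "params_base.yaml", package = "pfocea", mustWork = TRUE)
}

.need <- function(x, keys, where) {
  for (k in keys) {
    if (is.null(x[[k]])) {
      abort(sprintf("Configuration key `%s` is missing under `%s`.", k, where))
    }
  }
  invisible(x)
}

# Resolve one monetary config entry to USD 2021 (per cycle for `per: year`).
.resolve_cost <- function(entry, key, currency) {
  .need(entry, c("value", "currency", "price_year"), paste0("costs$", key))
  val <- switch(entry$currency,
    USD = as.numeric(entry$value),
    CNY = cny_to_usd(as.numeric(entry$value), entry$price_year, currency),
    abort(sprintf("costs$%s: unknown currency `%s`.", key, entry$currency))
  )
  if (identical(entry$per, "year")) val <- val / 4
  val
}

.range_row <- function(parameter, group, base, entry) {
  dist <- entry$distribution %||% "fixed"
  if (!dist %in% c("beta", "gamma", "fixed")) {
    abort(sprintf("`%s`: unknown distribution family `%s`.", parameter, dist))
  }
  tibble::tibble(
    parameter = parameter, group = group, base = base,
    low = entry$low %||% base, high = entry$high %||% base,
    distribution = dist
  )
}

#' Load and validate the full model parameter set
#'
#' Reads a hierarchical YAML configuration (the packaged base case by
#' default), performs the closed-form unit conversions (annual recurrence
#' rates to per-cycle probabilities, CNY price-year amounts to 2021 USD),
#' assembles the sensitivity ranges, and validates every invariant.
#'
#' @param config Path to a YAML file, or an already-parsed nested list with
#'   the same structure as the packaged `params_base.yaml`.
#' @return A validated `pfo_params` object: a list with elements `model`,
#'   `transitions`, `utilities`, `costs`, `regimen_mix`, `currency`,
#'   `scenarios` and a `ranges` tibble (one row per parameter with its
#'   base value, one-way range and PSA distribution family).
#' @examples
#' p <- load_parameters()
#' p$transitions$p_rec_closure
#' @export
load_parameters <- function(config = pfo_config_path()) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  .need(cfg, c("model", "currency", "transitions", "utilities", "costs"), "top level")

  cur_cfg <- .need(
    cfg$currency,
    c("exchange_rate_cny_per_usd", "gdp_per_capita_2021_usd", "cpi_healthcare_by_year"),
    "currency"
  )
  currency <- list(
    cpi_by_year = unlist(cur_cfg$cpi_healthcare_by_year),
    exchange_rate_cny_per_usd = cur_cfg$exchange_rate_cny_per_usd,
    gdp_per_capita_2021 = cur_cfg$gdp_per_capita_2021_usd
  )

  m <- .need(cfg$model, c("start_age", "cycle_length", "horizon_years", "discount_rate"), "model")
  dr <- m$discount_rate
  model <- list(
    start_age = as.numeric(m$start_age),
    cycle_length = as.numeric(m$cycle_length),
    horizon = as.numeric(m$horizon_years),
    discount_rate = as.numeric(dr$base %||% dr),
    discounting = m$discounting %||% "annual",
    wtp = wtp_threshold(currency$gdp_per_capita_2021)
  )

  tr_cfg <- .need(
    cfg$transitions,
    c("recurrence_closure", "recurrence_medical", "proportion_minor",
      "proportion_moderate", "proportion_fatal", "rr_moderate_nonstroke_death",
      "background_mortality_q3m"),
    "transitions"
  )
  mort <- dplyr::bind_rows(lapply(tr_cfg$background_mortality_q3m, tibble::as_tibble))
  mort[] <- lapply(mort, as.numeric)
  transitions <- list(
    p_rec_closure = rate_to_cycle_prob(tr_cfg$recurrence_closure$annual_rate_pct),
    p_rec_medical = rate_to_cycle_prob(tr_cfg$recurrence_medical$annual_rate_pct),
    prop_minor = tr_cfg$proportion_minor$base,
    prop_moderate = tr_cfg$proportion_moderate$base,
    prop_fatal = tr_cfg$proportion_fatal$base,
    rr_moderate_nonstroke_death = tr_cfg$rr_moderate_nonstroke_death$base,
    mortality = mort
  )

  u_keys <- c("post_minor", "post_moderate", "recurrent_event",
              "stable_medical", "stable_closure_early", "stable_closure_late")
  .need(cfg$utilities, u_keys, "utilities")
  utilities <- setNames(
    lapply(u_keys, function(k) cfg$utilities[[k]]$base),
    paste0("u_", u_keys)
  )

  c_keys <- c("device", "procedure", "other_closure", "minor_event",
              "moderate_event", "stroke_death", "q_post_minor", "q_post_moderate",
              "aspirin_pack", "clopidogrel_pack", "warfarin_tablet",
              "dabigatran_tablet", "rivaroxaban_tablet", "inr_test")
  .need(cfg$costs, c(c_keys, "inr_tests_per_year"), "costs")
  costs <- setNames(
    lapply(c_keys, function(k) .resolve_cost(cfg$costs[[k]], k, currency)),
    c_keys
  )
  costs$inr_tests_per_year <- cfg$costs$inr_tests_per_year

  ranges <- dplyr::bind_rows(
    .range_row("p_rec_closure", "transition", transitions$p_rec_closure, tr_cfg$recurrence_closure),
    .range_row("p_rec_medical", "transition", transitions$p_rec_medical, tr_cfg$recurrence_medical),
    .range_row("prop_minor", "transition", transitions$prop_minor, tr_cfg$proportion_minor),
    .range_row("prop_moderate", "transition", transitions$prop_moderate, tr_cfg$proportion_moderate),
    .range_row("prop_fatal", "transition", transitions$prop_fatal, tr_cfg$proportion_fatal),
    .range_row("rr_moderate_nonstroke_death", "transition",
               transitions$rr_moderate_nonstroke_death, tr_cfg$rr_moderate_nonstroke_death),
    dplyr::bind_rows(lapply(u_keys, function(k) {
      .range_row(paste0("u_", k), "utility", utilities[[paste0("u_", k)]], cfg$utilities[[k]])
    })),
    dplyr::bind_rows(lapply(c_keys, function(k) {
      .range_row(k, "cost", costs[[k]], cfg$costs[[k]])
    })),
    .range_row("discount_rate", "other", model$discount_rate,
               if (is.list(dr)) dr else list(base = dr))
  )

  params <- structure(
    list(
      model = model,
      transitions = transitions,
      utilities = utilities,
      costs = costs,
      regimen_mix = unlist(cfg$medical_regimen_mix %||%
        list(aspirin = 1)),
      currency = currency,
      scenarios = cfg$scenarios %||% list(),
      ranges = ranges
    ),
    class = "pfo_params"
  )
  validate_parameters(params)
}

#' The packaged base-case parameter set
#'
#' @return The `pfo_params` object produced by [load_parameters()] on the
#'   packaged configuration.
#' @export
default_parameters <- function() {
  load_parameters(pfo_config_path())
}

#' Validate a model parameter set
#'
#' Checks every structural invariant: probabilities and utilities in
#' `[0, 1]`, severity proportions summing to one, contiguous mortality
#' bands with risk increasing in age, non-negative costs, an integer
#' number of cycles, and mortality-table coverage of the simulated ages.
#' Errors name the offending key.
#'
#' @param params A `pfo_params` object.
#' @return `params`, invisibly, if valid.
#' @export
validate_parameters <- function(params) {
  m <- params$model
  tr <- params$transitions
  chk <- function(ok, msg) if (!ok) abort(paste0("Invalid parameter set: ", msg))

  n_cycles <- m$horizon / m$cycle_length
  chk(n_cycles > 0 && abs(n_cycles - round(n_cycles)) < 1e-9,
      "`model$horizon` must be a positive multiple of `model$cycle_length`.")
  chk(m$discount_rate >= 0 && m$discount_rate <= 1,
      "`model$discount_rate` must lie in [0, 1].")
  chk(m$discounting %in% c("annual", "midcycle"),
      "`model$discounting` must be \"annual\" or \"midcycle\".")
  mort <- tr$mortality
  chk(m$start_age >= min(mort$age_low) &&
        m$start_age + m$horizon <= max(mort$age_high),
      "`model$start_age` + `model$horizon` exceeds mortality table coverage.")

  for (k in c("p_rec_closure", "p_rec_medical", "prop_minor", "prop_moderate", "prop_fatal")) {
    chk(tr[[k]] >= 0 && tr[[k]] <= 1, sprintf("`transitions$%s` must lie in [0, 1].", k))
  }
  chk(abs(tr$prop_minor + tr$prop_moderate + tr$prop_fatal - 1) < 1e-9,
      "`transitions$prop_*` severity proportions must sum to 1.")
  chk(tr$rr_moderate_nonstroke_death >= 1,
      "`transitions$rr_moderate_nonstroke_death` must be >= 1.")
  chk(all(mort$age_low[-1] == mort$age_high[-nrow(mort)]),
      "`transitions$mortality` bands must be contiguous.")
  chk(all(diff(mort$q3m) > 0),
      "`transitions$mortality` q3m must increase strictly with age.")
  chk(all(mort$q3m >= 0 & mort$q3m <= 1),
      "`transitions$mortality` q3m must lie in [0, 1].")

  for (k in names(params$utilities)) {
    u <- params$utilities[[k]]
    chk(u >= 0 && u <= 1, sprintf("`utilities$%s` must lie in [0, 1].", k))
  }
  for (k in names(params$costs)) {
    chk(all(params$costs[[k]] >= 0), sprintf("`costs$%s` must be non-negative.", k))
  }
  mix <- params$regimen_mix
  chk(all(mix >= 0) && abs(sum(mix) - 1) < 1e-6,
      "`medical_regimen_mix` weights must be non-negative and sum to 1.")
  rng <- params$ranges
  chk(all(rng$low <= rng$base + 1e-12 & rng$base <= rng$high + 1e-12),
      "`ranges` must satisfy low <= base <= high for every parameter.")
  chk(all(rng$distribution %in% c("beta", "gamma", "fixed")),
      "`ranges$distribution` must be beta, gamma or fixed.")
  invisible(params)
}

#' @export
print.pfo_params <- function(x, ...) {
  m <- x$model
  cat("<pfo_params>\n")
  cat(sprintf(
    "  cohort: start age %g, horizon %g y (%d cycles of %g y), discount %.0f%% (%s)\n",
    m$start_age, m$horizon, as.integer(round(m$horizon / m$cycle_length)),
    m$cycle_length, 100 * m$discount_rate, m$discounting
  ))
  cat(sprintf(
    "  recurrence/cycle: closure %.6f, medical %.6f; WTP %.0f USD/QALY\n",
    x$transitions$p_rec_closure, x$transitions$p_rec_medical, m$wtp
  ))
  cat(sprintf("  %d parameters with sensitivity ranges\n",
              sum(x$ranges$low < x$ranges$high)))
  invisible(x)
}

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Write one parameter back into a pfo_params object. Setting a severity
# proportion rescales the other two to keep the split summing to 1.
.set_param <- function(params, name, value) {
  tr <- params$transitions
  if (name %in% c("prop_minor", "prop_moderate", "prop_fatal")) {
    others <- setdiff(c("prop_minor", "prop_moderate", "prop_fatal"), name)
    rest <- unlist(tr[others])
    params$transitions[[name]] <- value
    params$transitions[others] <- as.list(rest * (1 - value) / sum(rest))
    params$ranges$base[match(others, params$ranges$parameter)] <-
      unlist(params$transitions[others])
  } else if (name %in% c("p_rec_closure", "p_rec_medical", "rr_moderate_nonstroke_death")) {
    params$transitions[[name]] <- value
  } else if (name %in% names(params$utilities)) {
    params$utilities[[name]] <- value
  } else if (name %in% names(params$costs)) {
    params$costs[[name]] <- value
  } else if (name == "discount_rate") {
    params$model$discount_rate <- value
  } else {
    abort(sprintf("Unknown model parameter `%s`.", name))
  }
  params$ranges$base[params$ranges$parameter == name] <- value
  params
}

#' Generate a perturbed but valid parameter set
#'
#' Draws every parameter that has a sensitivity range uniformly within
#' that range, scaled towards the base value by `perturbation_scale`
#' (`0` returns the base set unchanged, `1` spans the full range), then
#' renormalises the severity proportions and re-validates. Intended for
#' exercising the pipeline on alternative parameterisations in tests.
#'
#' @param seed Integer seed; output is reproducible and the global RNG
#'   state is left untouched.
#' @param perturbation_scale Non-negative scalar in `[0, 1]`.
#' @param params Base parameter set to perturb.
#' @return A validated `pfo_params` object.
#' @export
make_fixture_parameters <- function(seed, perturbation_scale = 1,
                                    params = default_parameters()) {
  if (perturbation_scale < 0) abort("`perturbation_scale` must be >= 0.")
  s <- min(perturbation_scale, 1)
  rng <- params$ranges[params$ranges$low < params$ranges$high, ]
  .with_seed(seed, {
    draw <- runif(nrow(rng), rng$low, rng$high)
    new <- rng$base + s * (draw - rng$base)
    new <- pmin(pmax(new, rng$low), rng$high)
    names(new) <- rng$parameter
    props <- c("prop_minor", "prop_moderate", "prop_fatal")
    if (all(props %in% names(new))) {
      new[props] <- new[props] / sum(new[props])
      for (p in props) params$transitions[[p]] <- unname(new[p])
      params$ranges$base[match(props, params$ranges$parameter)] <- unname(new[props])
      new <- new[setdiff(names(new), props)]
    }
    for (nm in names(new)) params <- .set_param(params, nm, unname(new[nm]))
  })
  validate_parameters(params)
  params
}

`%||%` <- function(a, b) if (is.null(a)) b else a
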