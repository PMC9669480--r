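# One-way (tornado) and probabilistic sensitivity analyses.

#' Fit a beta distribution from a mean and 95% interval
#'
#' Method-of-moments fit treating the printed range as a 95% confidence
#' interval: `sd = (high - low) / 3.92`, so `v = sd^2`,
#' `shape1 = mean * (mean * (1 - mean) / v - 1)` and
#' `shape2 = shape1 * (1 - mean) / mean`. The fitted mean equals the
#' input mean exactly.
#'
#' @param mean Mean in (0, 1).
#' @param low,high Interval bounds, `0 <= low < high <= 1`.
#' @return A distribution spec: list with `family`, `shape1`, `shape2`,
#'   `mean`, `sd`.
#' @examples
#' fit_beta(0.80, 0.72, 0.88) # shape1 ~ 76, shape2 ~ 19
#' @export
fit_beta <- function(mean, low, high) {
  if (mean <= 0 || mean >= 1) abort("`mean` must lie strictly in (0, 1).")
  if (low < 0 || high > 1 || low >= high) {
    abort("Interval must satisfy 0 <= low < high <= 1.")
  }
  v <- ((high - low) / 3.92)^2
  if (v >= mean * (1 - mean)) {
    abort("Infeasible variance for a beta distribution: (high-low)/3.92 squared must be < mean*(1-mean).")
  }
  shape1 <- mean * (mean * (1 - mean) / v - 1)
  list(family = "beta", shape1 = shape1, shape2 = shape1 * (1 - mean) / mean,
       mean = mean, sd = sqrt(v))
}

#' Fit a gamma distribution from a mean and 95% interval
#'
#' Method-of-moments fit with `sd = (high - low) / 3.92`:
#' `shape = mean^2 / v`, `scale = v / mean`, so `shape * scale` equals
#' the input mean exactly.
#'
#' @param mean Positive mean.
#' @param low,high Interval bounds, `low < high`.
#' @return A distribution spec: list with `family`, `shape`, `scale`,
#'   `mean`, `sd`.
#' @examples
#' fit_gamma(4938, 1451, 5926) # shape ~ 18.7, scale ~ 264
#' @export
fit_gamma <- function(mean, low, high) {
  if (mean <= 0) abort("`mean` must be positive.")
  if (low >= high) abort("Interval must satisfy low < high.")
  v <- ((high - low) / 3.92)^2
  list(family = "gamma", shape = mean^2 / v, scale = v / mean,
       mean = mean, sd = sqrt(v))
}

# Run both base arms for a parameter set and compare.
.run_pair <- function(params) {
  cl <- run_cohort(closure_strategy(params), params, keep_trace = FALSE)
  me <- run_cohort(medical_strategy(params), params, keep_trace = FALSE)
  cea_compare(cl, me, params = params)
}

#' One-way sensitivity analysis (tornado)
#'
#' Sets each parameter to its low and high range value in turn (all
#' others at base; a severity proportion redistributes its complement
#' over the other two proportionally), recomputes the 30-year ICER per
#' QALY, and sorts parameters by the ICER span they induce. Parameters
#' without a range contribute a zero-span entry.
#'
#' @param params A `pfo_params` object.
#' @return A tibble (class `pfo_tornado`) with one row per varied
#'   parameter: `icer_at_low`, `icer_at_high`, `span`, sorted by
#'   descending span. The base-case ICER is attached as attribute
#'   `base_icer`.
#' @export
one_way_sa <- function(params) {
  base_icer <- .run_pair(params)$icer_per_qaly
  rng <- params$ranges
  rows <- purrr::pmap(rng, function(parameter, group, base, low, high, distribution) {
    lo <- if (low == base) base_icer else .run_pair(.set_param(params, parameter, low))$icer_per_qaly
    hi <- if (high == base) base_icer else .run_pair(.set_param(params, parameter, high))$icer_per_qaly
    tibble::tibble(
      parameter = parameter, group = group, base = base, low = low, high = high,
      icer_at_low = lo, icer_at_high = hi, span = abs(hi - lo)
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$span))
  class(out) <- c("pfo_tornado", class(out))
  attr(out, "base_icer") <- base_icer
  attr(out, "wtp") <- params$model$wtp
  out
}

# Distribution specs for every PSA-sampled parameter (beta for utilities
# and transition probabilities, gamma for costs; rows whose Table of
# inputs prints no distribution stay fixed).
.psa_distributions <- function(params) {
  rng <- params$ranges[params$ranges$distribution != "fixed" &
    params$ranges$low < params$ranges$high, ]
  specs <- purrr::pmap(rng, function(parameter, group, base, low, high, distribution) {
    spec <- switch(distribution,
      beta = fit_beta(base, low, high),
      gamma = fit_gamma(base, low, high)
    )
    spec$parameter <- parameter
    spec
  })
  setNames(specs, rng$parameter)
}

# Apply one draw of sampled values to a parameter set (fast path: the
# ranges table is left untouched; it is not used by the cohort engine).
.apply_draw <- function(params, values) {
  for (nm in names(values)) {
    if (nm %in% names(params$utilities)) {
      params$utilities[[nm]] <- values[[nm]]
    } else if (nm %in% names(params$costs)) {
      params$costs[[nm]] <- values[[nm]]
    } else {
      params$transitions[[nm]] <- values[[nm]]
    }
  }
  params
}

#' Probabilistic sensitivity analysis
#'
#' Draws every beta/gamma-distributed parameter independently from its
#' fitted distribution (shared parameters use the same draw in both
#' arms), reruns both arms per draw, and summarises the incremental
#' cost-effectiveness distribution: the probability that closure is
#' cost-effective at the willingness-to-pay threshold (positive
#' incremental net monetary benefit), its Monte Carlo standard error,
#' and the cost-effectiveness acceptability curve over a threshold grid.
#'
#' @param params A `pfo_params` object.
#' @param n_draws Number of Monte Carlo draws (default 10,000).
#' @param seed Integer seed; the global RNG state is preserved.
#' @param wtp_grid Thresholds (USD/QALY) for the acceptability curve.
#' @param wtp Decision threshold; defaults to the configured one.
#' @return A `pfo_psa` object: `draws` tibble (`d_cost`, `d_qaly`,
#'   `d_ly`, per-draw ICER break-even threshold), `prob_ce`, `mc_se`,
#'   `ceac` tibble, seed and draw count.
#' @export
run_psa <- function(params, n_draws = 10000, seed = 1,
                    wtp_grid = seq(0, 50000, by = 500), wtp = NULL) {
  if (n_draws < 1) abort("`n_draws` must be >= 1.")
  if (is.null(wtp)) wtp <- params$model$wtp
  specs <- .psa_distributions(params)

  samples <- .with_seed(seed, {
    cols <- lapply(specs, function(s) {
      if (s$family == "beta") {
        rbeta(n_draws, s$shape1, s$shape2)
      } else {
        rgamma(n_draws, shape = s$shape, scale = s$scale)
      }
    })
    if (length(cols)) do.call(cbind, cols) else matrix(0, n_draws, 0)
  })

  d_cost <- d_qaly <- d_ly <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    pi <- if (ncol(samples)) {
      .apply_draw(params, as.list(samples[i, ]))
    } else {
      params
    }
    cl <- run_cohort(closure_strategy(pi), pi, keep_trace = FALSE)$outcome
    me <- run_cohort(medical_strategy(pi), pi, keep_trace = FALSE)$outcome
    d_cost[i] <- cl$cost_discounted - me$cost_discounted
    d_qaly[i] <- cl$qaly_discounted - me$qaly_discounted
    d_ly[i] <- cl$ly_discounted - me$ly_discounted
  }

  # threshold above (below, for QALY-losing draws) which a draw favours
  # closure; the CEAC is the empirical distribution of these break-evens
  inmb <- wtp * d_qaly - d_cost
  prob_ce <- mean(inmb > 0)
  ceac <- tibble::tibble(
    wtp = wtp_grid,
    p_ce = vapply(wtp_grid, function(w) mean(w * d_qaly - d_cost > 0), numeric(1))
  )

  structure(
    list(
      draws = tibble::tibble(
        draw = seq_len(n_draws), d_cost = d_cost, d_qaly = d_qaly, d_ly = d_ly
      ),
      prob_ce = prob_ce,
      mc_se = sqrt(prob_ce * (1 - prob_ce) / n_draws),
      ceac = ceac, wtp = wtp, seed = seed, n_draws = n_draws
    ),
    class = "pfo_psa"
  )
}

#' @export
print.pfo_psa <- function(x, ...) {
  cat(sprintf(
    "<pfo_psa> %d draws (seed %s)\n  P(cost-effective at WTP %.0f USD/QALY) = %.3f (MC SE %.4f)\n",
    x$n_draws, format(x$seed), x$wtp, x$prob_ce, x$mc_se
  ))
  cr <- ceac_crossing(x)
  if (!is.na(cr)) cat(sprintf("  CEAC crosses 0.5 near %.0f USD/QALY\n", cr))
  invisible(x)
}

#' @rdname run_psa
#' @param x A `pfo_psa` object.
#' @param ... Unused.
#' @method tidy pfo_psa
#' @export
tidy.pfo_psa <- function(x, ...) x$draws

#' @rdname run_psa
#' @method glance pfo_psa
#' @export
glance.pfo_psa <- function(x, ...) {
  tibble::tibble(
    n_draws = x$n_draws, wtp = x$wtp, prob_ce = x$prob_ce,
    mc_se = x$mc_se, ceac_crossing = ceac_crossing(x)
  )
}

#' Threshold at which acceptability first exceeds one half
#'
#' Returns the willingness-to-pay value where the acceptability curve
#' crosses 0.5, computed as the median of the per-draw break-even
#' thresholds (the continuum limit of interpolating the CEAC between
#' bracketing grid points; with degenerate distributions it equals the
#' base-case ICER exactly). `NA` with a message if the crossing lies
#' outside the CEAC grid.
#'
#' @param psa A `pfo_psa` object.
#' @return USD/QALY value, or `NA` if out of grid.
#' @export
ceac_crossing <- function(psa) {
  d <- psa$draws
  # QALY-gaining draws favour closure above their ICER; QALY-losing
  # draws that save money are favoured at low thresholds, QALY-losing
  # draws that cost money never are
  breakeven <- ifelse(d$d_qaly > 0, pmax(d$d_cost / d$d_qaly, 0),
    ifelse(d$d_cost < 0, -Inf, Inf)
  )
  med <- stats::median(breakeven)
  grid <- range(psa$ceac$wtp)
  if (!is.finite(med) || med < grid[1] || med > grid[2]) {
    message("CEAC does not cross 0.5 within the threshold grid.")
    return(NA_real_)
  }
  med
}
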