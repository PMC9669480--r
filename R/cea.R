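# Incremental cost-effectiveness comparisons and the time-horizon sweep.

.as_outcome <- function(x) {
  if (inherits(x, "pfo_cohort")) x$outcome else x
}

#' Compare two arm outcomes
#'
#' Computes incremental cost, QALYs and life-years of the intervention
#' over the comparator (on unrounded totals), the ICER per QALY and per
#' life-year, a dominance classification, and the decision at the
#' willingness-to-pay threshold. When the intervention is cheaper and
#' more effective it "dominates" (the negative ratio is still reported);
#' when costlier and less effective it is "dominated"; a zero incremental
#' effect leaves the ICER undefined (`NA`).
#'
#' @param intervention,comparator `pfo_cohort` objects (or bare outcome
#'   lists) for the intervention and comparator arms.
#' @param wtp Willingness-to-pay threshold in USD/QALY; defaults to three
#'   times 2021 per-capita GDP.
#' @param params Parameter set supplying the default threshold.
#' @return A `pfo_cea` object; `tidy()` returns the incremental row,
#'   `glance()` a one-row summary including the decision.
#' @examples
#' p <- default_parameters()
#' cea_compare(run_cohort(closure_strategy(p), p),
#'             run_cohort(medical_strategy(p), p))
#' @export
cea_compare <- function(intervention, comparator, wtp = NULL,
                        params = NULL) {
  if (is.null(wtp)) {
    wtp <- if (!is.null(params)) params$model$wtp else wtp_threshold(12551.3)
  }
  a <- .as_outcome(intervention)
  b <- .as_outcome(comparator)
  d_cost <- a$cost_discounted - b$cost_discounted
  d_qaly <- a$qaly_discounted - b$qaly_discounted
  d_ly <- a$ly_discounted - b$ly_discounted

  dominance <- if (d_cost < 0 && d_qaly > 0) {
    "dominant"
  } else if (d_cost > 0 && d_qaly < 0) {
    "dominated"
  } else {
    "none"
  }
  icer_per_qaly <- if (d_qaly == 0) NA_real_ else d_cost / d_qaly
  icer_per_ly <- if (d_ly == 0) NA_real_ else d_cost / d_ly
  decision <- if (dominance == "dominant") {
    "cost-effective (dominant)"
  } else if (dominance == "dominated") {
    "not cost-effective (dominated)"
  } else if (is.na(icer_per_qaly)) {
    if (d_cost == 0) "equivalent" else "ICER undefined"
  } else if (d_qaly > 0 && icer_per_qaly < wtp) {
    "cost-effective"
  } else if (d_qaly < 0 && icer_per_qaly > wtp) {
    "cost-effective" # cheaper, loses QALYs at a rate above the threshold
  } else {
    "not cost-effective"
  }

  structure(
    list(
      intervention = a, comparator = b,
      d_cost = d_cost, d_qaly = d_qaly, d_ly = d_ly,
      icer_per_qaly = icer_per_qaly, icer_per_ly = icer_per_ly,
      dominance = dominance, wtp = wtp, decision = decision,
      inmb = wtp * d_qaly - d_cost
    ),
    class = "pfo_cea"
  )
}

#' @export
print.pfo_cea <- function(x, ...) {
  cat("<pfo_cea>\n")
  cat(sprintf(
    "  incremental: cost %.0f USD, %.3f QALY, %.3f LY\n",
    x$d_cost, x$d_qaly, x$d_ly
  ))
  icer <- function(v) if (is.na(v)) "undefined" else sprintf("%.0f", v)
  cat(sprintf(
    "  ICER %s USD/QALY, %s USD/LY%s\n",
    icer(x$icer_per_qaly), icer(x$icer_per_ly),
    if (x$dominance != "none") paste0(" (", x$dominance, ")") else ""
  ))
  cat(sprintf("  decision at WTP %.0f USD/QALY: %s\n", x$wtp, x$decision))
  invisible(x)
}

#' @rdname cea_compare
#' @param x A `pfo_cea` object.
#' @param ... Unused.
#' @method tidy pfo_cea
#' @export
tidy.pfo_cea <- function(x, ...) {
  tibble::tibble(
    d_cost = x$d_cost, d_qaly = x$d_qaly, d_ly = x$d_ly,
    icer_per_qaly = x$icer_per_qaly, icer_per_ly = x$icer_per_ly,
    dominance = x$dominance, inmb = x$inmb, decision = x$decision
  )
}

#' @rdname cea_compare
#' @method glance pfo_cea
#' @export
glance.pfo_cea <- function(x, ...) tidy(x, ...)

#' Net monetary benefit of an arm outcome
#'
#' `wtp * QALY - cost` on discounted totals; a positive incremental NMB
#' between two arms is equivalent to the ICER lying below the threshold
#' when the incremental QALY is positive.
#'
#' @param outcome A `pfo_cohort` object or outcome list.
#' @param wtp Willingness-to-pay in USD/QALY (non-negative).
#' @return Net monetary benefit in USD.
#' @export
nmb <- function(outcome, wtp) {
  if (wtp < 0) abort("`wtp` must be non-negative.")
  o <- .as_outcome(outcome)
  wtp * o$qaly_discounted - o$cost_discounted
}

#' ICERs across time horizons
#'
#' Re-runs both arms for each horizon and tabulates the ICER per QALY and
#' per life-year, mirroring the model's horizon analysis: the per-QALY
#' ICER falls as the horizon extends, and the per-LY ICER crosses the
#' willingness-to-pay threshold much later than the per-QALY ICER.
#'
#' @param params A `pfo_params` object.
#' @param horizons Horizons in years (each a multiple of the cycle length,
#'   within mortality-table coverage).
#' @param scenario Scenario id passed to [apply_scenario()].
#' @return A tibble (class `pfo_horizon`) with per-arm totals, ICERs and
#'   the cost-effectiveness decision per horizon.
#' @export
horizon_sweep <- function(params, horizons = 1:30, scenario = "base") {
  sc <- apply_scenario(params, scenario)
  rows <- lapply(horizons, function(h) {
    cl <- run_cohort(sc$closure, sc$params, horizon = h, keep_trace = FALSE)
    me <- run_cohort(sc$medical, sc$params, horizon = h, keep_trace = FALSE)
    cmp <- cea_compare(cl, me, params = sc$params)
    tibble::tibble(
      horizon = h,
      cost_closure = cl$outcome$cost_discounted,
      cost_medical = me$outcome$cost_discounted,
      qaly_closure = cl$outcome$qaly_discounted,
      qaly_medical = me$outcome$qaly_discounted,
      ly_closure = cl$outcome$ly_discounted,
      ly_medical = me$outcome$ly_discounted,
      icer_per_qaly = cmp$icer_per_qaly,
      icer_per_ly = cmp$icer_per_ly,
      decision = cmp$decision
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pfo_horizon", class(out))
  attr(out, "wtp") <- params$model$wtp
  out
}
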