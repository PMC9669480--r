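# ggplot2 figures for each result type.

#' @describeIn run_cohort Stacked state-occupancy trace over time.
#' @param object A fitted result object.
#' @method autoplot pfo_cohort
#' @export
autoplot.pfo_cohort <- function(object, ...) {
  trace <- tidy(object)
  long <- tidyr::pivot_longer(
    trace[, c("age", STATES)],
    cols = dplyr::all_of(STATES),
    names_to = "state", values_to = "occupancy"
  )
  long$state <- factor(long$state, levels = rev(STATES))
  ggplot2::ggplot(long, ggplot2::aes(.data$age, .data$occupancy, fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(
      title = paste0("Cohort trace: ", object$strategy),
      x = "Age (years)", y = "State occupancy", fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn one_way_sa Tornado diagram of one-way ICER ranges.
#' @param object A `pfo_tornado` tibble.
#' @param top Number of widest bars to display.
#' @param ... Unused.
#' @method autoplot pfo_tornado
#' @export
autoplot.pfo_tornado <- function(object, top = 12, ...) {
  d <- utils::head(object, top)
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  base_icer <- attr(object, "base_icer")
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$icer_at_low, xend = .data$icer_at_high,
                   y = .data$parameter, yend = .data$parameter),
      linewidth = 4, colour = "steelblue"
    ) +
    ggplot2::geom_vline(xintercept = base_icer, linetype = 2) +
    ggplot2::labs(
      title = "One-way sensitivity of the ICER",
      x = "ICER (USD/QALY)", y = NULL,
      caption = sprintf("Dashed line: base-case ICER %.0f USD/QALY", base_icer)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn run_psa Incremental cost-effectiveness plane (`type =
#'   "plane"`) or acceptability curve (`type = "ceac"`).
#' @param object A `pfo_psa` object.
#' @param type `"plane"` or `"ceac"`.
#' @method autoplot pfo_psa
#' @export
autoplot.pfo_psa <- function(object, type = c("plane", "ceac"), ...) {
  type <- match.arg(type)
  if (type == "plane") {
    ggplot2::ggplot(object$draws, ggplot2::aes(.data$d_qaly, .data$d_cost)) +
      ggplot2::geom_point(alpha = 0.15, size = 0.4, colour = "steelblue") +
      ggplot2::geom_abline(slope = object$wtp, intercept = 0, linetype = 2) +
      ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
      ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
      ggplot2::labs(
        title = "Cost-effectiveness plane",
        x = "Incremental QALYs", y = "Incremental cost (USD)",
        caption = sprintf("Dashed line: WTP %.0f USD/QALY", object$wtp)
      ) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$ceac, ggplot2::aes(.data$wtp, .data$p_ce)) +
      ggplot2::geom_line(colour = "steelblue") +
      ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
      ggplot2::geom_vline(xintercept = object$wtp, linetype = 2) +
      ggplot2::labs(
        title = "Cost-effectiveness acceptability curve",
        x = "Willingness-to-pay (USD/QALY)",
        y = "P(closure cost-effective)"
      ) +
      ggplot2::ylim(0, 1) +
      ggplot2::theme_minimal()
  }
}

#' @describeIn horizon_sweep ICER per QALY and per life-year vs. horizon.
#' @param object A `pfo_horizon` tibble.
#' @param ... Unused.
#' @method autoplot pfo_horizon
#' @export
autoplot.pfo_horizon <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("horizon", "icer_per_qaly", "icer_per_ly")],
    cols = -"horizon", names_to = "measure", values_to = "icer"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$horizon, .data$icer, colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = attr(object, "wtp"), linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      title = "ICER by time horizon",
      x = "Horizon (years)", y = "ICER (USD, log scale)", colour = NULL
    ) +
    ggplot2::theme_minimal()
}
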