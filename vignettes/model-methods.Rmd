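---
title: "Model and methods: cost-effectiveness of PFO closure after cryptogenic stroke"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: cost-effectiveness of PFO closure after cryptogenic stroke}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfocea)
```

## The decision problem

Patent foramen ovale (PFO) is a persistent inter-atrial communication
found in a substantial fraction of patients with cryptogenic (cause
undetermined) ischaemic stroke. Catheter-based device closure roughly
halves the annual recurrence risk relative to antithrombotic therapy
alone, at the price of an upfront device and procedure cost. `pfocea`
implements a quarterly-cycle, four-state Markov cohort model that asks
whether that trade-off is worth paying for in the Chinese healthcare
setting, from a payer perspective, in 2021 USD.

A homogeneous cohort enters at age 46 in the *stable* state and is
followed for 30 years (120 cycles of 3 months). Each cycle a cohort
fraction may suffer a recurrent ischaemic stroke, split by severity
into *minor* (modified Rankin scale 0–2), *moderate* (mRS 3–5) or
immediately *fatal*; non-fatal recurrences move occupancy into the
corresponding post-stroke state, where it stays (states only worsen:
a later minor stroke never improves a post-moderate patient). All
states are exposed to age-dependent background mortality from Chinese
life tables in 5-year bands, multiplied by a relative risk of 1.68 in
the post-moderate state.

The two comparators differ in three places only: the closure arm pays
an upfront bundle (device 4,938 + procedure 517 + other 1,180 USD),
takes aspirin + clopidogrel for one month and then aspirin through
month 6, and enjoys higher stable-state utility (0.84 during the first
six months, 0.88 after) than the medical arm (0.80); and the closure
arm's quarterly recurrence probability is lower (see below).

## Transition probabilities

Annual recurrence rates of 0.58 and 1.07 events per 100 patient-years
(closure and medical arm, from the randomized trial that also supplies
the cohort's baseline age) convert to quarterly probabilities through
a constant-hazard assumption:

$$r_{3m} = -\tfrac{1}{4}\ln(1 - r/100), \qquad
  p_{3m} = 1 - e^{-r_{3m}},$$

giving 0.00145316446292076 and 0.0026858009288564 per cycle. The
recurrence probability is held constant over the horizon. Severity
splits are 53.4% minor / 32.4% moderate / 14.2% fatal.

Competing risks within a cycle are ordered: background (non-stroke)
death acts first, recurrence strikes its survivors. At these
magnitudes (background mortality at most 0.01 per cycle, recurrence at
most 0.003) the alternative ordering changes outcomes far below
reporting precision; a pinned order keeps the engine, the
microsimulation and the tests exactly consistent.

## Rewards, half-cycle correction, discounting

Transitions happen somewhere inside a cycle, so state rewards (utility
weights, quarterly post-stroke maintenance costs of 338/514 USD,
medication costs) accrue on the *trapezoid* of the cycle-start and
cycle-end occupancy vectors — the half-cycle correction. One-time
rewards attach to the cycle's event flows: 1,901 USD per minor event,
2,513 per moderate event, 2,154 per stroke death (non-stroke deaths
carry no terminal cost), and a recurrent-event utility of 0.20 that
replaces the destination-state utility for the transitioning fraction
during its event half-cycle. The upfront procedure bundle is charged
at time zero, undiscounted. Life-years accrue 0.25 per alive trapezoid
cycle; both discounted and undiscounted totals are reported, with the
headline life-years discounted like everything else.

Two discounting conventions are implemented (`run_cohort(discounting=)`):

* `"annual"` (default): discrete annual compounding — rewards earned in
  completed year $y = \lfloor (k-1)/4 \rfloor$ are discounted by
  $(1+r)^{-y}$, the behaviour of discrete-time decision-tree software
  with yearly discount steps;
* `"midcycle"`: continuous-equivalent discounting
  $(1+r)^{-(k-\frac12)/4}$ at cycle midpoints.

The default was calibrated on the published arm totals: mid-cycle
discounting under-shoots all four QALY/LY totals by about 3%, while
discrete annual compounding reproduces them within 0.7%. Both
conventions are legitimate; the switch exists precisely because the
original implementation's variant is observable only through its
outputs.

## Costing the strategies

Monetary inputs are tagged with a currency and price year in the
configuration. CNY amounts are inflated to 2021 through the
healthcare-sector CPI chain (factors 1.027, 1.038, 1.06, 1.043, 1.024,
1.018, 1.004 for 2015–2021; only factors *after* the price year apply)
and divided by the average exchange rate 6.4515. Pack-based
antiplatelets (aspirin 30 × 100 mg at 2.3 USD, clopidogrel 28 × 75 mg
at 14.6 USD) are costed as one pack per month, three per quarter;
per-tablet drugs use 91.25 days per quarter (warfarin 3 mg at 0.08
USD/day plus INR monitoring at 21 × 12 USD per year, dabigatran 110 mg
twice daily at 2.2 USD/tablet, rivaroxaban 20 mg once daily at 4.2
USD/tablet).

Two costing choices were genuinely open and were settled against the
published arm totals:

* **Medication accrues on stable-state occupancy only.** The quarterly
  post-stroke maintenance costs come from an all-in economic study of
  stroke care and are read as already covering secondary-prevention
  medication; the arm-specific antithrombotic is therefore costed only
  while the patient is stable (and never in the dead state). The
  published scenario totals discriminate sharply between this and an
  all-survivors basis: the dabigatran arm computes to within 2% on the
  stable basis but 11% high on the all-alive basis.
* **Base-case medical therapy is a regimen mix, not aspirin alone.**
  The source trial's medical arm took aspirin (46.5%), warfarin
  (25.2%), clopidogrel (14.0%), aspirin + dipyridamole (8.1%, costed
  as aspirin since dipyridamole has no printed price) or aspirin +
  clopidogrel (6.2%); the base case costs the weighted average,
  about 30.8 USD per quarter. Lifelong aspirin alone would price the
  medical arm near 3,000 USD against the published 4,186 and push the
  ICER ~30% high; the mix lands within 2% of every published total.
  Single regimens remain selectable via
  `medical_strategy(params, medication=)`, and the warfarin /
  dabigatran / rivaroxaban scenarios replace the mix wholesale.

## Outcomes and decision rule

For each arm the model returns discounted cost, QALYs and life-years.
`cea_compare()` forms increments on unrounded totals, the ICER per
QALY and per life-year, and a dominance classification (cheaper and
more effective = dominant; the negative ratio is still reported, as
the published table does). The willingness-to-pay threshold follows
Chinese pharmacoeconomic guidance: three times 2021 per-capita GDP,
3 × 12,551.3 = 37,653.9 USD/QALY. `horizon_sweep()` repeats the
comparison over horizons 1–30 years; the per-QALY ICER falls
monotonically with horizon, dropping below the threshold within the
first few years, while the per-LY ICER (which ignores the utility
advantage of closure) crosses only after more than 20 years.

## Sensitivity analyses

**One-way (tornado).** Every parameter with a printed range is set to
its low and high bound in turn, everything else at base, and the
30-year ICER per QALY recomputed. Severity proportions are varied with
the complement redistributed proportionally over the other two so the
split still sums to one. Parameters without a range contribute
zero-span entries. Bars are sorted by span; with base inputs the
stable-state utilities (post-closure after 6 months, then medical-arm)
dominate, and no one-way ICER reaches the threshold.

**Probabilistic.** Ranges are treated as 95% intervals,
`sd = (high − low)/3.92`. Utilities and the two recurrence
probabilities get method-of-moments beta fits (exact mean, rejecting
infeasible variances); costs get gamma fits (shape = mean²/v,
scale = v/mean). Severity proportions, background mortality, the
non-stroke-death relative risk and the discount rate have no printed
distribution and stay fixed. Each of 10,000 draws samples all fitted
parameters independently (no correlation structure is specified by the
inputs; shared parameters naturally use the same draw in both arms),
reruns both arms, and records the increments. The probability of
cost-effectiveness is the fraction of draws with positive incremental
net monetary benefit at the threshold; the acceptability curve
recomputes that fraction over a 0–50,000 USD/QALY grid in 500-unit
steps, spanning the published figure's domain. `ceac_crossing()`
reports where acceptability passes one half as the median of per-draw
break-even thresholds — the continuum limit of interpolating the
gridded curve, which degenerates exactly to the base-case ICER when
all distributions are point masses.

## The microsimulation oracle

`simulate_patients()` walks individual patients through the very same
transition rules and reward conventions (one shared transition-row
definition; an independently coded row builder is kept in the test
suite so the 2×2 arithmetic is checked twice). Its mean outcomes
converge to the cohort engine's totals by construction, so it
validates the reward, half-cycle and discounting plumbing rather than
the row arithmetic. `compare_to_cohort()` checks mean cost/QALY/LY
within three standard errors and the occupancy path against a binomial
envelope; because the envelope is evaluated over ~500
(cycle, state) cells, the per-cell threshold is Šidák-adjusted so the
family-wise false-alarm rate matches a single three-standard-error
check — without the adjustment an exact implementation would be
flagged with high probability on pure Monte Carlo noise. A
deliberately mismatched recurrence risk is caught as a negative
control.

## Perturbed parameter sets

`make_fixture_parameters(seed, scale)` draws every ranged parameter
uniformly within its printed range (scaled toward base by `scale`,
with the severity trio renormalised) and revalidates. It emulates
alternative parameterisations of the same model — plausible Chinese
cost/utility/risk configurations — and is what the property tests run
against in addition to the base case. It does not emulate structural
uncertainty (different state spaces, time-varying recurrence,
procedure complications), so passing tests speak to the
implementation's correctness and the conclusion's parametric
robustness, not to model-structure risk.

## Numerical choices and edge cases

* Age bands are half-open `[low, high)`; the cohort ages
  deterministically by 0.25 years per cycle, so 46 + 29.75 = 75.75
  stays inside the printed table and any horizon beyond coverage is
  rejected up front.
* The relative-risk product `1.68 × q` is capped at 1.
* Horizons must be positive multiples of the cycle length; a
  non-integer cycle count is an error, not a rounding.
* Zero incremental QALYs leave the ICER `NA` with an explicit label
  rather than an infinity.
* Degenerate inputs used by the tests (zero or unit mortality in every
  band, unit utilities) are constructed directly on the parameter
  object, bypassing the loader's validation on purpose.
* All randomness (PSA, microsimulation, fixtures) flows through
  explicit seeds and restores the caller's RNG state.

## Problem sizes

The shipped tests run the full 120-cycle model everywhere, the PSA at
10,000 draws (about half a minute), the microsimulation oracle at
200,000 patients per arm for the headline comparison and 30,000 for
routine checks — sizes at which Monte Carlo error is comfortably below
the tolerances being asserted.

## Known limitations

* Procedure-related complications (new-onset atrial fibrillation,
  residual shunt) are outside the model, as are subgroup effects,
  adherence, crossover and repeat procedures.
* The recurrence probability is constant in age and time since the
  index event; the cohort is homogeneous.
* The PSA samples parameters independently; correlation between, for
  example, the two arms' stable-state utilities would tighten or widen
  the acceptability probability.
* The medical-arm regimen mix is a costing assumption calibrated
  against the published totals; the warfarin scenario's INR schedule
  (21 tests/year for life) prices that scenario slightly above its
  published total, suggesting the original analysis tapered monitoring
  in a way its inputs do not state.

## A worked base case

```{r base-case}
params <- default_parameters()
closure <- run_cohort(closure_strategy(params), params)
medical <- run_cohort(medical_strategy(params), params)
cea_compare(closure, medical, params = params)
```
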