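# Base-case model inputs for the PFO-closure vs. medical-therapy
# cost-utility model (Chinese healthcare payer perspective, USD 2021).
#
# Monetary values carry an explicit currency and price year; CNY amounts
# are inflated through the healthcare CPI chain to 2021 and converted at
# the average exchange rate. `low`/`high` are the one-way sensitivity /
# PSA ranges (already in final units: probabilities per cycle, utilities,
# USD 2021). `distribution: fixed` rows are excluded from probabilistic
# sampling.

model:
  start_age: 46          # years at model entry
  cycle_length: 0.25     # years per cycle (3 months)
  horizon_years: 30
  discount_rate: {base: 0.05, low: 0.0, high: 0.08, distribution: fixed}
  discounting: annual    # annual | midcycle, see run_cohort()

currency:
  exchange_rate_cny_per_usd: 6.4515
  gdp_per_capita_2021_usd: 12551.3
  cpi_healthcare_by_year:
    2015: 1.027
    2016: 1.038
    2017: 1.06
    2018: 1.043
    2019: 1.024
    2020: 1.018
    2021: 1.004

transitions:
  # Annual recurrent ischaemic stroke rates per 100 patient-years; the
  # loader converts them to per-cycle probabilities. low/high are the
  # printed per-cycle probability ranges.
  recurrence_closure: {annual_rate_pct: 0.58, low: 0.00079, high: 0.00212, distribution: beta}
  recurrence_medical: {annual_rate_pct: 1.07, low: 0.0017, high: 0.00367, distribution: beta}
  # Severity split of recurrent strokes (must sum to 1).
  proportion_minor: {base: 0.534, low: 0.470, high: 0.596, distribution: fixed}
  proportion_moderate: {base: 0.324, low: 0.267, high: 0.386, distribution: fixed}
  proportion_fatal: {base: 0.142, low: 0.102, high: 0.192, distribution: fixed}
  rr_moderate_nonstroke_death: {base: 1.68, low: 1.49, high: 1.91, distribution: fixed}
  background_mortality_q3m:
    - {age_low: 45, age_high: 50, q3m: 0.00048}
    - {age_low: 50, age_high: 55, q3m: 0.00076}
    - {age_low: 55, age_high: 60, q3m: 0.00121}
    - {age_low: 60, age_high: 65, q3m: 0.00193}
    - {age_low: 65, age_high: 70, q3m: 0.00325}
    - {age_low: 70, age_high: 75, q3m: 0.00565}
    - {age_low: 75, age_high: 80, q3m: 0.00991}

utilities:
  post_minor: {base: 0.76, low: 0.69, high: 0.82, distribution: beta}
  post_moderate: {base: 0.21, low: 0.17, high: 0.26, distribution: beta}
  recurrent_event: {base: 0.2, low: 0.16, high: 0.26, distribution: beta}
  stable_medical: {base: 0.80, low: 0.72, high: 0.88, distribution: beta}
  stable_closure_early: {base: 0.84, low: 0.80, high: 0.88, distribution: beta}  # first 6 months
  stable_closure_late: {base: 0.88, low: 0.79, high: 0.97, distribution: beta}   # after 6 months

costs:
  device: {value: 4938, currency: USD, price_year: 2021, low: 1451, high: 5926, distribution: gamma}
  procedure: {value: 517, currency: USD, price_year: 2021, low: 459, high: 574, distribution: gamma}
  other_closure: {value: 1180, currency: USD, price_year: 2021, low: 611, high: 1749, distribution: gamma}
  minor_event: {value: 12214, currency: CNY, price_year: 2020, low: 950, high: 3802, distribution: gamma}
  moderate_event: {value: 16149, currency: CNY, price_year: 2020, low: 1257, high: 5026, distribution: gamma}
  stroke_death: {value: 2154, currency: USD, price_year: 2021, low: 1077, high: 4308, distribution: gamma}
  q_post_minor: {value: 8684, currency: CNY, price_year: 2020, per: year, low: 169, high: 676, distribution: gamma}
  q_post_moderate: {value: 514, currency: USD, price_year: 2021, per: cycle, low: 257, high: 1028, distribution: gamma}
  aspirin_pack: {value: 2.3, currency: USD, price_year: 2021, low: 1.2, high: 4.7, distribution: gamma}      # 30 x 100 mg
  clopidogrel_pack: {value: 14.6, currency: USD, price_year: 2021, low: 7.3, high: 29.1, distribution: gamma} # 28 x 75 mg
  warfarin_tablet: {value: 0.08, currency: USD, price_year: 2021, distribution: fixed}     # 3 mg
  dabigatran_tablet: {value: 2.2, currency: USD, price_year: 2021, distribution: fixed}    # 110 mg
  rivaroxaban_tablet: {value: 4.2, currency: USD, price_year: 2021, distribution: fixed}   # 20 mg
  inr_test: {value: 12, currency: USD, price_year: 2021, distribution: fixed}
  inr_tests_per_year: 21

# Antithrombotic regimen distribution of the source trial's medical arm,
# used to cost base-case medical therapy (dipyridamole is not priced and
# its combination is costed as aspirin alone).
medical_regimen_mix:
  aspirin: 0.465
  warfarin: 0.252
  clopidogrel: 0.140
  aspirin_dipyridamole: 0.081
  aspirin_clopidogrel: 0.062

# Scenario parameter overrides.
scenarios:
  sf6d:
    utilities:
      post_minor: 0.8
      post_moderate: 0.59
      stable_medical: 0.87
      stable_closure_early: 0.91
      stable_closure_late: 0.96
  eq5d:
    utilities:
      post_minor: 0.87
      post_moderate: 0.51
      stable_medical: 0.87
      stable_closure_early: 0.91
      stable_closure_late: 0.96
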