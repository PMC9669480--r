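#' Convert an annual event rate to a per-cycle transition probability
#'
#' Converts an annual recurrence rate, expressed as events per 100
#' patient-years, into a transition probability per 3-month model cycle.
#' The annual rate is first turned into a quarterly instantaneous rate,
#' `-log(1 - rate/100) / 4`, which is then converted to a probability,
#' `1 - exp(-rate_3m)`. Both steps assume the event hazard is constant
#' within the year.
#'
#' @param rate_pct Numeric vector of annual rates per 100 patient-years,
#'   in `[0, 100)`.
#' @return Per-cycle transition probabilities in `[0, 1)`.
#' @examples
#' rate_to_cycle_prob(0.58) # closure arm, 0.00145316446292076
#' rate_to_cycle_prob(1.07) # medical arm, 0.0026858009288564
#' @export
rate_to_cycle_prob <- function(rate_pct) {
  if (!is.numeric(rate_pct) || any(!is.finite(rate_pct))) {
    abort("`rate_pct` must be finite numeric.")
  }
  if (any(rate_pct < 0) || any(rate_pct >= 100)) {
    abort("`rate_pct` must lie in [0, 100): it is an annual rate per 100 patient-years.")
  }
  rate_3m <- -log(1 - rate_pct / 100) / 4
  1 - exp(-rate_3m)
}

# Healthcare-sector CPI factors for China, one per calendar year.
.default_cpi <- c(
  `2015` = 1.027, `2016` = 1.038, `2017` = 1.06, `2018` = 1.043,
  `2019` = 1.024, `2020` = 1.018, `2021` = 1.004
)

.default_currency <- function() {
  list(
    cpi_by_year = .default_cpi,
    exchange_rate_cny_per_usd = 6.4515,
    gdp_per_capita_2021 = 12551.3
  )
}

#' Convert a CNY amount at a given price year to 2021 USD
#'
#' Inflates a Chinese Yuan amount from its price year to 2021 using the
#' healthcare-sector consumer price index chain (factors for the years
#' strictly after the price year, through 2021), then converts to USD at
#' the average exchange rate of 6.4515 CNY/USD. A 2021 price is converted
#' at the exchange rate alone.
#'
#' @param amount Amount in CNY (non-negative).
#' @param price_year Calendar year of the price, between 2015 and 2021.
#' @param currency Currency context: list with `cpi_by_year` (named numeric),
#'   `exchange_rate_cny_per_usd`. Defaults to the packaged 2015-2021 chain.
#' @return Amount in 2021 USD.
#' @examples
#' cny_to_usd(12214, 2020) # 1900.8, the minor stroke event cost
#' cny_to_usd(16149, 2020) # 2513.2, the moderate stroke event cost
#' @export
cny_to_usd <- function(amount, price_year, currency = .default_currency()) {
  if (any(amount < 0)) abort("`amount` must be non-negative.")
  yrs <- as.integer(names(currency$cpi_by_year))
  if (any(price_year < min(yrs)) || any(price_year > max(yrs))) {
    abort(sprintf(
      "`price_year` must be within the CPI table (%d-%d).", min(yrs), max(yrs)
    ))
  }
  infl <- vapply(price_year, function(y) {
    prod(currency$cpi_by_year[yrs > y])
  }, numeric(1))
  amount * infl / currency$exchange_rate_cny_per_usd
}

#' Convert an annual CNY cost to a quarterly 2021 USD cost
#'
#' Applies [cny_to_usd()] and divides by four cycles per year, matching the
#' derivation of the quarterly post-stroke maintenance costs.
#'
#' @inheritParams cny_to_usd
#' @return Cost in 2021 USD per 3-month cycle.
#' @examples
#' annual_cny_to_quarterly_usd(8684, 2020) # 337.9 per cycle
#' @export
annual_cny_to_quarterly_usd <- function(amount, price_year,
                                        currency = .default_currency()) {
  cny_to_usd(amount, price_year, currency) / 4
}

#' Willingness-to-pay threshold from per-capita GDP
#'
#' The decision threshold follows Chinese pharmacoeconomic guidance:
#' three times the per-capita gross domestic product per QALY gained.
#'
#' @param gdp_per_capita Per-capita GDP in USD (non-negative).
#' @return Willingness-to-pay in USD per QALY.
#' @examples
#' wtp_threshold(12551.3) # 37653.9 USD/QALY
#' @export
wtp_threshold <- function(gdp_per_capita) {
  if (any(gdp_per_capita < 0)) abort("`gdp_per_capita` must be non-negative.")
  3 * gdp_per_capita
}

# Three-month background mortality of the Chinese general population,
# by 5-year age band (half-open [age_low, age_high)).
.default_mortality <- function() {
  tibble::tibble(
    age_low = c(45, 50, 55, 60, 65, 70, 75),
    age_high = c(50, 55, 60, 65, 70, 75, 80),
    q3m = c(0.00048, 0.00076, 0.00121, 0.00193, 0.00325, 0.00565, 0.00991)
  )
}

#' Background (non-stroke) mortality per 3-month cycle
#'
#' Looks up the 3-month all-cause mortality of the general population for
#' the 5-year age band containing `age`. Bands are half-open
#' `[age_low, age_high)`, covering ages 45 to 80.
#'
#' @param age Numeric vector of ages in years, each in `[45, 80)`.
#' @param bands Mortality table: tibble with `age_low`, `age_high`, `q3m`.
#' @return Per-cycle death probabilities.
#' @examples
#' background_mortality(46) # 0.00048
#' background_mortality(75.75) # 0.00991
#' @export
background_mortality <- function(age, bands = .default_mortality()) {
  if (any(age < min(bands$age_low)) || any(age >= max(bands$age_high))) {
    abort(sprintf(
      "`age` must lie in [%g, %g): outside mortality table coverage.",
      min(bands$age_low), max(bands$age_high)
    ))
  }
  bands$q3m[findInterval(age, bands$age_low)]
}
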