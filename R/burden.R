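# Healthy life years gained (HLYG) = years of life lost (YLL) averted plus
# years lived with disability (YLD) averted, relative to the null scenario.
# YLD uses prevalent case-years (occupancy of the depression/anxiety state)
# times the combined disability weight; YLL caps remaining life expectancy
# at the model horizon. Health impacts are undiscounted by default; costs
# are discounted at 3% elsewhere.

#' Years of life lost for averted deaths in one cohort-year
#'
#' Each averted death gains the smaller of the remaining life expectancy
#' (`life_expectancy - age`) and the time left before the model horizon
#' closes, floored at zero.
#'
#' @param deaths_averted Number of deaths averted (>= 0).
#' @param age Current age of the cohort (<= 100).
#' @param life_expectancy Average life expectancy in the country, years.
#' @param years_remaining_in_horizon Years left before the end of the model
#'   time horizon.
#' @return YLL in years.
#' @examples
#' yll_for_cohort(1, 15, 80, 100)  # 65
#' yll_for_cohort(1, 15, 80, 10)   # 10
#' @export
yll_for_cohort <- function(deaths_averted, age, life_expectancy,
                           years_remaining_in_horizon) {
  if (any(deaths_averted < 0) || any(age < 0) || any(age > 100) ||
      any(life_expectancy < 0) || any(years_remaining_in_horizon < 0))
    stop("inputs must be non-negative (age <= 100)")
  deaths_averted * pmax(pmin(life_expectancy - age,
                             years_remaining_in_horizon), 0)
}

#' Years lived with disability for one model year
#'
#' @param prevalent_cases_averted Prevalent depression/anxiety case-years
#'   averted during the year (>= 0).
#' @param disability_weight Combined disability weight in `[0, 1]`.
#' @return YLD in years.
#' @export
yld_for_year <- function(prevalent_cases_averted, disability_weight) {
  if (any(prevalent_cases_averted < 0)) stop("cases averted must be >= 0")
  if (any(disability_weight < 0 | disability_weight > 1))
    stop("disability weight must lie in [0, 1]")
  prevalent_cases_averted * disability_weight
}

#' Discount an annual stream to its present value
#'
#' End-of-year convention with the base year at `t = 0` (first element
#' undiscounted): `sum(values[t] / (1 + rate)^t)`, `t = 0, 1, ...`.
#'
#' @param values Numeric vector, one value per year starting at the base
#'   year.
#' @param rate Annual discount rate (>= 0).
#' @return The discounted total.
#' @examples
#' discount_stream(c(0, 100), 0.03)  # 97.087
#' @export
discount_stream <- function(values, rate) {
  if (rate < 0) stop("'rate' must be >= 0")
  sum(values / (1 + rate)^(seq_along(values) - 1))
}

#' Burden averted by an intervention relative to the null scenario
#'
#' YLL: suicide deaths averted per (year, age) times
#' `min(life_expectancy - age, horizon - year)` floored at zero. YLD:
#' prevalent depression/anxiety case-years averted per year times the
#' combined disability weight. Both streams are discounted at
#' `discount_health` (default 0) with model year 1 as the undiscounted base
#' year. Yearly net averted quantities may be negative in late years (people
#' kept alive by the intervention remain at risk); streams are aggregated
#' signed.
#'
#' @param null_trace,intervention_trace `state_trace` objects from
#'   [run_scenario()] on the same profile.
#' @param discount_health Annual discount rate applied to health impacts
#'   (default 0).
#' @return A list of class `burden_result`: `yll_by_year`, `yld_by_year`,
#'   `hlyg_total` (discounted YLL + YLD), `yll_total`, `yld_total`,
#'   `yld_share`, `cases_averted_by_year`, `suicides_averted_by_year`,
#'   `discount_rate_health`.
#' @export
compute_burden <- function(null_trace, intervention_trace,
                           discount_health = 0) {
  av <- averted(null_trace, intervention_trace)
  horizon <- null_trace$horizon
  le <- null_trace$life_expectancy
  dw <- null_trace$disability_weight
  sui_av <- null_trace$suicides_by_age - intervention_trace$suicides_by_age
  # gain[t, a] = min(life expectancy remaining, horizon remaining), >= 0
  gain <- pmax(pmin(outer(rep(1, horizon), le - AGES),
                    outer(horizon - seq_len(horizon), rep(1, length(AGES)))),
               0)
  yll_by_year <- rowSums(sui_av * gain)
  prev_av <- null_trace$summary$prevalent_cases -
    intervention_trace$summary$prevalent_cases
  yld_by_year <- prev_av * dw
  yll_total <- discount_stream(yll_by_year, discount_health)
  yld_total <- discount_stream(yld_by_year, discount_health)
  hlyg <- yll_total + yld_total
  structure(list(
    yll_by_year = yll_by_year, yld_by_year = yld_by_year,
    yll_total = yll_total, yld_total = yld_total, hlyg_total = hlyg,
    yld_share = if (hlyg > 0) yld_total / hlyg else NA_real_,
    cases_averted_by_year = av$cases_averted,
    suicides_averted_by_year = av$suicides_averted,
    discount_rate_health = discount_health
  ), class = "burden_result")
}
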