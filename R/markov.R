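# Four-state annual-cycle Markov cohort model. Alive states: at-risk
# (general), at-risk (subthreshold) and depression/anxiety; dead states
# (suicide, other causes) are absorbing. The at-risk state is split into
# general and subthreshold compartments so the indicated program can target
# students with subthreshold depression/anxiety; the universal program
# covers both compartments. All flows are computed simultaneously on
# start-of-cycle occupancy (no within-cycle compounding), then ageing,
# births and migration are applied — the same event order as the
# demographic projection.

#' Specify an intervention scenario
#'
#' @param program `"null"` (comparator with all intervention impacts
#'   removed), `"universal"` (all secondary-school students aged 12-17) or
#'   `"indicated"` (only students screened as having subthreshold
#'   depression/anxiety).
#' @param coverage_target Population coverage among eligible adolescents at
#'   full implementation (default 0.95).
#' @param eligible_ages Ages receiving the program (default 12:17).
#' @param enrolment_adjusted If `TRUE`, coverage is further multiplied by the
#'   country's secondary-school enrolment (adolescents out of school are not
#'   reached).
#' @param subthreshold_fraction Fraction of the eligible-age at-risk
#'   population with subthreshold depression/anxiety (default 0.05).
#' @param subthreshold_incidence_multiplier Relative incidence of
#'   depression/anxiety among subthreshold adolescents (default 2).
#' @param dep_state_suicide_multiplier Relative suicide rate in the
#'   depression/anxiety state versus at-risk (default 1: no differential).
#' @param rollout Stage schedule: planning (year 1) and policy development
#'   (year 2) have no delivery; delivery ramps linearly over
#'   `delivery_start..(full_start-1)` (default 1/3, 2/3, 1 across years
#'   3-5); full implementation from `full_start` (default 6) onwards.
#' @param effects An `effect_spec` (see [default_effect_spec()]).
#' @param rr_incidence,rr_suicide Optional explicit relative risks; by
#'   default resolved from `effects` according to `program`. Intervention
#'   effects last one year and are renewed each year a cohort remains
#'   eligible; they attenuate completely after leaving eligibility.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(program = c("null", "universal", "indicated"),
                          coverage_target = 0.95,
                          eligible_ages = 12:17,
                          enrolment_adjusted = TRUE,
                          subthreshold_fraction = 0.05,
                          subthreshold_incidence_multiplier = 2,
                          dep_state_suicide_multiplier = 1,
                          rollout = list(delivery_start = 3, full_start = 6),
                          effects = default_effect_spec(),
                          rr_incidence = NULL, rr_suicide = NULL) {
  program <- match.arg(program)
  if (coverage_target < 0 || coverage_target > 1)
    stop("'coverage_target' must lie in [0, 1]")
  if (min(eligible_ages) < 0 || max(eligible_ages) > 100)
    stop("'eligible_ages' must lie within 0-100")
  if (subthreshold_fraction <= 0 || subthreshold_fraction >= 1)
    stop("'subthreshold_fraction' must lie in (0, 1)")
  if (is.null(rr_incidence))
    rr_incidence <- switch(program, null = 1,
                           universal = effects$rr_dep_universal$point,
                           indicated = effects$rr_dep_indicated$point)
  if (is.null(rr_suicide))
    rr_suicide <- switch(program, null = 1,
                         universal = ,
                         indicated = effects$rr_suicide_adopted$point)
  structure(list(program = program, coverage_target = coverage_target,
                 eligible_ages = eligible_ages,
                 enrolment_adjusted = enrolment_adjusted,
                 subthreshold_fraction = subthreshold_fraction,
                 subthreshold_incidence_multiplier =
                   subthreshold_incidence_multiplier,
                 dep_state_suicide_multiplier = dep_state_suicide_multiplier,
                 rollout = rollout, effects = effects,
                 rr_incidence = rr_incidence, rr_suicide = rr_suicide),
            class = "scenario_spec")
}

#' Delivery ramp fraction for a model year
#'
#' Years before `delivery_start` return 0 (planning/policy development);
#' years from `full_start` return 1; intermediate years ramp linearly.
#'
#' @param year Model year (1-based).
#' @param rollout Stage schedule list (see [scenario_spec()]).
#' @return Fraction of target coverage delivered, in `[0, 1]`.
#' @export
rollout_fraction <- function(year, rollout = list(delivery_start = 3,
                                                  full_start = 6)) {
  ds <- rollout$delivery_start
  fs <- rollout$full_start
  ifelse(year < ds, 0, pmin((year - ds + 1) / max(fs - ds, 1), 1))
}

#' Run the Markov model under one scenario
#'
#' Baseline occupancy of the depression/anxiety state equals the combined
#' prevalence times the population; the at-risk remainder is split between
#' general and subthreshold compartments at eligible ages. Each cycle:
#' at-risk flows into depression/anxiety via combined incidence (the
#' subthreshold compartment at a multiplied rate), depression/anxiety flows
#' back via remission (returners split between compartments in proportion to
#' their occupancy), all alive states are exposed to suicide and other-cause
#' mortality. During implementation years, coverage-adjusted (and, when
#' requested, enrolment-adjusted) relative risks scale the incidence and
#' suicide rates of covered compartments at eligible ages: both at-risk
#' compartments and the depression/anxiety state for the universal program
#' (suicide effect; incidence applies to at-risk compartments only),
#' the subthreshold compartment only for the indicated program. Effects are
#' renewed annually while a cohort remains eligible and vanish afterwards.
#'
#' @param profile A `country_profile`.
#' @param scenario A `scenario_spec`.
#' @param horizon Years to simulate (default 100).
#' @param keep_trace If `TRUE` (default) store full per-state occupancy and
#'   event arrays; if `FALSE` store only the aggregates needed downstream
#'   (faster, used inside Monte Carlo loops).
#' @return A list of class `state_trace`; always contains `summary` (a
#'   data.frame with per-year totals of incident cases, suicide deaths,
#'   other-cause deaths, prevalent depression/anxiety cases at cycle start
#'   and alive population), `suicides_by_age` (year x age, sexes summed),
#'   `eligible_pop`, `disability_weight` and `horizon`; with
#'   `keep_trace = TRUE` also `occupancy` (per-state
#'   `(horizon+1) x 101 x 2` arrays, dead states cumulative by age at
#'   death), `incident_cases`, `suicide_deaths`, `deaths_other`,
#'   `migrants` and `births`.
#' @export
run_scenario <- function(profile, scenario, horizon = 100, keep_trace = TRUE) {
  if (horizon < 1) stop("'horizon' must be >= 1")
  stopifnot(inherits(profile, "country_profile"),
            inherits(scenario, "scenario_spec"))
  horizon <- as.integer(horizon)
  comb <- combine_epi(profile)
  inc_r <- comb$incidence
  mult <- scenario$subthreshold_incidence_multiplier
  dmult <- scenario$dep_state_suicide_multiplier
  p_rem <- rate_to_prob(comb$remission)
  sui_r <- profile$suicide_mortality
  oth_r <- pmax(profile$all_cause_mortality - sui_r, 0)
  p_oth <- rate_to_prob(oth_r)

  elig <- AGES >= min(scenario$eligible_ages) &
    AGES <= max(scenario$eligible_ages)
  sub_frac <- scenario$subthreshold_fraction
  enr <- if (isTRUE(scenario$enrolment_adjusted)) profile$enrolment_12_17 else 1
  active <- scenario$program != "null"

  # baseline occupancy
  D <- comb$prevalence * profile$population
  AR <- profile$population - D
  U <- AR * 0
  U[elig, ] <- sub_frac * AR[elig, ]
  S <- AR - U

  # year-invariant transition probabilities; the compiled cycle engine
  # recomputes eligible-age cells during intervention years
  p_inc_S0 <- rate_to_prob(inc_r)
  p_inc_U0 <- rate_to_prob(inc_r * mult)
  p_sui0 <- rate_to_prob(sui_r)
  p_sui_D0 <- rate_to_prob(sui_r * dmult)
  f_vec <- rollout_fraction(seq_len(horizon), scenario$rollout)
  cov_base <- scenario$coverage_target * enr
  newborns <- profile$births_per_year * c(0.49, 0.51)  # female, male split

  res <- markov_engine_cpp(
    S, U, D, p_inc_S0, p_inc_U0, p_sui0, p_sui_D0, p_oth, p_rem,
    inc_r, sui_r, profile$net_migration, f_vec, cov_base,
    scenario$rr_incidence, scenario$rr_suicide, mult, dmult, elig,
    as.integer(min(scenario$eligible_ages)),
    as.integer(max(scenario$eligible_ages) + 1L),
    sub_frac, newborns, horizon, active,
    scenario$program == "indicated", keep_trace)

  if (isTRUE(res$normalized))
    warning("per-cycle exit probabilities exceeded 1 and were normalized; ",
            "check rate inputs")
  if (isTRUE(res$clipped))
    warning("net migration outflow clipped at available population")

  incident_total <- res$incident_total
  suicide_total <- res$suicide_total
  other_total <- res$other_total
  prevalent_cases <- res$prevalent_cases
  alive_total <- res$alive_total
  eligible_pop <- res$eligible_pop
  suicides_by_age <- res$suicides_by_age
  dimnames(suicides_by_age) <- list(year = seq_len(horizon), age = AGES)

  na <- length(AGES); ns <- length(SEXES)
  if (keep_trace) {
    dn <- list(year = 0:horizon, age = AGES, sex = SEXES)
    dn1 <- list(year = seq_len(horizon), age = AGES, sex = SEXES)
    as_occ <- function(x) array(x, c(horizon + 1, na, ns), dimnames = dn)
    as_ev <- function(x) array(x, c(horizon, na, ns), dimnames = dn1)
    occ <- list(at_risk_general = as_occ(res$occ_S),
                at_risk_subthreshold = as_occ(res$occ_U),
                dep_anx = as_occ(res$occ_D),
                dead_suicide = as_occ(res$occ_dead_suicide),
                dead_other = as_occ(res$occ_dead_other))
    ev_incident <- as_ev(res$ev_incident)
    ev_suicide <- as_ev(res$ev_suicide)
    ev_other <- as_ev(res$ev_other)
    ev_migrants <- as_ev(res$ev_migrants)
  }

  out <- list(
    program = scenario$program,
    country = profile$name,
    income_group = profile$income_group,
    horizon = horizon,
    summary = data.frame(year = seq_len(horizon),
                         incident_cases = incident_total,
                         suicide_deaths = suicide_total,
                         deaths_other = other_total,
                         prevalent_cases = prevalent_cases,
                         alive = alive_total),
    suicides_by_age = suicides_by_age,
    eligible_pop = eligible_pop,
    mean_population = mean(alive_total),
    disability_weight = comb$disability_weight,
    life_expectancy = profile$life_expectancy
  )
  if (keep_trace) {
    out$occupancy <- occ
    out$incident_cases <- ev_incident
    out$suicide_deaths <- ev_suicide
    out$deaths_other <- ev_other
    out$migrants <- ev_migrants
    out$births <- rep(profile$births_per_year, horizon)
  }
  structure(out, class = "state_trace")
}

#' Year-wise averted outcomes of an intervention versus the null scenario
#'
#' @param null_trace,intervention_trace `state_trace` objects from
#'   [run_scenario()] on the same profile and horizon.
#' @return A data.frame of class `averted_outcomes` with columns `year`,
#'   `cases_averted`, `suicides_averted` (null minus intervention).
#' @export
averted <- function(null_trace, intervention_trace) {
  stopifnot(inherits(null_trace, "state_trace"),
            inherits(intervention_trace, "state_trace"))
  if (null_trace$horizon != intervention_trace$horizon ||
      !identical(null_trace$country, intervention_trace$country))
    stop("traces must share horizon and underlying profile")
  out <- data.frame(
    year = null_trace$summary$year,
    cases_averted = null_trace$summary$incident_cases -
      intervention_trace$summary$incident_cases,
    suicides_averted = null_trace$summary$suicide_deaths -
      intervention_trace$summary$suicide_deaths)
  class(out) <- c("averted_outcomes", "data.frame")
  out
}

#' Export a state trace to long format
#'
#' @param trace A `state_trace` run with `keep_trace = TRUE`.
#' @return A data.frame with columns year, age, sex, state, count.
#' @export
state_trace_long <- function(trace) {
  if (is.null(trace$occupancy))
    stop("trace was run with keep_trace = FALSE")
  do.call(rbind, lapply(names(trace$occupancy), function(st) {
    d <- as.data.frame.table(trace$occupancy[[st]], responseName = "count")
    names(d)[1:3] <- c("year", "age", "sex")
    d$year <- as.integer(as.character(d$year))
    d$age <- as.integer(as.character(d$age))
    d$state <- st
    d[, c("year", "age", "sex", "state", "count")]
  }))
}
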