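# Staged WHO-CHOICE-style costing. Years 1-2 (planning, policy development)
# carry only program-level costs; delivery-linked categories ramp with
# coverage over years 3-5 and run at full scale from year 6. Categories:
# program management, advocacy, facilitator training, program delivery
# (facilitator contact time), supplies and equipment (student materials),
# and — for the indicated program only — facilitator time spent screening
# all enrolled eligible students to find the subthreshold minority.

COST_CATEGORIES <- c("management", "advocacy", "training", "delivery",
                     "supplies_equipment", "screening")

#' Cost a scenario over the model horizon
#'
#' Delivery cost per covered student-year is
#' `session_count * session_minutes / students_per_group / 60 *
#' facilitator_wage` plus materials. Facilitator training is amortized:
#' facilitators needed = covered students / (students_per_group *
#' groups_per_facilitator); each costs `training_hours` of trainer plus
#' trainee wages, spread over `training_amortization_years` (default 5).
#' The indicated program screens every enrolled eligible student
#' (`screening_minutes_per_student` of facilitator time each) but delivers
#' only to the subthreshold fraction. Program-level overheads (management,
#' advocacy) run every year from year 1. The null program costs nothing.
#'
#' @param profile A `country_profile`.
#' @param scenario A `scenario_spec`.
#' @param horizon Years (default 100).
#' @param trace Optional `state_trace` for this scenario (re-used for the
#'   eligible-age population series); computed if missing.
#' @param discount_cost Annual discount rate for costs (default 0.03).
#' @return A list of class `cost_trace`: `cost_by_year` (year x category
#'   matrix in I$), `total_discounted`, `total_undiscounted`,
#'   `per_capita_annualized` (undiscounted total / horizon / mean
#'   population), `mean_population`.
#' @export
cost_scenario <- function(profile, scenario, horizon = 100, trace = NULL,
                          discount_cost = 0.03) {
  uc <- profile$unit_costs
  if (any(unlist(uc[names(uc) != "program_overhead_items"]) < 0))
    stop("unit costs must be non-negative")
  if (is.null(trace))
    trace <- run_scenario(profile, scenario, horizon, keep_trace = FALSE)
  if (trace$mean_population <= 0) stop("zero population")
  horizon <- trace$horizon
  cost <- matrix(0, horizon, length(COST_CATEGORIES),
                 dimnames = list(year = seq_len(horizon), COST_CATEGORIES))
  if (scenario$program != "null") {
    overhead <- unlist(uc$program_overhead_items)
    cost[, "management"] <- overhead[["management"]]
    cost[, "advocacy"] <- overhead[["advocacy"]]
    f <- rollout_fraction(seq_len(horizon), scenario$rollout)
    enr <- if (isTRUE(scenario$enrolment_adjusted)) profile$enrolment_12_17
           else 1
    enrolled <- trace$eligible_pop * enr
    reached <- enrolled * scenario$coverage_target * f
    covered <- if (scenario$program == "indicated")
      reached * scenario$subthreshold_fraction else reached
    hours_per_student <- uc$session_count * uc$session_minutes / 60 /
      uc$students_per_group
    cost[, "delivery"] <- covered * hours_per_student * uc$facilitator_wage
    cost[, "supplies_equipment"] <- covered * uc$materials_per_student
    facilitators <- covered /
      (uc$students_per_group * uc$groups_per_facilitator)
    amort <- uc$training_amortization_years %||% 5
    cost[, "training"] <- facilitators / amort * uc$training_hours *
      (uc$trainer_wage + uc$facilitator_wage)
    if (scenario$program == "indicated")
      cost[, "screening"] <- reached *
        uc$screening_minutes_per_student / 60 * uc$facilitator_wage
  }
  yearly <- rowSums(cost)
  structure(list(
    program = scenario$program, country = profile$name,
    cost_by_year = cost,
    total_discounted = discount_stream(yearly, discount_cost),
    total_undiscounted = sum(yearly),
    per_capita_annualized = sum(yearly) / horizon / trace$mean_population,
    mean_population = trace$mean_population,
    discount_rate_cost = discount_cost,
    horizon = horizon
  ), class = "cost_trace")
}
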