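# Average cost-effectiveness ratios and per-million standardization.
# ACER = total discounted intervention cost / incremental HLYGs versus the
# null scenario; rates are standardized per 1 million population per year
# using the mean projected population over the horizon.

#' Combine a cost trace and a burden result into a CEA result
#'
#' @param cost_trace A `cost_trace` from [cost_scenario()].
#' @param burden A `burden_result` from [compute_burden()].
#' @param country,program,income_group Labels (defaulted from the inputs).
#' @return A one-row data.frame: country, income_group, program, total_cost
#'   (discounted I$), hlyg, acer (`NA` with `acer_undefined = TRUE` when
#'   hlyg is zero or negative), yll, yld, yld_share, cases_averted_total,
#'   suicides_averted_total, the per-million-per-year standardized rates,
#'   per-capita annualized cost, mean_population and horizon.
#' @export
compute_acer <- function(cost_trace, burden,
                         country = cost_trace$country,
                         program = cost_trace$program,
                         income_group = NA_character_) {
  stopifnot(inherits(cost_trace, "cost_trace"),
            inherits(burden, "burden_result"))
  hlyg <- burden$hlyg_total
  undefined <- !(hlyg > 0)
  horizon <- cost_trace$horizon
  pm <- cost_trace$mean_population / 1e6
  data.frame(
    country = country, income_group = income_group, program = program,
    total_cost = cost_trace$total_discounted,
    hlyg = hlyg,
    acer = if (undefined) NA_real_ else cost_trace$total_discounted / hlyg,
    acer_undefined = undefined,
    yll = burden$yll_total, yld = burden$yld_total,
    yld_share = burden$yld_share,
    cases_averted_total = sum(burden$cases_averted_by_year),
    suicides_averted_total = sum(burden$suicides_averted_by_year),
    cases_averted_per_million_per_year =
      sum(burden$cases_averted_by_year) / horizon / pm,
    suicides_averted_per_million_per_year =
      sum(burden$suicides_averted_by_year) / horizon / pm,
    hlyg_per_million_per_year = hlyg / horizon / pm,
    cost_per_capita_per_year = cost_trace$per_capita_annualized,
    mean_population = cost_trace$mean_population,
    horizon = horizon,
    stringsAsFactors = FALSE)
}

#' Run null + intervention scenarios for one country
#'
#' Runs the null scenario once and each requested program against it,
#' returning one CEA row per program.
#'
#' @param profile A `country_profile`.
#' @param programs Programs to evaluate (default universal and indicated).
#' @param horizon Years (default 100).
#' @param effects An `effect_spec`.
#' @param scenario_args Named list of extra arguments passed to
#'   [scenario_spec()] (coverage, subthreshold settings, rollout, explicit
#'   RR overrides, ...).
#' @param discount_cost,discount_health Annual discount rates (defaults
#'   0.03 and 0).
#' @return A data.frame with one row per program (see [compute_acer()]).
#' @export
run_country <- function(profile, programs = c("universal", "indicated"),
                        horizon = 100, effects = default_effect_spec(),
                        scenario_args = list(),
                        discount_cost = 0.03, discount_health = 0) {
  make_scen <- function(program)
    do.call(scenario_spec, c(list(program = program, effects = effects),
                             scenario_args))
  null_trace <- run_scenario(profile, make_scen("null"), horizon,
                             keep_trace = FALSE)
  do.call(rbind, lapply(programs, function(pr) {
    scen <- make_scen(pr)
    tr <- run_scenario(profile, scen, horizon, keep_trace = FALSE)
    burden <- compute_burden(null_trace, tr, discount_health)
    # standardize against the undisturbed (null) population
    ct <- cost_scenario(profile, scen, horizon, trace = tr,
                        discount_cost = discount_cost)
    ct$mean_population <- null_trace$mean_population
    ct$per_capita_annualized <- ct$total_undiscounted / horizon /
      null_trace$mean_population
    compute_acer(ct, burden, income_group = profile$income_group)
  }))
}

#' Run the full country portfolio
#'
#' @param profiles List of `country_profile`s (see [generate_portfolio()]).
#' @param ... Passed to [run_country()].
#' @return A data.frame with one row per country x program.
#' @export
run_portfolio <- function(profiles, ...) {
  do.call(rbind, lapply(profiles, run_country, ...))
}

#' Aggregate CEA results over a group of countries
#'
#' Group totals are sums of costs and HLYGs; the group ACER is the ratio of
#' sums (not the mean of country ratios); standardized per-million rates are
#' recomputed from summed counts and summed population, i.e.
#' population-weighted.
#'
#' @param results A data.frame of CEA rows for one program (from
#'   [run_country()]/[run_portfolio()]).
#' @param label Group label for the `country` field.
#' @return A one-row data.frame in the same shape.
#' @export
aggregate_group <- function(results, label = "group") {
  if (nrow(results) == 0) stop("empty result set")
  if (length(unique(results$program)) != 1)
    stop("aggregate one program at a time")
  horizon <- results$horizon[1]
  pop <- sum(results$mean_population)
  cost <- sum(results$total_cost)
  hlyg <- sum(results$hlyg)
  cases <- sum(results$cases_averted_total)
  suis <- sum(results$suicides_averted_total)
  yld <- sum(results$yld)
  undefined <- !(hlyg > 0)
  data.frame(
    country = label,
    income_group = if (length(unique(results$income_group)) == 1)
      results$income_group[1] else "all",
    program = results$program[1],
    total_cost = cost, hlyg = hlyg,
    acer = if (undefined) NA_real_ else cost / hlyg,
    acer_undefined = undefined,
    yll = sum(results$yll), yld = yld,
    yld_share = if (hlyg > 0) yld / hlyg else NA_real_,
    cases_averted_total = cases, suicides_averted_total = suis,
    cases_averted_per_million_per_year = cases / horizon / (pop / 1e6),
    suicides_averted_per_million_per_year = suis / horizon / (pop / 1e6),
    hlyg_per_million_per_year = hlyg / horizon / (pop / 1e6),
    cost_per_capita_per_year =
      sum(results$cost_per_capita_per_year * results$mean_population) / pop,
    mean_population = pop, horizon = horizon,
    stringsAsFactors = FALSE)
}

#' Income-group x program summary of a portfolio run
#'
#' The headline output table: for each income group and program, annualized
#' per-capita cost, cases and suicides averted and HLYGs per 1 million
#' population per year, and the group ACER.
#'
#' @param results Per-country CEA rows from [run_portfolio()].
#' @return A data.frame with one row per income group x program (plus
#'   all-country rows per program).
#' @export
summarize_portfolio <- function(results) {
  rows <- list()
  for (pr in unique(results$program)) {
    sub <- results[results$program == pr, ]
    for (grp in unique(sub$income_group))
      rows[[paste(grp, pr)]] <-
        aggregate_group(sub[sub$income_group == grp, ], label = grp)
    rows[[paste("all", pr)]] <- aggregate_group(sub, label = "all")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
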