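# Seeded synthetic country profiles with the statistical structure the model
# assumes: a 1-year age x sex population pyramid, Siler-shaped all-cause
# mortality, suicide mortality ramping up through adolescence, depression and
# anxiety incidence peaking in young adulthood with near-steady-state
# prevalence, secondary-school enrolment, and WHO-CHOICE-style unit costs
# that differ by income group. These are stand-ins emulating the shape of
# real demographic/epidemiological inputs, not any country's actual data.

income_group_defaults <- function(income_group) {
  switch(income_group,
    LLMIC = list(
      pop_mean = 4e7, pop_sdlog = 0.5,
      growth = 0.025,                    # pyramid steepness: young population
      life_expectancy = c(67, 2),
      enrolment_mean = 0.62,
      siler = c(A = 0.05, B = 1.0, C = 1.0e-3, D = 5.0e-5, E = 0.085),
      suicide_plateau = c(female = 0.6e-4, male = 1.8e-4),
      unit_costs = list(
        facilitator_wage = 5.0, trainer_wage = 8.0, supervisor_wage = 7.0,
        materials_per_student = 0.50, screening_minutes_per_student = 10,
        session_count = 10, session_minutes = 45, students_per_group = 25,
        training_hours = 16, groups_per_facilitator = 4,
        program_overhead_items = list(management = 3.0e5, advocacy = 1.5e5))),
    UMHIC = list(
      pop_mean = 4e7, pop_sdlog = 0.5,
      growth = 0.005,                    # flatter, older pyramid
      life_expectancy = c(78, 1.5),
      enrolment_mean = 0.92,
      siler = c(A = 0.02, B = 1.2, C = 4.0e-4, D = 2.5e-5, E = 0.092),
      suicide_plateau = c(female = 0.5e-4, male = 1.5e-4),
      unit_costs = list(
        facilitator_wage = 5.5, trainer_wage = 9.0, supervisor_wage = 8.0,
        materials_per_student = 0.60, screening_minutes_per_student = 10,
        session_count = 10, session_minutes = 45, students_per_group = 25,
        training_hours = 16, groups_per_facilitator = 4,
        program_overhead_items = list(management = 6.0e5, advocacy = 3.0e5))),
    stop(sprintf("unknown income group '%s' (expected LLMIC or UMHIC)",
                 income_group))
  )
}

# log-normal-shaped age curve on 0-100, rescaled to peak at 1
lnorm_age_shape <- function(peak_age, sdlog) {
  s <- stats::dlnorm(pmax(AGES, 0.5), meanlog = log(peak_age) + sdlog^2,
                     sdlog = sdlog)
  s / max(s)
}

#' Generate a seeded synthetic country profile
#'
#' Builds one complete input bundle for the cost-effectiveness model: base
#' year population by single year of age (0-100, with 100 treated as 100+)
#' and sex, annual births, net migration, all-cause and suicide mortality
#' rates, depression and anxiety epidemiology (prevalence, incidence,
#' remission by age and sex), secondary-school enrolment among ages 12-17,
#' average life expectancy, disability weights, and unit costs for program
#' delivery. Deterministic for a fixed seed. Depression/anxiety incidence has
#' an adolescent/young-adult peak, suicide mortality rises from near zero in
#' childhood through adolescence, and prevalence is set at the steady state
#' implied by incidence and remission (with small noise), so the Markov model
#' starts near epidemiological equilibrium.
#'
#' @param seed Non-negative integer seed.
#' @param income_group `"LLMIC"` (low- and lower-middle-income) or `"UMHIC"`
#'   (upper-middle- and high-income). UMHIC profiles have higher unit costs,
#'   higher enrolment, lower mortality and an older age structure.
#' @param name Optional profile label.
#' @return A list of class `country_profile`.
#' @examples
#' p <- generate_country(1, "LLMIC")
#' sum(p$population)  # total base-year population
#' @export
generate_country <- function(seed, income_group = c("LLMIC", "UMHIC"),
                             name = NULL) {
  if (!is.numeric(seed) || length(seed) != 1L || seed < 0 || seed != floor(seed))
    stop("'seed' must be a non-negative integer")
  income_group <- match.arg(income_group)
  g <- income_group_defaults(income_group)

  profile <- withr::with_seed(as.integer(seed %% 2147483647), {
    total_pop <- stats::rlnorm(1, log(g$pop_mean), g$pop_sdlog)

    # pyramid: exponential decline with age, damped by survivorship at old
    # ages, mild multiplicative noise per age
    shape <- exp(-g$growth * AGES) * exp(-(pmax(AGES - 65, 0) / 30)^2)
    shape <- shape * stats::rlnorm(length(AGES), 0, 0.02)
    pop <- age_sex_matrix()
    pop[, "female"] <- 0.49 * shape
    pop[, "male"] <- 0.51 * shape
    pop <- pop / sum(pop) * total_pop

    births <- sum(pop[1, ]) * stats::rlnorm(1, 0, 0.03)

    # Siler all-cause mortality, sex-differentiated, small level noise
    s <- g$siler
    m_age <- s["A"] * exp(-s["B"] * AGES) + s["C"] + s["D"] * exp(s["E"] * AGES)
    mort <- age_sex_matrix()
    mort[, "female"] <- m_age * 0.85
    mort[, "male"] <- m_age * 1.20
    mort <- mort * stats::rlnorm(1, 0, 0.05)

    # suicide mortality: logistic ramp from age ~10, sex-specific plateau
    ramp <- stats::plogis((AGES - 15) / 1.5) * (AGES >= 6)
    sui <- age_sex_matrix()
    sui[, "female"] <- g$suicide_plateau["female"] * ramp
    sui[, "male"] <- g$suicide_plateau["male"] * ramp
    sui <- sui * stats::rlnorm(1, 0, 0.10)
    sui <- pmin(sui, 0.9 * mort)  # suicide is a component of all-cause

    epi <- function(peak_f, peak_m, peak_age, sdlog, baseline, remission) {
      shape <- lnorm_age_shape(peak_age, sdlog)
      inc <- age_sex_matrix()
      inc[, "female"] <- peak_f * (baseline + (1 - baseline) * shape)
      inc[, "male"] <- peak_m * (baseline + (1 - baseline) * shape)
      inc <- inc * stats::rlnorm(1, 0, 0.08)
      rem <- age_sex_matrix(remission) * stats::rlnorm(1, 0, 0.05)
      prev <- inc / (inc + rem) * stats::rlnorm(1, 0, 0.03)
      list(prevalence = prev, incidence = inc, remission = rem)
    }
    dep <- epi(0.022, 0.015, peak_age = 20, sdlog = 0.45,
               baseline = 0.25, remission = 0.30)
    anx <- epi(0.016, 0.011, peak_age = 15, sdlog = 0.55,
               baseline = 0.30, remission = 0.22)

    enr <- stats::rbeta(1, g$enrolment_mean * 80, (1 - g$enrolment_mean) * 80)
    le <- stats::rnorm(1, g$life_expectancy[1], g$life_expectancy[2])

    # small net in-migration concentrated at working ages
    mig <- age_sex_matrix()
    mig_shape <- stats::dnorm(AGES, 28, 8)
    mig_total <- total_pop * stats::runif(1, -5e-4, 1.5e-3)
    mig[, "female"] <- 0.5 * mig_total * mig_shape / sum(mig_shape)
    mig[, "male"] <- 0.5 * mig_total * mig_shape / sum(mig_shape)

    uc <- g$unit_costs
    wage_noise <- stats::rlnorm(1, 0, 0.10)
    uc$facilitator_wage <- uc$facilitator_wage * wage_noise
    uc$trainer_wage <- uc$trainer_wage * wage_noise
    uc$supervisor_wage <- uc$supervisor_wage * wage_noise
    uc$materials_per_student <- uc$materials_per_student *
      stats::rlnorm(1, 0, 0.10)

    structure(list(
      name = name %||% sprintf("%s-seed%d", income_group, seed),
      income_group = income_group,
      population = pop,
      births_per_year = births,
      net_migration = mig,
      all_cause_mortality = mort,
      suicide_mortality = sui,
      dep_epi = dep,
      anx_epi = anx,
      enrolment_12_17 = enr,
      life_expectancy = le,
      dw_dep = 0.30,
      dw_anx = 0.20,
      comorbidity_k = 2,
      unit_costs = uc
    ), class = "country_profile")
  })
  validate_country_profile(profile)
  profile
}

#' Validate the invariants of a country profile
#'
#' Checks non-negative counts and rates, prevalences in `[0, 1)`, enrolment
#' in `[0, 1]`, the full 0-100 x sex grid, and that every per-cycle exit
#' probability implied by the rates stays within `[0, 1]`.
#'
#' @param profile A `country_profile`.
#' @return The profile, invisibly; errors on violation.
#' @export
validate_country_profile <- function(profile) {
  stopifnot(inherits(profile, "country_profile"))
  grids <- list(population = profile$population,
                all_cause_mortality = profile$all_cause_mortality,
                suicide_mortality = profile$suicide_mortality)
  for (nm in names(grids)) {
    m <- grids[[nm]]
    if (!identical(dim(m), c(length(AGES), length(SEXES))))
      stop(sprintf("'%s' must be a 101 x 2 (age x sex) matrix", nm))
    if (any(m < 0)) stop(sprintf("'%s' has negative entries", nm))
  }
  for (cond in c("dep_epi", "anx_epi")) {
    e <- profile[[cond]]
    if (any(e$prevalence < 0 | e$prevalence >= 1))
      stop(sprintf("%s prevalence outside [0, 1)", cond))
    if (any(e$incidence < 0) || any(e$remission < 0))
      stop(sprintf("%s incidence/remission negative", cond))
  }
  if (profile$enrolment_12_17 < 0 || profile$enrolment_12_17 > 1)
    stop("enrolment must lie in [0, 1]")
  if (any(unlist(profile$unit_costs[names(profile$unit_costs) !=
                                      "program_overhead_items"]) < 0))
    stop("unit costs must be non-negative")
  # exit probabilities per cycle cannot exceed 1
  comb <- combine_epi(profile)
  exit_alive <- rate_to_prob(comb$incidence) +
    rate_to_prob(profile$suicide_mortality) +
    rate_to_prob(pmax(profile$all_cause_mortality -
                        profile$suicide_mortality, 0))
  if (any(exit_alive > 1))
    stop("per-cycle exit probability exceeds 1; rates inconsistent")
  invisible(profile)
}

#' Generate a portfolio of synthetic countries
#'
#' Draws `n_llmic` low-/lower-middle-income and `n_umhic` upper-middle-/
#' high-income profiles with distinct sub-seeds derived from `seed`. The
#' default analysis portfolio is 10 + 10, echoing a 20-country study set
#' spanning both income groups.
#'
#' @param n_llmic,n_umhic Non-negative counts (at least one in total).
#' @param seed Integer seed for the whole portfolio.
#' @return A list of `country_profile` objects, LLMIC first.
#' @export
generate_portfolio <- function(n_llmic = 10, n_umhic = 10, seed = 1) {
  if (n_llmic < 0 || n_umhic < 0) stop("country counts must be non-negative")
  if (n_llmic + n_umhic < 1) stop("portfolio must contain at least one country")
  subseed <- function(i) (as.numeric(seed) * 10007 + i) %% 2147483647
  c(
    lapply(seq_len(n_llmic), function(i)
      generate_country(subseed(i), "LLMIC", name = sprintf("LLMIC-%02d", i))),
    lapply(seq_len(n_umhic), function(i)
      generate_country(subseed(n_llmic + i), "UMHIC",
                       name = sprintf("UMHIC-%02d", i)))
  )
}

#' Write a country profile to a directory of CSV tables plus a YAML header
#'
#' Schema (fixed so real country data can later be dropped in):
#' `profile.yaml` holds scalars and unit costs; `population.csv` (age, sex,
#' count); `mortality.csv` (age, sex, all_cause, suicide); `epidemiology.csv`
#' (age, sex, condition, prevalence, incidence, remission);
#' `migration.csv` (age, sex, net_migration).
#'
#' @param profile A `country_profile`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_country_profile <- function(profile, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- function(m) data.frame(age = rep(AGES, times = 2),
                                 sex = rep(SEXES, each = length(AGES)),
                                 value = as.vector(m))
  hdr <- list(name = profile$name, income_group = profile$income_group,
              births_per_year = profile$births_per_year,
              enrolment_12_17 = profile$enrolment_12_17,
              life_expectancy = profile$life_expectancy,
              dw_dep = profile$dw_dep, dw_anx = profile$dw_anx,
              comorbidity_k = profile$comorbidity_k,
              unit_costs = profile$unit_costs)
  yaml::write_yaml(hdr, file.path(dir, "profile.yaml"), precision = 15)
  p <- long(profile$population); names(p)[3] <- "count"
  utils::write.csv(p, file.path(dir, "population.csv"), row.names = FALSE)
  m <- long(profile$all_cause_mortality); names(m)[3] <- "all_cause"
  m$suicide <- as.vector(profile$suicide_mortality)
  utils::write.csv(m, file.path(dir, "mortality.csv"), row.names = FALSE)
  epi <- do.call(rbind, lapply(c(dep = "dep", anx = "anx"), function(cond) {
    e <- profile[[paste0(cond, "_epi")]]
    d <- long(e$prevalence); names(d)[3] <- "prevalence"
    d$condition <- cond
    d$incidence <- as.vector(e$incidence)
    d$remission <- as.vector(e$remission)
    d[, c("age", "sex", "condition", "prevalence", "incidence", "remission")]
  }))
  utils::write.csv(epi, file.path(dir, "epidemiology.csv"), row.names = FALSE)
  mg <- long(profile$net_migration); names(mg)[3] <- "net_migration"
  utils::write.csv(mg, file.path(dir, "migration.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a country profile written by [write_country_profile()]
#'
#' @param dir Directory containing the profile tables.
#' @return A `country_profile`.
#' @export
read_country_profile <- function(dir) {
  hdr <- yaml::read_yaml(file.path(dir, "profile.yaml"))
  wide <- function(df, col) {
    m <- age_sex_matrix()
    for (s in SEXES) {
      d <- df[df$sex == s, ]
      m[match(d$age, AGES), s] <- d[[col]]
    }
    m
  }
  pop <- utils::read.csv(file.path(dir, "population.csv"))
  mort <- utils::read.csv(file.path(dir, "mortality.csv"))
  epi <- utils::read.csv(file.path(dir, "epidemiology.csv"))
  mig <- utils::read.csv(file.path(dir, "migration.csv"))
  epi_of <- function(cond) {
    d <- epi[epi$condition == cond, ]
    list(prevalence = wide(d, "prevalence"), incidence = wide(d, "incidence"),
         remission = wide(d, "remission"))
  }
  profile <- structure(list(
    name = hdr$name, income_group = hdr$income_group,
    population = wide(pop, "count"),
    births_per_year = hdr$births_per_year,
    net_migration = wide(mig, "net_migration"),
    all_cause_mortality = wide(mort, "all_cause"),
    suicide_mortality = wide(mort, "suicide"),
    dep_epi = epi_of("dep"), anx_epi = epi_of("anx"),
    enrolment_12_17 = hdr$enrolment_12_17,
    life_expectancy = hdr$life_expectancy,
    dw_dep = hdr$dw_dep, dw_anx = hdr$dw_anx,
    comorbidity_k = hdr$comorbidity_k,
    unit_costs = hdr$unit_costs
  ), class = "country_profile")
  validate_country_profile(profile)
  profile
}
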