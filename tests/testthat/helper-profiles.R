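# Hand-built profiles with fully controlled rates, for closed-form and
# ledger oracles. Rates are flat across age and sex unless population is
# restricted to specific ages.

flat_profile <- function(pop = 1000, mort = 0, sui = 0,
                         inc_dep = 0, rem_dep = 0.3, prev_dep = 0,
                         inc_anx = 0, rem_anx = 0.3, prev_anx = 0,
                         births = 0, mig = 0, enrolment = 1, le = 80,
                         ages = NULL, income = "LLMIC", name = "toy",
                         wage = 1, overhead = 0, k = 1) {
  asm <- function(x = 0) matrix(x, nrow = 101, ncol = 2,
                                dimnames = list(age = 0:100,
                                                sex = c("female", "male")))
  popm <- asm(0)
  if (is.null(ages)) popm[] <- pop else popm[ages + 1, ] <- pop
  structure(list(
    name = name, income_group = income,
    population = popm,
    births_per_year = births,
    net_migration = asm(mig),
    all_cause_mortality = asm(mort + sui),
    suicide_mortality = asm(sui),
    dep_epi = list(prevalence = asm(prev_dep), incidence = asm(inc_dep),
                   remission = asm(rem_dep)),
    anx_epi = list(prevalence = asm(prev_anx), incidence = asm(inc_anx),
                   remission = asm(rem_anx)),
    enrolment_12_17 = enrolment, life_expectancy = le,
    dw_dep = 0.30, dw_anx = 0.20, comorbidity_k = k,
    unit_costs = list(
      facilitator_wage = wage, trainer_wage = wage, supervisor_wage = wage,
      materials_per_student = 0.5, screening_minutes_per_student = 10,
      session_count = 10, session_minutes = 45, students_per_group = 25,
      training_hours = 16, groups_per_facilitator = 4,
      program_overhead_items = list(management = overhead, advocacy = 0))
  ), class = "country_profile")
}

# Brute-force scalar-loop reference of the Markov cycle: enumerates every
# flow per cell per year from the documented update rule. Deliberately
# written as plain nested loops, independent of the package's engine.
reference_markov <- function(profile, scenario, horizon) {
  p <- function(r) 1 - exp(-r)
  comb_prev <- combine_prevalence(profile$dep_epi$prevalence,
                                  profile$anx_epi$prevalence,
                                  profile$comorbidity_k)
  inc <- profile$dep_epi$incidence + profile$anx_epi$incidence -
    profile$comorbidity_k * profile$dep_epi$incidence *
    profile$anx_epi$incidence
  pd <- profile$dep_epi$prevalence; pa <- profile$anx_epi$prevalence
  rem <- ifelse(pd + pa > 0,
                (pd * profile$dep_epi$remission +
                   pa * profile$anx_epi$remission) / pmax(pd + pa, 1e-300),
                (profile$dep_epi$remission + profile$anx_epi$remission) / 2)
  sui <- profile$suicide_mortality
  oth <- pmax(profile$all_cause_mortality - sui, 0)
  elig_age <- function(a) a >= min(scenario$eligible_ages) &&
    a <= max(scenario$eligible_ages)
  enr <- if (isTRUE(scenario$enrolment_adjusted)) profile$enrolment_12_17 else 1

  D <- comb_prev * profile$population
  S <- profile$population - D
  U <- S * 0
  for (a in 0:100) if (elig_age(a)) {
    U[a + 1, ] <- scenario$subthreshold_fraction * S[a + 1, ]
    S[a + 1, ] <- S[a + 1, ] - U[a + 1, ]
  }
  occ <- list(S = list(S), U = list(U), D = list(D))
  cases <- numeric(horizon); suicides <- numeric(horizon)
  for (t in 1:horizon) {
    f <- rollout_fraction(t, scenario$rollout)
    Sn <- S * 0; Un <- S * 0; Dn <- S * 0
    case_t <- 0; sui_t <- 0
    for (s in 1:2) for (a in 0:100) {
      i <- a + 1
      covf <- if (scenario$program != "null" && elig_age(a))
        f * scenario$coverage_target * enr else 0
      rri <- 1 - covf * (1 - scenario$rr_incidence)
      rrs <- 1 - covf * (1 - scenario$rr_suicide)
      if (scenario$program == "indicated") {
        rri_S <- 1; rrs_S <- 1; rrs_D <- 1
      } else {
        rri_S <- rri; rrs_S <- rrs; rrs_D <- rrs
      }
      pSi <- p(inc[i, s] * rri_S)
      pUi <- p(inc[i, s] * scenario$subthreshold_incidence_multiplier * rri)
      pSs <- p(sui[i, s] * rrs_S)
      pUs <- p(sui[i, s] * rrs)
      pDs <- p(sui[i, s] * scenario$dep_state_suicide_multiplier * rrs_D)
      po <- p(oth[i, s]); pr <- p(rem[i, s])
      sc <- function(tot) if (tot > 1) 1 / tot else 1
      kS <- sc(pSi + pSs + po); kU <- sc(pUi + pUs + po); kD <- sc(pr + pDs + po)
      iS <- S[i, s] * pSi * kS; sS <- S[i, s] * pSs * kS
      oS <- S[i, s] * po * kS
      iU <- U[i, s] * pUi * kU; sU <- U[i, s] * pUs * kU
      oU <- U[i, s] * po * kU
      rD <- D[i, s] * pr * kD; sD <- D[i, s] * pDs * kD
      oD <- D[i, s] * po * kD
      pool <- S[i, s] + U[i, s]
      rU <- if (pool > 0) rD * U[i, s] / pool else 0
      Sn[i, s] <- S[i, s] - iS - sS - oS + (rD - rU)
      Un[i, s] <- U[i, s] - iU - sU - oU + rU
      Dn[i, s] <- D[i, s] + iS + iU - rD - sD - oD
      case_t <- case_t + iS + iU
      sui_t <- sui_t + sS + sU + sD
    }
    cases[t] <- case_t; suicides[t] <- sui_t
    # ageing, 100+ absorbing, births, boundary bookkeeping, migration
    age1 <- function(m, newb) {
      r <- m * 0
      for (s in 1:2) {
        for (a in 1:99) r[a + 1, s] <- m[a, s]
        r[101, s] <- m[100, s] + m[101, s]
        r[1, s] <- newb[s]
      }
      r
    }
    S <- age1(Sn, profile$births_per_year * c(0.49, 0.51))
    U <- age1(Un, c(0, 0))
    D <- age1(Dn, c(0, 0))
    en <- min(scenario$eligible_ages) + 1
    ex <- max(scenario$eligible_ages) + 2
    for (s in 1:2) {
      mv <- scenario$subthreshold_fraction * S[en, s]
      S[en, s] <- S[en, s] - mv; U[en, s] <- U[en, s] + mv
      if (ex <= 101) { S[ex, s] <- S[ex, s] + U[ex, s]; U[ex, s] <- 0 }
    }
    for (s in 1:2) for (i in 1:101) {
      tot <- S[i, s] + U[i, s] + D[i, s]
      m <- max(profile$net_migration[i, s], -tot)
      if (tot > 0) {
        S[i, s] <- S[i, s] + m * S[i, s] / tot
        U[i, s] <- U[i, s] + m * U[i, s] / tot
        D[i, s] <- D[i, s] + m * D[i, s] / tot
      } else if (m > 0) S[i, s] <- S[i, s] + m
    }
    occ$S[[t + 1]] <- S; occ$U[[t + 1]] <- U; occ$D[[t + 1]] <- D
  }
  list(occ = occ, cases = cases, suicides = suicides)
}
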