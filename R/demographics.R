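# Cohort-component population projection: deterministic expectation
# arithmetic over 1-year age x sex cohorts with deaths (suicide and other
# causes), births into the age-0 cohort, and net migration. Age 100 is an
# absorbing 100+ bucket so the accounting ledger balances exactly.

shift_age <- function(m) {
  r <- m * 0
  r[2:100, ] <- m[1:99, ]
  r[101, ] <- m[100, ] + m[101, ]  # 100+ absorbs
  r
}

#' Project a country population forward by 1-year age-sex cohorts
#'
#' Each annual cycle applies, in this fixed order: deaths (suicide and other
#' causes, computed on start-of-year populations via `p = 1 - exp(-rate)`),
#' ageing (each cohort moves up one year; age 100 is an absorbing 100+
#' bucket), then births into the age-0 cohort and net migration at the
#' destination age. Newborns face age-0 mortality over their first full
#' cycle. Migration outflows are clipped so no cell goes negative (with a
#' warning). Fractional persons are allowed throughout: this is cohort
#' expectation arithmetic, not sampling.
#'
#' @param profile A `country_profile`.
#' @param horizon Projection horizon in years (>= 1), default 100.
#' @return A list of class `population_trajectory`: `counts` (array
#'   `(horizon+1) x 101 x 2`, year 0 = base year), `deaths_other` and
#'   `deaths_suicide` (arrays `horizon x 101 x 2`, indexed by start-of-year
#'   age), `births` (length `horizon`), `migrants` (net migration actually
#'   applied, `horizon x 101 x 2`, indexed by destination age).
#' @export
project_population <- function(profile, horizon = 100) {
  if (!is.numeric(horizon) || horizon < 1) stop("'horizon' must be >= 1")
  validate_country_profile(profile)
  horizon <- as.integer(horizon)
  na <- length(AGES); ns <- length(SEXES)
  dn <- list(year = 0:horizon, age = AGES, sex = SEXES)
  dn1 <- list(year = seq_len(horizon), age = AGES, sex = SEXES)
  counts <- array(0, c(horizon + 1, na, ns), dimnames = dn)
  deaths_o <- array(0, c(horizon, na, ns), dimnames = dn1)
  deaths_s <- array(0, c(horizon, na, ns), dimnames = dn1)
  migrants <- array(0, c(horizon, na, ns), dimnames = dn1)
  births <- numeric(horizon)

  sui_r <- profile$suicide_mortality
  oth_r <- pmax(profile$all_cause_mortality - sui_r, 0)
  p_sui <- rate_to_prob(sui_r)
  p_oth <- rate_to_prob(oth_r)
  tot <- p_sui + p_oth
  over <- tot > 1
  if (any(over)) {  # competing-risk normalization; cannot occur for sane rates
    p_sui[over] <- p_sui[over] / tot[over]
    p_oth[over] <- p_oth[over] / tot[over]
  }

  pop <- profile$population
  counts[1, , ] <- pop
  clipped <- FALSE
  for (t in seq_len(horizon)) {
    ds <- pop * p_sui
    do <- pop * p_oth
    deaths_s[t, , ] <- ds
    deaths_o[t, , ] <- do
    pop <- shift_age(pop - ds - do)
    pop[1, ] <- profile$births_per_year * c(0.49, 0.51)  # female, male split
    births[t] <- profile$births_per_year
    mig <- profile$net_migration
    mig_applied <- pmax(mig, -pop)  # cannot remove more than present
    if (any(mig_applied > mig + 1e-12)) clipped <- TRUE
    pop <- pop + mig_applied
    migrants[t, , ] <- mig_applied
    counts[t + 1, , ] <- pop
  }
  if (clipped)
    warning("net migration outflow clipped at available population")
  structure(list(counts = counts, deaths_other = deaths_o,
                 deaths_suicide = deaths_s, births = births,
                 migrants = migrants, horizon = horizon),
            class = "population_trajectory")
}

#' Export a population trajectory to long format
#'
#' @param traj A `population_trajectory`.
#' @return A data.frame with columns year, age, sex, state
#'   (alive/deaths_other/deaths_suicide/migrants), count.
#' @export
trajectory_long <- function(traj) {
  flat <- function(a, state) {
    d <- as.data.frame.table(a, responseName = "count")
    names(d)[1:3] <- c("year", "age", "sex")
    d$year <- as.integer(as.character(d$year))
    d$age <- as.integer(as.character(d$age))
    d$state <- state
    d[, c("year", "age", "sex", "state", "count")]
  }
  rbind(flat(traj$counts, "alive"),
        flat(traj$deaths_other, "deaths_other"),
        flat(traj$deaths_suicide, "deaths_suicide"),
        flat(traj$migrants, "migrants"))
}
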