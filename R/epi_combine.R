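# Dependent-comorbidity combination of depression and anxiety into a single
# "depression and/or anxiety" condition. Comorbid prevalence is modelled as
# k * p_dep * p_anx with k >= 1 encoding positive dependence (k = 1 recovers
# independence); disability weights combine multiplicatively for the comorbid
# group, GBD style.

#' Combine depression and anxiety prevalence with dependent comorbidity
#'
#' Combined prevalence is `p_dep + p_anx - k * p_dep * p_anx`: the union of
#' the two conditions when their joint (comorbid) prevalence is
#' `k * p_dep * p_anx`. `k = 1` is independence; `k > 1` means the conditions
#' co-occur more often than chance, shrinking the union.
#'
#' @param p_dep,p_anx Marginal prevalences, proportions in `[0, 1)`. Vectors
#'   and matrices are combined elementwise.
#' @param k Dependence factor, `>= 1`.
#' @return Combined prevalence.
#' @examples
#' combine_prevalence(0.05, 0.05, k = 1)  # 0.0975
#' combine_prevalence(0.05, 0.05, k = 2)  # 0.095
#' @export
combine_prevalence <- function(p_dep, p_anx, k = 2) {
  if (any(p_dep < 0 | p_dep >= 1) || any(p_anx < 0 | p_anx >= 1))
    stop("prevalences must lie in [0, 1)")
  if (any(k < 1)) stop("'k' must be >= 1")
  comorbid <- k * p_dep * p_anx
  if (any(comorbid > pmin(p_dep, p_anx) + 1e-12))
    stop("comorbid prevalence k*p_dep*p_anx exceeds a marginal prevalence")
  p_dep + p_anx - comorbid
}

#' Combine disability weights with dependent comorbidity
#'
#' Prevalence-weighted mean disability weight over the three mutually
#' exclusive groups (depression only, anxiety only, comorbid), where the
#' comorbid group's weight combines multiplicatively:
#' `1 - (1 - dw_dep) * (1 - dw_anx)`.
#'
#' @param dw_dep,dw_anx Condition-specific disability weights in `[0, 1]`.
#' @param p_dep,p_anx Marginal prevalences in `[0, 1)`.
#' @param k Dependence factor, `>= 1`.
#' @return Combined disability weight for the merged condition.
#' @export
combine_disability_weight <- function(dw_dep, dw_anx, p_dep, p_anx, k = 2) {
  if (any(dw_dep < 0 | dw_dep > 1) || any(dw_anx < 0 | dw_anx > 1))
    stop("disability weights must lie in [0, 1]")
  comorbid <- k * p_dep * p_anx
  p_comb <- combine_prevalence(p_dep, p_anx, k)
  if (any(p_comb <= 0)) stop("combined prevalence is zero; weight undefined")
  dw_com <- 1 - (1 - dw_dep) * (1 - dw_anx)
  ((p_dep - comorbid) * dw_dep + (p_anx - comorbid) * dw_anx +
      comorbid * dw_com) / p_comb
}

#' Combine depression and anxiety epidemiology into one condition
#'
#' Applies the dependent-comorbidity rules elementwise over the (age, sex)
#' grids of a country profile: prevalence via [combine_prevalence()];
#' incidence as the sum of the two incidence rates minus the comorbid
#' double-count `k * i_dep * i_anx` (the same dependence structure applied to
#' incident risk); remission as the prevalence-weighted mean of the two
#' remission rates; the disability weight via [combine_disability_weight()]
#' evaluated at the population-mean prevalences.
#'
#' @param profile A `country_profile` (see [generate_country()]).
#' @param k Dependence factor, `>= 1`; defaults to the profile's own
#'   `comorbidity_k`.
#' @return A list of class `combined_epi` with elements `prevalence`,
#'   `incidence`, `remission` ((age x sex) matrices), scalar
#'   `disability_weight`, and `dependence_factor`.
#' @export
combine_epi <- function(profile, k = profile$comorbidity_k) {
  d <- profile$dep_epi
  a <- profile$anx_epi
  prev <- combine_prevalence(d$prevalence, a$prevalence, k)
  inc <- d$incidence + a$incidence - k * d$incidence * a$incidence
  pd <- d$prevalence
  pa <- a$prevalence
  w <- pd + pa
  rem <- ifelse(w > 0, (pd * d$remission + pa * a$remission) / pmax(w, 1e-300),
                (d$remission + a$remission) / 2)
  # scalar DW at population-weighted mean prevalence, so one weight serves
  # the whole merged state; with no prevalent cases the future case mix
  # follows incidence, so fall back to incidence weighting
  tot_pop <- sum(profile$population)
  wt <- if (tot_pop > 0) profile$population / tot_pop
        else matrix(1 / length(profile$population),
                    nrow(profile$population), ncol(profile$population))
  mpd <- sum(pd * wt); mpa <- sum(pa * wt)
  if (mpd + mpa > 0) {
    dw <- combine_disability_weight(profile$dw_dep, profile$dw_anx,
                                    mpd, mpa, k)
  } else {
    wi <- sum(d$incidence * wt); wa <- sum(a$incidence * wt)
    dw <- if (wi + wa > 0) (wi * profile$dw_dep + wa * profile$dw_anx) /
            (wi + wa)
          else (profile$dw_dep + profile$dw_anx) / 2
  }
  structure(list(prevalence = prev, incidence = inc, remission = rem,
                 disability_weight = dw, dependence_factor = k),
            class = "combined_epi")
}
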