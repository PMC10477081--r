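# Effect-size derivation: pooled SMDs from the meta-analyses are converted to
# odds ratios with Chinn's constant, then to relative risks with the
# comparator-risk identity; suicide-attempt effects map one-to-one onto
# suicide mortality under a constant case-fatality proportion; a conservative
# adoption rule replaces a pooled point estimate by the CI bound closer to
# the null.

CHINN <- pi / sqrt(3)

#' Convert a standardized mean difference to an odds ratio
#'
#' Chinn's method: `ln OR = SMD * pi / sqrt(3)`, i.e. an SMD on a continuous
#' symptom scale is rescaled to the log-odds scale assuming an underlying
#' logistic distribution.
#'
#' @param smd Standardized mean difference (negative = protective).
#' @return Odds ratio.
#' @examples
#' smd_to_or(-0.10)  # ~0.834
#' @export
smd_to_or <- function(smd) {
  stopifnot(is.numeric(smd), all(is.finite(smd)))
  exp(smd * CHINN)
}

#' Convert an odds ratio to a relative risk
#'
#' Uses the handbook identity `RR = OR / (1 - ACR * (1 - OR))` where `ACR` is
#' the assumed comparator (control-group) risk of the event. As `ACR -> 0`
#' the RR approaches the OR.
#'
#' @param or Odds ratio (> 0).
#' @param acr Assumed comparator risk, a proportion in (0, 1).
#' @return Relative risk.
#' @examples
#' or_to_rr(smd_to_or(-0.10), acr = 0.05)  # ~0.84
#' @export
or_to_rr <- function(or, acr) {
  stopifnot(all(or > 0))
  if (any(acr <= 0 | acr >= 1)) stop("'acr' must lie strictly in (0, 1)")
  or / (1 - acr * (1 - or))
}

#' Adopt a conservative point estimate from a confidence interval
#'
#' For protective effects (RR < 1) the upper 95% CI bound is the bound closer
#' to no effect; adopting it as the point estimate deliberately understates
#' the intervention benefit.
#'
#' @param point Pooled point estimate (relative risk).
#' @param ci Length-2 numeric `c(lower, upper)` bracketing `point`.
#' @return The upper CI bound.
#' @examples
#' adopt_conservative_rr(0.65, c(0.51, 0.83))  # 0.83
#' @export
adopt_conservative_rr <- function(point, ci) {
  if (length(ci) != 2L || ci[1] > ci[2]) stop("'ci' must be c(lower, upper)")
  if (point < ci[1] || point > ci[2]) stop("'point' must lie inside 'ci'")
  ci[2]
}

#' Map a suicide-attempt relative risk onto suicide mortality
#'
#' If the case-fatality proportion of suicide attempts is the same with and
#' without the intervention, deaths scale exactly as attempts do:
#' `deaths = attempts * CFR`, so `deaths_1/deaths_0 = attempts_1/attempts_0`
#' for any CFR in (0, 1]. The mapping is therefore the identity.
#'
#' @param rr_attempts Relative risk for suicide attempts (> 0).
#' @return The same value, now interpreted as the suicide-mortality RR.
#' @export
attempts_rr_to_mortality_rr <- function(rr_attempts) {
  stopifnot(all(rr_attempts > 0))
  rr_attempts
}

#' Population-effective relative risk under partial coverage
#'
#' A fraction `coverage` of the target group experiences risk `rr` and the
#' remainder risk 1, so the group-level risk ratio is the mixture
#' `1 - coverage * (1 - rr)`.
#'
#' @param rr Individual-level relative risk (> 0).
#' @param coverage Proportion of the group covered, in `[0, 1]`.
#' @return Group-level relative risk, in `[min(rr, 1), max(rr, 1)]`.
#' @export
effective_rr <- function(rr, coverage) {
  stopifnot(all(rr > 0))
  if (any(coverage < 0 | coverage > 1)) stop("'coverage' must lie in [0, 1]")
  1 - coverage * (1 - rr)
}

#' Default intervention effect specification
#'
#' Bundles the pooled effect sizes and derivation inputs used throughout:
#' SMDs for depression/anxiety symptoms under the universal and indicated
#' programs with their 95% CIs, the pooled and conservatively adopted
#' suicide-attempt RRs, the assumed comparator risks used in the OR-to-RR
#' identity, the 1-year effect duration, and the printed 95% CIs of the
#' converted RRs (used to parameterize Monte Carlo distributions).
#'
#' @param acr_universal,acr_indicated Assumed comparator risks. The indicated
#'   value is roughly double the universal one, reflecting the elevated
#'   baseline risk of the subthreshold target group.
#' @return A list of class `effect_spec`.
#' @export
default_effect_spec <- function(acr_universal = 0.05, acr_indicated = 0.10) {
  smd_u <- list(point = -0.10, ci = c(-0.17, -0.04))
  smd_i <- list(point = -0.19, ci = c(-0.33, -0.05))
  rr_su_pooled <- list(point = 0.65, ci = c(0.51, 0.83))
  rr_su_adopt <- attempts_rr_to_mortality_rr(
    adopt_conservative_rr(rr_su_pooled$point, rr_su_pooled$ci))
  structure(list(
    smd_universal = smd_u,
    smd_indicated = smd_i,
    acr_universal = acr_universal,
    acr_indicated = acr_indicated,
    rr_dep_universal = list(
      point = round(or_to_rr(smd_to_or(smd_u$point), acr_universal), 2),
      ci = c(0.75, 0.94)),
    rr_dep_indicated = list(
      point = round(or_to_rr(smd_to_or(smd_i$point), acr_indicated), 2),
      ci = c(0.57, 0.93)),
    rr_suicide_pooled = rr_su_pooled,
    rr_suicide_adopted = list(point = rr_su_adopt, ci = c(0.70, 0.99)),
    effect_duration = 1,
    repeat_exposure_max_age = 17
  ), class = "effect_spec")
}
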