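# Uncertainty and sensitivity machinery: parameter distributions (lognormal
# for relative risks matched to printed 95% CIs, beta for proportions, gamma
# for costs and rate multipliers), Monte Carlo uncertainty intervals
# (2.5th/97.5th percentiles over joint draws), one-at-a-time +/-10%
# deterministic sweeps with tornado ranking, Spearman rank-correlation
# probabilistic sensitivity analysis, and the effect-size threshold
# analysis (scaling both intervention effects toward the null).

#' Define a parameter uncertainty distribution
#'
#' @param name Parameter label.
#' @param kind One of `"lognormal_rr"` (hyperparameters matched so the 95%
#'   quantiles hit a supplied CI), `"beta_proportion"`, `"gamma_cost"`, or
#'   `"fixed"`.
#' @param mean Point estimate / distribution mean.
#' @param ci Length-2 95% CI (required for `lognormal_rr`).
#' @param cv Coefficient of variation for beta/gamma kinds (default 0.2).
#' @param lower,upper Hard domain bounds; samples and perturbed values are
#'   clipped here.
#' @return A list of class `param_distribution`.
#' @export
param_distribution <- function(name, kind = c("lognormal_rr",
                                              "beta_proportion",
                                              "gamma_cost", "fixed"),
                               mean, ci = NULL, cv = 0.2,
                               lower = -Inf, upper = Inf) {
  kind <- match.arg(kind)
  if (kind == "lognormal_rr") {
    if (is.null(ci) || length(ci) != 2 || any(ci <= 0))
      stop("lognormal_rr requires a positive 95% CI")
    if (mean <= 0) stop("RR mean must be > 0")
  }
  if (kind == "beta_proportion" && (mean <= 0 || mean >= 1))
    stop("beta_proportion mean must lie in (0, 1)")
  if (kind == "gamma_cost" && mean < 0)
    stop("gamma_cost mean must be >= 0")
  structure(list(name = name, kind = kind, mean = mean, ci = ci, cv = cv,
                 lower = lower, upper = upper),
            class = "param_distribution")
}

#' Sample from a parameter distribution
#'
#' @param dist A `param_distribution`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`, clipped to the domain bounds.
#' @export
sample_distribution <- function(dist, n) {
  x <- switch(dist$kind,
    fixed = rep(dist$mean, n),
    lognormal_rr = {
      sdlog <- (log(dist$ci[2]) - log(dist$ci[1])) / (2 * stats::qnorm(0.975))
      stats::rlnorm(n, log(dist$mean), sdlog)
    },
    beta_proportion = {
      m <- dist$mean
      v <- (dist$cv * m)^2
      v <- min(v, 0.9 * m * (1 - m))
      conc <- m * (1 - m) / v - 1
      stats::rbeta(n, m * conc, (1 - m) * conc)
    },
    gamma_cost = {
      shape <- 1 / dist$cv^2
      stats::rgamma(n, shape = shape, rate = shape / dist$mean)
    })
  pmin(pmax(x, dist$lower), dist$upper)
}

#' Default parameter registry for the portfolio analysis
#'
#' Registers every scalar model input swept by the sensitivity analyses:
#' the three intervention relative risks (lognormal, 95% quantiles matched
#' to the printed CIs), the disability weight, the subthreshold prevalence
#' and incidence multiplier, the comorbidity dependence factor, coverage and
#' enrolment, portfolio-wide multipliers on the epidemiological rate
#' surfaces, and the unit-cost inputs. Multipliers are centred at 1.
#'
#' @param effects An `effect_spec` providing the RR means and CIs.
#' @return Named list of `param_distribution`s.
#' @export
default_parameters <- function(effects = default_effect_spec()) {
  p <- list(
    param_distribution("rr_dep_universal", "lognormal_rr",
                       effects$rr_dep_universal$point,
                       ci = effects$rr_dep_universal$ci, lower = 1e-6),
    param_distribution("rr_dep_indicated", "lognormal_rr",
                       effects$rr_dep_indicated$point,
                       ci = effects$rr_dep_indicated$ci, lower = 1e-6),
    param_distribution("rr_suicide", "lognormal_rr",
                       effects$rr_suicide_adopted$point,
                       ci = effects$rr_suicide_adopted$ci, lower = 1e-6),
    param_distribution("disability_weight", "beta_proportion", 0.30,
                       cv = 0.15, lower = 0.01, upper = 0.99),
    param_distribution("subthreshold_fraction", "beta_proportion", 0.05,
                       cv = 0.20, lower = 0.005, upper = 0.5),
    param_distribution("subthreshold_incidence_multiplier", "gamma_cost",
                       2.0, cv = 0.15, lower = 1, upper = 5),
    param_distribution("comorbidity_k", "gamma_cost", 2.0, cv = 0.10,
                       lower = 1, upper = 3),
    param_distribution("coverage_target", "beta_proportion", 0.95,
                       cv = 0.02, lower = 0, upper = 1),
    param_distribution("enrolment_multiplier", "gamma_cost", 1, cv = 0.05,
                       lower = 0, upper = 1.5),
    param_distribution("incidence_dep_multiplier", "gamma_cost", 1,
                       cv = 0.20, lower = 0),
    param_distribution("incidence_anx_multiplier", "gamma_cost", 1,
                       cv = 0.20, lower = 0),
    param_distribution("remission_multiplier", "gamma_cost", 1, cv = 0.20,
                       lower = 0.05),
    param_distribution("suicide_rate_multiplier", "gamma_cost", 1,
                       cv = 0.20, lower = 0),
    param_distribution("mortality_multiplier", "gamma_cost", 1, cv = 0.10,
                       lower = 0.1),
    param_distribution("life_expectancy_multiplier", "gamma_cost", 1,
                       cv = 0.03, lower = 0.5, upper = 1.3),
    param_distribution("facilitator_wage_multiplier", "gamma_cost", 1,
                       cv = 0.20, lower = 0),
    param_distribution("trainer_wage_multiplier", "gamma_cost", 1,
                       cv = 0.20, lower = 0),
    param_distribution("materials_multiplier", "gamma_cost", 1, cv = 0.20,
                       lower = 0),
    param_distribution("screening_minutes_multiplier", "gamma_cost", 1,
                       cv = 0.20, lower = 0),
    param_distribution("overhead_multiplier", "gamma_cost", 1, cv = 0.20,
                       lower = 0),
    param_distribution("session_time_multiplier", "gamma_cost", 1,
                       cv = 0.20, lower = 0)
  )
  stats::setNames(p, vapply(p, `[[`, "", "name"))
}

# Apply a named vector of parameter values to model inputs, returning
# modified copies (profiles are never mutated in place).
apply_parameter_values <- function(profiles, effects, scenario_args, values) {
  v <- function(nm, default = NULL)
    if (nm %in% names(values)) values[[nm]] else default
  if (!is.null(v("rr_dep_universal")))
    effects$rr_dep_universal$point <- v("rr_dep_universal")
  if (!is.null(v("rr_dep_indicated")))
    effects$rr_dep_indicated$point <- v("rr_dep_indicated")
  if (!is.null(v("rr_suicide")))
    effects$rr_suicide_adopted$point <- v("rr_suicide")
  for (nm in c("subthreshold_fraction", "subthreshold_incidence_multiplier",
               "coverage_target"))
    if (!is.null(v(nm))) scenario_args[[nm]] <- v(nm)
  profiles <- lapply(profiles, function(p) {
    if (!is.null(v("disability_weight"))) {
      ratio <- p$dw_anx / p$dw_dep
      p$dw_dep <- v("disability_weight")
      p$dw_anx <- min(v("disability_weight") * ratio, 1)
    }
    if (!is.null(v("comorbidity_k"))) p$comorbidity_k <- v("comorbidity_k")
    if (!is.null(v("enrolment_multiplier")))
      p$enrolment_12_17 <- min(p$enrolment_12_17 * v("enrolment_multiplier"), 1)
    if (!is.null(v("incidence_dep_multiplier")))
      p$dep_epi$incidence <- p$dep_epi$incidence * v("incidence_dep_multiplier")
    if (!is.null(v("incidence_anx_multiplier")))
      p$anx_epi$incidence <- p$anx_epi$incidence * v("incidence_anx_multiplier")
    if (!is.null(v("remission_multiplier"))) {
      p$dep_epi$remission <- p$dep_epi$remission * v("remission_multiplier")
      p$anx_epi$remission <- p$anx_epi$remission * v("remission_multiplier")
    }
    if (!is.null(v("mortality_multiplier")))
      p$all_cause_mortality <- p$all_cause_mortality * v("mortality_multiplier")
    if (!is.null(v("suicide_rate_multiplier")))
      p$suicide_mortality <- pmin(p$suicide_mortality *
                                    v("suicide_rate_multiplier"),
                                  0.95 * p$all_cause_mortality)
    if (!is.null(v("life_expectancy_multiplier")))
      p$life_expectancy <- p$life_expectancy * v("life_expectancy_multiplier")
    uc <- p$unit_costs
    if (!is.null(v("facilitator_wage_multiplier")))
      uc$facilitator_wage <- uc$facilitator_wage *
        v("facilitator_wage_multiplier")
    if (!is.null(v("trainer_wage_multiplier")))
      uc$trainer_wage <- uc$trainer_wage * v("trainer_wage_multiplier")
    if (!is.null(v("materials_multiplier")))
      uc$materials_per_student <- uc$materials_per_student *
        v("materials_multiplier")
    if (!is.null(v("screening_minutes_multiplier")))
      uc$screening_minutes_per_student <- uc$screening_minutes_per_student *
        v("screening_minutes_multiplier")
    if (!is.null(v("session_time_multiplier")))
      uc$session_minutes <- uc$session_minutes * v("session_time_multiplier")
    if (!is.null(v("overhead_multiplier")))
      uc$program_overhead_items <- lapply(uc$program_overhead_items,
                                          `*`, v("overhead_multiplier"))
    p$unit_costs <- uc
    p
  })
  list(profiles = profiles, effects = effects, scenario_args = scenario_args)
}

scale_rr_toward_null <- function(rr, reduction) 1 - (1 - rr) * (1 - reduction)

#' Build a pipeline model closure over a country portfolio
#'
#' Returns `function(values = NULL, rr_reduction = 0)` that applies a named
#' vector of parameter values (see [default_parameters()]) and an optional
#' proportional reduction of all intervention effect sizes
#' (`rr(f) = 1 - (1 - rr) * (1 - f)`), runs the full portfolio, and returns
#' a named numeric vector of outputs: `acer_<program>_<group>`,
#' `hlyg_pm_<program>_<group>` (HLYGs per million per year),
#' `cost_pc_<program>_<group>` (annualized I$ per capita) and
#' `yld_share_<program>_all`, for groups llmic/umhic/all.
#'
#' @param profiles List of `country_profile`s.
#' @param horizon Model horizon in years.
#' @param programs Programs to evaluate.
#' @param scenario_args Baseline extra arguments for [scenario_spec()].
#' @param effects Baseline `effect_spec`.
#' @param discount_cost,discount_health Discount rates.
#' @return A closure; its `summary` attribute-carrying full output is
#'   available via `attr(result, "summary")`.
#' @export
pipeline_model <- function(profiles, horizon = 100,
                           programs = c("universal", "indicated"),
                           scenario_args = list(),
                           effects = default_effect_spec(),
                           discount_cost = 0.03, discount_health = 0) {
  force(profiles); force(horizon); force(programs); force(scenario_args)
  force(effects); force(discount_cost); force(discount_health)
  function(values = NULL, rr_reduction = 0) {
    inp <- apply_parameter_values(profiles, effects, scenario_args,
                                  values %||% numeric(0))
    eff <- inp$effects
    if (rr_reduction > 0) {
      eff$rr_dep_universal$point <-
        scale_rr_toward_null(eff$rr_dep_universal$point, rr_reduction)
      eff$rr_dep_indicated$point <-
        scale_rr_toward_null(eff$rr_dep_indicated$point, rr_reduction)
      eff$rr_suicide_adopted$point <-
        scale_rr_toward_null(eff$rr_suicide_adopted$point, rr_reduction)
    }
    res <- run_portfolio(inp$profiles, programs = programs, horizon = horizon,
                         effects = eff, scenario_args = inp$scenario_args,
                         discount_cost = discount_cost,
                         discount_health = discount_health)
    summ <- summarize_portfolio(res)
    out <- numeric(0)
    for (i in seq_len(nrow(summ))) {
      key <- paste0(summ$program[i], "_", tolower(summ$country[i]))
      out[paste0("acer_", key)] <- summ$acer[i]
      out[paste0("hlyg_pm_", key)] <- summ$hlyg_per_million_per_year[i]
      out[paste0("cost_pc_", key)] <- summ$cost_per_capita_per_year[i]
      if (summ$country[i] == "all")
        out[paste0("yld_share_", key)] <- summ$yld_share[i]
    }
    attr(out, "summary") <- summ
    attr(out, "results") <- res
    out
  }
}

#' Monte Carlo uncertainty analysis
#'
#' Draws all parameters jointly from their distributions, evaluates the
#' model per draw, and reports the 2.5th/97.5th percentile uncertainty
#' interval per output alongside the all-parameters-at-means point
#' estimate. Seeded and reproducible.
#'
#' @param model A closure taking a named vector of parameter values (e.g.
#'   from [pipeline_model()], or any `function(values)` returning a named
#'   numeric vector).
#' @param dists Named list of `param_distribution`s.
#' @param n Number of iterations (default 1000).
#' @param seed Integer seed.
#' @return A list of class `monte_carlo_result`: `point`, `ui` (output x
#'   c(lo, hi) matrix), `outputs` (n x output matrix), `draws` (n x
#'   parameter matrix), `n`, `seed`.
#' @export
monte_carlo <- function(model, dists, n = 1000, seed = 1) {
  if (n < 2) stop("'n' must be >= 2")
  draws <- withr::with_seed(as.integer(seed), {
    m <- vapply(dists, sample_distribution, numeric(n), n = n)
    if (n == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(dists)))
    m
  })
  colnames(draws) <- names(dists)
  rows <- lapply(seq_len(n), function(i) model(draws[i, ]))
  outputs <- do.call(rbind, lapply(rows, function(r) {
    attributes(r) <- attributes(r)["names"]; r
  }))
  means <- vapply(dists, `[[`, numeric(1), "mean")
  point <- model(means)
  ui <- t(apply(outputs, 2, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE, names = FALSE))
  colnames(ui) <- c("lo", "hi")
  structure(list(point = point, ui = ui, outputs = outputs, draws = draws,
                 n = n, seed = seed),
            class = "monte_carlo_result")
}

#' One-at-a-time deterministic sensitivity analysis
#'
#' Evaluates the model with each parameter at `mean * (1 - delta)` and
#' `mean * (1 + delta)` (default +/-10%), all others held at their means;
#' perturbed values falling outside a parameter's domain bounds are clipped
#' with a warning.
#'
#' @param model Closure as in [monte_carlo()].
#' @param dists Named list of `param_distribution`s.
#' @param delta Proportional perturbation (default 0.10).
#' @return A data.frame of class `dsa_report`: parameter, output, low, high,
#'   range; the all-at-means baseline is in `attr(, "baseline")`.
#' @export
dsa_univariate <- function(model, dists, delta = 0.10) {
  means <- vapply(dists, `[[`, numeric(1), "mean")
  baseline <- model(means)
  swept <- names(dists)[vapply(dists, `[[`, "", "kind") != "fixed"]
  rows <- lapply(swept, function(nm) {
    d <- dists[[nm]]
    lo <- d$mean * (1 - delta)
    hi <- d$mean * (1 + delta)
    clip <- function(x) {
      cx <- min(max(x, d$lower), d$upper)
      if (cx != x)
        warning(sprintf("'%s' perturbation %.4g clipped to domain bound %.4g",
                        nm, x, cx))
      cx
    }
    vlo <- means; vlo[nm] <- clip(lo)
    vhi <- means; vhi[nm] <- clip(hi)
    out_lo <- model(vlo)
    out_hi <- model(vhi)
    data.frame(parameter = nm, output = names(baseline),
               low = as.numeric(out_lo[names(baseline)]),
               high = as.numeric(out_hi[names(baseline)]),
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rep$range <- abs(rep$high - rep$low)
  attr(rep, "baseline") <- baseline
  class(rep) <- c("dsa_report", "data.frame")
  rep
}

#' Tornado ranking of a DSA report for one output
#'
#' @param report A `dsa_report` from [dsa_univariate()].
#' @param output Output name (e.g. `"acer_universal_all"`).
#' @return The report rows for that output sorted by decreasing range, with
#'   a `rank` column.
#' @export
tornado_ranking <- function(report, output) {
  sub <- report[report$output == output, ]
  if (nrow(sub) == 0) stop(sprintf("unknown output '%s'", output))
  sub <- sub[order(-sub$range), ]
  sub$rank <- seq_len(nrow(sub))
  rownames(sub) <- NULL
  sub
}

#' Spearman rank correlation between parameter draws and model outputs
#'
#' The multivariate probabilistic sensitivity analysis: for each parameter,
#' the rank correlation of its joint Monte Carlo draws with the output,
#' accounting implicitly for simultaneous variation of all other
#' parameters. Constant parameter columns yield `NA` (undefined).
#'
#' @param draws n x parameter matrix (e.g. `mc$draws`).
#' @param outputs Length-n vector, or n x output matrix (e.g.
#'   `mc$outputs[, "acer_universal_all"]`).
#' @return A data.frame: parameter, output, r_s.
#' @export
psa_spearman <- function(draws, outputs) {
  draws <- as.matrix(draws)
  outputs <- as.matrix(outputs)
  if (nrow(draws) != nrow(outputs) || nrow(draws) < 3)
    stop("draws and outputs must share >= 3 rows")
  if (is.null(colnames(outputs)))
    colnames(outputs) <- paste0("output", seq_len(ncol(outputs)))
  grid <- expand.grid(parameter = colnames(draws),
                      output = colnames(outputs),
                      stringsAsFactors = FALSE)
  grid$r_s <- mapply(function(p, o) {
    x <- draws[, p]; y <- outputs[, o]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(NA_real_)
    stats::cor(x[ok], y[ok], method = "spearman")
  }, grid$parameter, grid$output)
  grid
}

#' Effect-size threshold analysis
#'
#' Re-evaluates the model while proportionally reducing every intervention
#' effect size toward the null (`rr(f) = 1 - (1 - rr) * (1 - f)`,
#' `f = 0..1`; `f = 1` means RR = 1 and the ACER is undefined). Reports the
#' ACER curve per output and, for each cost-effectiveness ceiling, the
#' largest reduction at which the ACER stays below it (linear interpolation
#' between grid points).
#'
#' @param model Closure from [pipeline_model()] (must accept
#'   `rr_reduction`).
#' @param reductions Grid of reductions in `[0, 1]` (default 0 to 1 by
#'   0.01).
#' @param ceilings Named vector of I$/HLYG ceilings keyed by program
#'   substring (default `c(universal = 5000, indicated = 50000)`).
#' @return A list of class `threshold_report`: `curve` (data.frame
#'   reduction x output x acer) and `crossings` (output, ceiling,
#'   max_reduction).
#' @export
threshold_analysis <- function(model, reductions = seq(0, 1, by = 0.01),
                               ceilings = c(universal = 5000,
                                            indicated = 50000)) {
  evals <- lapply(reductions, function(f) model(rr_reduction = f))
  outs <- names(evals[[1]])
  acer_outs <- grep("^acer_", outs, value = TRUE)
  curve <- do.call(rbind, lapply(seq_along(reductions), function(i)
    data.frame(reduction = reductions[i], output = acer_outs,
               acer = as.numeric(evals[[i]][acer_outs]),
               stringsAsFactors = FALSE)))
  crossings <- do.call(rbind, lapply(acer_outs, function(o) {
    prog <- names(ceilings)[vapply(names(ceilings), grepl, TRUE, x = o)]
    if (length(prog) == 0) return(NULL)
    ceil <- ceilings[[prog[1]]]
    v <- curve$acer[curve$output == o]
    below <- which(!is.na(v) & v <= ceil)
    if (length(below) == 0) {
      mr <- NA_real_
    } else {
      i <- max(below)
      mr <- reductions[i]
      if (i < length(reductions) && !is.na(v[i + 1]) && v[i + 1] > ceil)
        mr <- reductions[i] + (ceil - v[i]) / (v[i + 1] - v[i]) *
          (reductions[i + 1] - reductions[i])
    }
    data.frame(output = o, ceiling = ceil, max_reduction = mr,
               stringsAsFactors = FALSE)
  }))
  structure(list(curve = curve, crossings = crossings),
            class = "threshold_report")
}
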