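---
title: "Modelling the cost-effectiveness of school-based socio-emotional learning programs"
author: "selcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-effectiveness of school-based SEL programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selcea)
```

## The question the model answers

School-based socio-emotional learning (SEL) programs teach adolescents
psychological skills that reduce the incidence of depression/anxiety and
suicidal behaviour. Two delivery designs compete for the same budget line:
a *universal* program delivered to all secondary-school students aged
12–17, and an *indicated* program that first screens all students and then
delivers only to the roughly 5% with subthreshold depression/anxiety —
clinically relevant symptoms short of diagnostic criteria. `selcea`
implements a population-level Markov cohort model, in the WHO-CHOICE
generalized cost-effectiveness tradition, that asks what each design costs
to scale up nationally and how much population health it buys, expressed
as an average cost-effectiveness ratio (ACER, 2017 international dollars
per healthy life year gained) against a null scenario with the
intervention's impacts removed.

Because the real national input databases (demography, disease
epidemiology, school enrolment, unit costs) are external assets, the
package ships a seeded synthetic-country generator that emulates their
statistical structure. Every analysis in this package therefore runs end
to end from code, and all reported numbers are statements about the
synthetic portfolio — qualitative orderings and mechanisms, not any real
country's results.

## Model structure

### Demographic engine

Each country is projected forward by deterministic cohort-component
arithmetic over single-year age (0–100) by sex cohorts: deaths (suicide
and other causes, converted from rates via $p = 1 - e^{-r}$ per annual
cycle), ageing, births into the age-0 cohort, and net migration.
Fractional persons are allowed — this is expectation arithmetic, not
microsimulation. Two conventions are fixed and tested rather than left
implicit:

* **Age 100 is an absorbing 100+ bucket.** An open-ended terminal age
  keeps the accounting ledger exact (the alternative — cohorts silently
  exiting at the top of the grid — breaks conservation).
* **Within-year order** is deaths → ageing → births and migration, all
  computed on start-of-year populations. Newborns enter at the end of
  their birth year and face age-0 mortality over their first full cycle.

The per-cohort ledger identity (each year's cell equals last year's cell
minus deaths plus arrivals) holds to numerical precision and is asserted
to 1e-9 over a full century in the test suite.

### Health states and transitions

The Markov model tracks five states: *at-risk (general)*, *at-risk
(subthreshold)*, *depression/anxiety*, and two absorbing dead states
(suicide, other causes). Depression and anxiety are collapsed into a
single condition before simulation using a dependent-comorbidity
combination: comorbid prevalence is parameterized as
$k\,p_{dep}\,p_{anx}$ with $k \ge 1$ ($k = 1$ recovers independence;
default $k = 2$), so combined prevalence is
$p_{dep} + p_{anx} - k\,p_{dep}\,p_{anx}$. Combined incidence uses the
same dependence structure; combined remission is the prevalence-weighted
mean; the combined disability weight is the prevalence-weighted mean over
the depression-only, anxiety-only and comorbid groups, the comorbid group
weighted multiplicatively as $1-(1-dw_{dep})(1-dw_{anx})$. The $k$
parameterization is the simplest dependence structure with a testable
independence limit; it is a stand-in for fuller comorbidity methods and
is exposed as a configurable (and swept) parameter.

Each cycle, flows are computed simultaneously on start-of-cycle
occupancy: at-risk → depression/anxiety via combined incidence (the
subthreshold compartment at a multiplied rate, default 2×),
depression/anxiety → at-risk via remission (returners split between the
two at-risk compartments in proportion to their occupancy), and both
alive-state groups exposed to suicide and other-cause mortality. The
suicide rate is identical in all alive states by default
(`dep_state_suicide_multiplier = 1`): no published relative suicide risk
for the depressed state is assumed, and the knob exists for sensitivity
work. If a cell's total exit probability would exceed 1 (possible only
under pathological rate inputs), competing risks are normalized
proportionally and a warning is raised.

The subthreshold compartment exists only at eligible ages: each cohort
entering age 12 moves 5% (configurable) of its at-risk members into the
subthreshold compartment, and the compartment merges back into the
general at-risk pool when the cohort turns 18. This is the minimal
structure that lets an indicated program target screened students while
keeping the two program arms on an identical state space (the null
scenario also carries the split, so traces are cell-comparable).

### Intervention effects

Pooled meta-analytic effect sizes enter as standardized mean differences
on symptom scales: −0.10 (95% CI −0.17 to −0.04) for universal and −0.19
(−0.33 to −0.05) for indicated programs at 1-year follow-up. They are
converted to odds ratios with Chinn's constant
($\ln OR = SMD \cdot \pi/\sqrt{3}$) and then to relative risks with the
handbook identity $RR = OR/(1 - ACR(1 - OR))$ at assumed comparator risks
of 0.05 (universal) and 0.10 (indicated) — the indicated comparator risk
being roughly double reflects the elevated baseline risk of the
subthreshold group, and this pair reproduces the published point
conversions RR 0.84 and RR 0.73 exactly at two decimals. Converting the
SMD CI endpoints through the same identities does not reproduce every
printed CI digit, so Monte Carlo distributions are parameterized from the
printed RR CIs directly (0.75–0.94 and 0.57–0.93), not from endpoint-wise
conversion.

For suicide, a pooled RR of 0.65 (0.51–0.83) for suicide *attempts* is
first made conservative by adopting the upper CI bound (0.83) as the
point estimate — the bound closer to no effect — and then applied
unchanged to suicide *mortality*: if the case-fatality proportion of
attempts is constant across arms, deaths scale exactly as attempts do
(deaths $=$ attempts $\times$ CFR in both arms, so the ratio is CFR-free;
the test suite verifies this identity numerically over a CFR grid).

Coverage converts individual-level RRs to population-level ones as the
mixture $1 - c(1 - RR)$, with $c$ = 95% target coverage × secondary-school
enrolment × the rollout ramp. The universal program covers both at-risk
compartments (and its suicide effect also reaches students already in the
depression/anxiety state); the indicated program covers the subthreshold
compartment only. Effects last one year and are renewed each year a
cohort remains in the eligible age band; after age 17 they attenuate
completely.

### Burden accounting

Health gains are healthy life years gained (HLYGs) versus the null run,
the sum of:

* **YLL**: suicide deaths averted per (year, age) × the smaller of
  remaining life expectancy ($LE - age$) and remaining model horizon,
  floored at zero.
* **YLD**: prevalent depression/anxiety case-years averted per year × the
  combined disability weight. "Cases occurring in a year" is read as
  point-prevalent occupancy of the depression/anxiety state at cycle
  start — YLD is a prevalence × disability-weight construct in standard
  burden accounting. An incident-only reading would scale YLD down
  roughly by the mean episode duration but not change any ordering; the
  prevalent-case reading is flagged as an interpretation choice.

Costs are discounted at 3%/year and health impacts at 0% by default
(end-of-year convention, model year 1 undiscounted); both rates are
arguments, and the sensitivity analysis re-runs the model at 3% and 6%
health discounting. Net averted quantities may turn negative in late
years (people the program keeps alive remain at risk of later death and
illness); streams are aggregated signed rather than floored, which is the
consistent ledger treatment.

### Costing

Costing follows a staged scale-up template: years 1–2 (planning, policy
development) carry only program-level management and advocacy overheads;
delivery-linked costs ramp linearly (1/3, 2/3, 1) over years 3–5 — the
Markov coverage uses the same ramp — and run at full scale from year 6.
Delivery cost per covered student-year is facilitator contact time
(10 sessions × 45 min ÷ groups of 25) at the facilitator wage plus
materials; training is amortized over 5-year facilitator cohorts (16 h of
trainer plus trainee time per facilitator, one facilitator per 4 groups);
the indicated program additionally screens *every* enrolled eligible
student (10 min of facilitator time each) while delivering only to the
subthreshold 5% — screening is cost-only and does not alter epidemiology.
These resource quantities are configurable placeholders fixed once; the
per-income-group unit costs (e.g. facilitator wages of I\$5.0/h in LLMIC
vs I\$5.5/h in UMHIC profiles, with higher overheads and materials in
UMHIC) are a documented *calibration* chosen so that annualized
per-capita cost lands in the I\$0.05–0.20 band that scaled school-based
programs are reported to occupy — they are not derived from any costing
database.

### CEA and aggregation

ACER = total discounted cost ÷ HLYGs versus null, flagged undefined (not
infinite) at zero HLYGs. Income-group results aggregate costs and effects
*before* dividing (ratio of sums, not mean of ratios), and per-million
standardizations divide by the mean projected population over the horizon
× horizon years — the averaging rule behind "per 1 million population per
year" is fixed here since units alone do not determine it.

## The synthetic portfolio

`generate_country()` draws, per seeded country: a population pyramid
(exponential age decline, steeper in LLMIC profiles), Siler-shaped
all-cause mortality, suicide mortality as a logistic ramp from age ~10 to
a sex-specific plateau (male > female), depression and anxiety incidence
as log-normal-shaped age curves peaking near ages 20 and 15 with
persistent adult baselines, flat remission rates (~0.30 and ~0.22/yr),
and prevalence at the implied steady state $inc/(inc+rem)$ with small
noise — the model therefore starts near epidemiological equilibrium,
which the generator asserts to within 20%. Enrolment is beta-distributed
around 0.62 (LLMIC) and 0.92 (UMHIC). Disability weights default to 0.30
(depression) and 0.20 (anxiety). The default portfolio is 10 LLMIC + 10
UMHIC countries.

What the generator does *not* emulate: cohort trends in any rate
(all rates are stationary), migration age-profiles beyond a single
working-age bump, conflict or epidemic mortality shocks, country-level
correlation between epidemiology and costs, and detection/treatment
cascades. Passing tests therefore demonstrate the internal consistency
and qualitative mechanics of the pipeline on data with the right *shape*,
not agreement with any country's measured burden; headline absolute
ACERs here are several-fold lower than published multi-country estimates,
which depend on the real inputs.

## Uncertainty machinery

Twenty-one portfolio-level scalar parameters are registered: the three
intervention RRs (lognormal, 95% quantiles matched to the printed CIs),
the disability weight (beta; one parameter scales both condition weights
since the model consumes a single combined weight), subthreshold
prevalence and incidence multiplier, the comorbidity factor, coverage and
enrolment, multipliers on every epidemiological rate surface, and the
unit-cost inputs (gamma, CV 20% unless tighter is warranted). A published
analysis of this kind sweeps country-specific cells too (hundreds of
parameters); here the registry deliberately sweeps global scalars, so its
count is smaller and its tornado coarser.

* **Monte Carlo**: 1,000 joint draws by default; 95% uncertainty
  intervals are the 2.5th/97.5th output percentiles; the all-at-means
  point estimate is reported alongside and falls inside the UI.
* **Deterministic sensitivity**: ±10% of each mean, one at a time,
  others at means; out-of-domain perturbations (e.g. coverage 0.95 ×
  1.1) are clipped to bounds with a warning. On the default portfolio
  the depression/anxiety effect size dominates both tornados; the
  disability weight ranks in the top three; the suicide effect size
  ranks around sixth for the universal program because averted YLDs are
  ~92% of its health gains here, which caps how much the suicide pathway
  can move the ACER.
* **Spearman PSA**: rank correlation of each parameter's joint draws
  with each ACER, computed with `stats::cor(method = "spearman")` and
  cross-checked in the tests against an explicit rank-then-Pearson
  computation; constant columns report `NA`.
* **Threshold analysis**: both intervention effects are scaled toward
  the null as $RR(f) = 1 - (1-RR)(1-f)$ on a 1% grid; at $f = 1$ all RRs
  are 1, HLYG is zero and the ACER is undefined. Ceiling crossings
  (I\$5,000/HLYG universal, I\$50,000/HLYG indicated) are reported with
  linear interpolation between grid points.

## Numerical choices and degenerate inputs

Rates convert to probabilities by $1-e^{-r}$, guaranteeing $[0,1)$;
competing risks normalize proportionally only if a cell's exits would
exceed 1; remission returning to an empty at-risk pool goes to the
general compartment; migration into an empty cell enters the general
at-risk state; migration outflows are clipped at the available
population with a warning; zero-HLYG ACERs are `NA` with an explicit
flag. All randomness flows through explicit seeds (`withr::with_seed`),
so profiles, portfolios and Monte Carlo runs are bit-reproducible; the
annual cycle itself contains no randomness. The cycle engine is
implemented in C++ for speed and is pinned by exact-match tests against
hand-computed chains and an independent scalar-loop R enumeration of all
state flows.

## Problem sizes

The shipped analyses use the full study conditions: 20 countries, ages
0–100 × 2 sexes, 100-year horizon, 1,000 Monte Carlo iterations, 101
threshold grid points. A complete base case runs in under a second and
the full uncertainty suite in a few minutes on a single core; unit tests
use smaller horizons and portfolios where the property under test does
not require the full size.

## Known limitations

* Absolute results are calibrated only to a per-capita cost band; they
  are not comparable to any real country's figures.
* The universal-to-indicated health-gain ratio is structurally pinned
  near $\big[(1-s)+sm\big](1-RR_u) \;/\; \big[s\,m\,(1-RR_i)\big]$ for
  subthreshold share $s$ and incidence multiplier $m$; with the default
  $s=0.05$, $m=2$ and the converted RRs this is ≈6, and recurrence
  dynamics lift the simulated ratio only to ≈7.5 — a structural property
  worth keeping in mind when comparing against analyses reporting
  larger multiples.
* Screening in the indicated arm is cost-only: no detection benefit, no
  imperfect sensitivity/specificity.
* No healthcare cost offsets, productivity or education effects; no
  half-cycle correction (annual accounting throughout); stationary
  rates over the century.
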