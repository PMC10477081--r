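# Markov engine: hand-computed chains, null equivalence, conservation,
# absorbing dead states, monotonicity and program dominance.

test_that("two-cycle four-state chain matches the hand computation", {
  p <- flat_profile(ages = 30, pop = 1000, mort = 0.01, sui = 0.004,
                    inc_dep = 0.1, rem_dep = 0.3, prev_dep = 0.2,
                    births = 0, mig = 0)
  tr <- run_scenario(p, scenario_spec("null"), horizon = 2)
  # hand-computed chain (independent arithmetic, female column)
  p_inc <- 1 - exp(-0.1); p_rem <- 1 - exp(-0.3)
  p_sui <- 1 - exp(-0.004); p_oth <- 1 - exp(-0.01)
  S <- 800; D <- 200; cyc_s <- cyc_o <- numeric(2)
  for (cycle in 1:2) {
    iS <- S * p_inc; sS <- S * p_sui; oS <- S * p_oth
    rD <- D * p_rem; sD <- D * p_sui; oD <- D * p_oth
    S1 <- S - iS - sS - oS + rD
    D1 <- D + iS - rD - sD - oD
    cyc_s[cycle] <- sS + sD; cyc_o[cycle] <- oS + oD
    S <- S1; D <- D1
  }
  # cohort has aged 30 -> 32; deaths are tallied at the age when they occur
  expect_equal(unname(tr$occupancy$at_risk_general[3, 33, "female"]), S,
               tolerance = 1e-12)
  expect_equal(unname(tr$occupancy$dep_anx[3, 33, "female"]), D,
               tolerance = 1e-12)
  expect_equal(unname(tr$occupancy$dead_suicide[3, 31, "female"]), cyc_s[1],
               tolerance = 1e-12)
  expect_equal(unname(tr$occupancy$dead_suicide[3, 32, "female"]), cyc_s[2],
               tolerance = 1e-12)
  expect_equal(unname(tr$occupancy$dead_other[3, 32, "female"]), cyc_o[2],
               tolerance = 1e-12)
  expect_equal(tr$summary$suicide_deaths, 2 * cyc_s, tolerance = 1e-12)
})

test_that("all-RRs-equal-1 intervention is identical to the null scenario", {
  p <- generate_country(5, "LLMIC")
  null <- run_scenario(p, scenario_spec("null"), horizon = 30)
  inert <- run_scenario(p, scenario_spec("universal", rr_incidence = 1,
                                         rr_suicide = 1), horizon = 30)
  expect_equal(inert$summary, null$summary, tolerance = 1e-12)
  expect_equal(inert$occupancy$dep_anx, null$occupancy$dep_anx,
               tolerance = 1e-12)
  av <- averted(null, inert)
  expect_equal(sum(abs(av$cases_averted)), 0, tolerance = 1e-9)
  expect_equal(sum(abs(av$suicides_averted)), 0, tolerance = 1e-9)
})

test_that("a fully protective incidence effect zeroes eligible incidence", {
  p <- generate_country(5, "LLMIC")
  scen <- scenario_spec("universal", rr_incidence = 0, rr_suicide = 1,
                        coverage_target = 1, enrolment_adjusted = FALSE)
  tr <- run_scenario(p, scen, horizon = 10)
  # full implementation from year 6: no incident cases at eligible ages
  expect_equal(max(abs(tr$incident_cases[6:10, 13:18, ])), 0)
  # incidence continues at non-eligible ages
  expect_gt(sum(tr$incident_cases[6:10, 25:40, ]), 0)
})

test_that("brute-force ledger enumeration matches the engine exactly", {
  p <- flat_profile(ages = c(11, 14, 16), pop = 900, mort = 0.008,
                    sui = 1e-4, inc_dep = 0.03, rem_dep = 0.28,
                    prev_dep = 0.08, inc_anx = 0.02, rem_anx = 0.22,
                    prev_anx = 0.05, births = 40, mig = 2)
  for (program in c("null", "universal", "indicated")) {
    scen <- scenario_spec(program,
                          rollout = list(delivery_start = 2, full_start = 4))
    tr <- run_scenario(p, scen, horizon = 8)
    ref <- reference_markov(p, scen, horizon = 8)
    for (t in 1:9) {
      expect_equal(unname(tr$occupancy$at_risk_general[t, , ]),
                   unname(ref$occ$S[[t]]), tolerance = 1e-12)
      expect_equal(unname(tr$occupancy$at_risk_subthreshold[t, , ]),
                   unname(ref$occ$U[[t]]), tolerance = 1e-12)
      expect_equal(unname(tr$occupancy$dep_anx[t, , ]),
                   unname(ref$occ$D[[t]]), tolerance = 1e-12)
    }
    expect_equal(tr$summary$incident_cases, ref$cases, tolerance = 1e-12)
    expect_equal(tr$summary$suicide_deaths, ref$suicides, tolerance = 1e-12)
  }
})

test_that("per-cycle conservation ledger reconciles alive and dead", {
  p <- generate_country(9, "UMHIC")
  tr <- run_scenario(p, scenario_spec("universal"), horizon = 40)
  alive <- apply(tr$occupancy$at_risk_general +
                   tr$occupancy$at_risk_subthreshold +
                   tr$occupancy$dep_anx, 1, sum)
  for (t in 1:40) {
    expected <- alive[t] - sum(tr$suicide_deaths[t, , ]) -
      sum(tr$deaths_other[t, , ]) + tr$births[t] +
      sum(tr$migrants[t, , ])
    expect_equal(unname(alive[t + 1]), unname(expected), tolerance = 1e-9)
  }
})

test_that("dead states are absorbing and occupancy stays non-negative", {
  p <- generate_country(9, "LLMIC")
  tr <- run_scenario(p, scenario_spec("indicated"), horizon = 30)
  dead_tot <- apply(tr$occupancy$dead_suicide + tr$occupancy$dead_other,
                    1, sum)
  expect_true(all(diff(dead_tot) >= 0))
  for (st in names(tr$occupancy))
    expect_true(all(tr$occupancy[[st]] >= -1e-12))
})

test_that("more protective RRs avert weakly more outcomes", {
  p <- generate_country(13, "LLMIC")
  null <- run_scenario(p, scenario_spec("null"), horizon = 40,
                       keep_trace = FALSE)
  cases <- suis <- numeric(0)
  for (rr in c(1, 0.9, 0.8, 0.6)) {
    tr <- run_scenario(p, scenario_spec("universal", rr_incidence = rr,
                                        rr_suicide = rr),
                       horizon = 40, keep_trace = FALSE)
    av <- averted(null, tr)
    cases <- c(cases, sum(av$cases_averted))
    suis <- c(suis, sum(av$suicides_averted))
  }
  expect_true(all(diff(cases) > 0))
  expect_true(all(diff(suis) > 0))
})

test_that("universal averts more cases than indicated on the same profile", {
  p <- generate_country(17, "LLMIC")
  null <- run_scenario(p, scenario_spec("null"), horizon = 50,
                       keep_trace = FALSE)
  u <- run_scenario(p, scenario_spec("universal"), horizon = 50,
                    keep_trace = FALSE)
  i <- run_scenario(p, scenario_spec("indicated"), horizon = 50,
                    keep_trace = FALSE)
  expect_gt(sum(averted(null, u)$cases_averted),
            sum(averted(null, i)$cases_averted))
  # both programs avert cases and suicides during full implementation
  expect_true(all(averted(null, u)$cases_averted[6:50] > 0))
  expect_true(all(averted(null, u)$suicides_averted[6:50] > 0))
})

test_that("averted() enforces shape compatibility", {
  p <- generate_country(1, "LLMIC")
  a <- run_scenario(p, scenario_spec("null"), 5, keep_trace = FALSE)
  b <- run_scenario(p, scenario_spec("null"), 6, keep_trace = FALSE)
  expect_error(averted(a, b), "horizon")
})

test_that("inconsistent rates trigger the exit-probability warning", {
  p <- flat_profile(ages = 50, pop = 100, mort = 3, sui = 1, inc_dep = 2,
                    prev_dep = 0.1)
  expect_warning(run_scenario(p, scenario_spec("null"), 2), "normalized")
})

test_that("rollout ramps 1/3, 2/3, full across years 3-5", {
  expect_equal(rollout_fraction(1:7),
               c(0, 0, 1 / 3, 2 / 3, 1, 1, 1))
  expect_equal(rollout_fraction(1:3,
                                list(delivery_start = 1, full_start = 1)),
               c(1, 1, 1))
})
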