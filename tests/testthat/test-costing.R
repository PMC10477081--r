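# Staged costing: category structure, linearity in unit costs,
# program ordering, discounting.

test_that("stages gate delivery costs and the null program costs nothing", {
  p <- generate_country(3, "LLMIC")
  scen <- scenario_spec("universal")
  ct <- cost_scenario(p, scen, horizon = 10)
  # years 1-2: program-level costs only
  expect_equal(sum(ct$cost_by_year[1:2, c("training", "delivery",
                                          "supplies_equipment",
                                          "screening")]), 0)
  expect_gt(sum(ct$cost_by_year[1:2, c("management", "advocacy")]), 0)
  # ramp: delivery in year 4 is twice year 3, year 6 equals year 7
  expect_equal(ct$cost_by_year[4, "delivery"] /
                 ct$cost_by_year[3, "delivery"], 2, tolerance = 0.05)
  expect_gt(ct$cost_by_year[6, "delivery"], 0)
  # screening only exists for the indicated program
  expect_equal(sum(ct$cost_by_year[, "screening"]), 0)
  ci <- cost_scenario(p, scenario_spec("indicated"), horizon = 10)
  expect_gt(sum(ci$cost_by_year[, "screening"]), 0)
  cn <- cost_scenario(p, scenario_spec("null"), horizon = 10)
  expect_equal(cn$total_undiscounted, 0)
})

test_that("zero coverage leaves only program-level costs", {
  p <- generate_country(3, "LLMIC")
  ct <- cost_scenario(p, scenario_spec("universal", coverage_target = 0), 10)
  expect_equal(sum(ct$cost_by_year[, c("training", "delivery",
                                       "supplies_equipment", "screening")]),
               0)
  expect_gt(ct$total_undiscounted, 0)
})

test_that("doubling the facilitator wage doubles wage-linked categories", {
  p <- generate_country(3, "LLMIC")
  p2 <- p
  p2$unit_costs$facilitator_wage <- 2 * p$unit_costs$facilitator_wage
  for (prog in c("universal", "indicated")) {
    a <- cost_scenario(p, scenario_spec(prog), 12)
    b <- cost_scenario(p2, scenario_spec(prog), 12)
    expect_equal(b$cost_by_year[, "delivery"],
                 2 * a$cost_by_year[, "delivery"])
    expect_equal(b$cost_by_year[, "screening"],
                 2 * a$cost_by_year[, "screening"])
    expect_equal(b$cost_by_year[, "supplies_equipment"],
                 a$cost_by_year[, "supplies_equipment"])
  }
})

test_that("costs are monotone in coverage and session volume", {
  p <- generate_country(6, "UMHIC")
  totals <- vapply(c(0.2, 0.5, 0.95), function(cov)
    cost_scenario(p, scenario_spec("universal", coverage_target = cov),
                  15)$total_undiscounted, numeric(1))
  expect_true(all(diff(totals) > 0))
  p2 <- p; p2$unit_costs$session_count <- p$unit_costs$session_count + 5
  expect_gt(cost_scenario(p2, scenario_spec("universal"), 15)$total_undiscounted,
            cost_scenario(p, scenario_spec("universal"), 15)$total_undiscounted)
})

test_that("indicated costs less than universal; discounting shrinks totals", {
  for (seed in c(3, 8)) for (grp in c("LLMIC", "UMHIC")) {
    p <- generate_country(seed, grp)
    cu <- cost_scenario(p, scenario_spec("universal"), 50)
    ci <- cost_scenario(p, scenario_spec("indicated"), 50)
    expect_lt(ci$total_undiscounted, cu$total_undiscounted)
    expect_lt(cu$total_discounted, cu$total_undiscounted)
  }
})

test_that("per-capita annualized cost sits in the expected range", {
  p <- generate_country(1, "LLMIC")
  ct <- cost_scenario(p, scenario_spec("universal"), 100)
  expect_gte(ct$per_capita_annualized, 0.05)
  expect_lte(ct$per_capita_annualized, 0.20)
})

test_that("degenerate inputs are rejected", {
  p <- generate_country(1, "LLMIC")
  p$unit_costs$facilitator_wage <- -1
  expect_error(cost_scenario(p, scenario_spec("universal"), 5),
               "non-negative")
})
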