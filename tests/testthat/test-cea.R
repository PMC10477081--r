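# ACER arithmetic, group aggregation as ratio-of-sums, purity of the
# pipeline runs.

fake_cost <- function(cost, pop = 1e6, horizon = 50, program = "universal") {
  structure(list(program = program, country = "X",
                 cost_by_year = NULL, total_discounted = cost,
                 total_undiscounted = cost,
                 per_capita_annualized = cost / horizon / pop,
                 mean_population = pop, discount_rate_cost = 0.03,
                 horizon = horizon), class = "cost_trace")
}
fake_burden <- function(hlyg, yld_share = 0.9, years = 50) {
  yld <- hlyg * yld_share; yll <- hlyg - yld
  structure(list(yll_by_year = rep(yll / years, years),
                 yld_by_year = rep(yld / years, years),
                 yll_total = yll, yld_total = yld, hlyg_total = hlyg,
                 yld_share = if (hlyg > 0) yld_share else NA_real_,
                 cases_averted_by_year = rep(1, years),
                 suicides_averted_by_year = rep(0.01, years),
                 discount_rate_health = 0), class = "burden_result")
}

test_that("ACER is cost over HLYG, undefined at zero HLYG", {
  r <- compute_acer(fake_cost(958), fake_burden(1))
  expect_equal(r$acer, 958)
  expect_false(r$acer_undefined)
  r2 <- compute_acer(fake_cost(958), fake_burden(2))
  expect_equal(r2$acer, 479)
  r0 <- compute_acer(fake_cost(958), fake_burden(0))
  expect_true(r0$acer_undefined)
  expect_true(is.na(r0$acer))
})

test_that("group aggregation is ratio-of-sums, not mean of ratios", {
  a <- compute_acer(fake_cost(100), fake_burden(10), country = "A",
                    income_group = "LLMIC")
  b <- compute_acer(fake_cost(300), fake_burden(10), country = "B",
                    income_group = "LLMIC")
  g <- aggregate_group(rbind(a, b))
  expect_equal(g$acer, 400 / 20)
  expect_equal(g$total_cost, 400)
  expect_equal(g$hlyg, 20)
  # mediant property: group ACER between member min and max
  set.seed(42)
  rows <- do.call(rbind, lapply(1:6, function(i)
    compute_acer(fake_cost(runif(1, 50, 500)),
                 fake_burden(runif(1, 1, 30)), country = paste0("C", i),
                 income_group = "LLMIC")))
  g2 <- aggregate_group(rows)
  expect_gte(g2$acer, min(rows$acer))
  expect_lte(g2$acer, max(rows$acer))
  # single-country aggregation is the identity on totals
  g1 <- aggregate_group(a)
  expect_equal(g1$acer, a$acer)
  expect_equal(g1$hlyg, a$hlyg)
  expect_error(aggregate_group(rows[0, ]))
  expect_error(aggregate_group(rbind(a, compute_acer(fake_cost(1),
                                                     fake_burden(1),
                                                     program = "x"))))
})

test_that("an uneven-ratio pair shows sums-vs-means distinction", {
  a <- compute_acer(fake_cost(100), fake_burden(1), income_group = "LLMIC")
  b <- compute_acer(fake_cost(100), fake_burden(99), income_group = "LLMIC")
  g <- aggregate_group(rbind(a, b))
  expect_equal(g$acer, 200 / 100)
  expect_false(isTRUE(all.equal(g$acer, mean(c(a$acer, b$acer)))))
})

test_that("run_country returns one consistent row per program", {
  p <- generate_country(1, "LLMIC")
  res <- run_country(p, horizon = 30)
  expect_equal(nrow(res), 2)
  expect_setequal(res$program, c("universal", "indicated"))
  expect_true(all(res$hlyg > 0))
  expect_true(all(res$acer > 0))
  expect_equal(res$acer, res$total_cost / res$hlyg)
  expect_equal(res$hlyg_per_million_per_year,
               res$hlyg / res$horizon / (res$mean_population / 1e6))
})

test_that("pipeline runs are pure: profiles are never mutated", {
  p <- generate_country(1, "LLMIC")
  snapshot <- unserialize(serialize(p, NULL))
  r1 <- run_country(p, horizon = 20)
  r2 <- run_country(p, horizon = 20)
  expect_identical(p, snapshot)
  expect_identical(r1, r2)
})

test_that("summarize_portfolio produces the income-group x program table", {
  profs <- generate_portfolio(2, 2, seed = 3)
  res <- run_portfolio(profs, horizon = 25)
  s <- summarize_portfolio(res)
  expect_equal(nrow(s), 6)  # (LLMIC, UMHIC, all) x 2 programs
  expect_setequal(unique(s$program), c("universal", "indicated"))
  expect_setequal(unique(s$country), c("LLMIC", "UMHIC", "all"))
})
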