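# Synthetic country generator: seeded determinism, epidemiological shape,
# income-group separation, serialization round trip.

test_that("generation is deterministic per seed and varies across seeds", {
  a <- generate_country(1, "LLMIC")
  b <- generate_country(1, "LLMIC")
  expect_identical(a, b)
  c2 <- generate_country(2, "LLMIC")
  expect_false(identical(a$population, c2$population))
  expect_error(generate_country(-1, "LLMIC"))
  expect_error(generate_country(1, "MIDDLE"))
})

test_that("profiles satisfy the documented invariants", {
  for (seed in c(1, 7, 21)) for (grp in c("LLMIC", "UMHIC")) {
    p <- generate_country(seed, grp)
    expect_silent(validate_country_profile(p))
    expect_true(all(p$population >= 0))
    expect_true(all(dim(p$population) == c(101, 2)))
    expect_gte(p$enrolment_12_17, 0); expect_lte(p$enrolment_12_17, 1)
    # soft steady-state: prevalence within 20% of inc/(inc+rem)
    for (cond in c("dep_epi", "anx_epi")) {
      e <- p[[cond]]
      target <- e$incidence / (e$incidence + e$remission)
      expect_lt(max(abs(e$prevalence - target) / target), 0.20)
    }
  }
})

test_that("epidemiological age shapes match the assumed structure", {
  p <- generate_country(3, "LLMIC")
  inc <- p$dep_epi$incidence[, "female"]
  peak_age <- which.max(inc) - 1
  expect_gte(peak_age, 12); expect_lte(peak_age, 30)
  # suicide near zero in childhood, rising through adolescence
  sui <- p$suicide_mortality[, "male"]
  expect_lt(sui[9], 0.05 * sui[21])        # age 8 vs age 20
  expect_gt(sui[17], sui[13])              # rising 12 -> 16
  expect_true(all(p$suicide_mortality <= p$all_cause_mortality))
})

test_that("income groups separate on enrolment and unit costs", {
  umhic <- generate_country(1, "UMHIC")
  expect_gt(umhic$enrolment_12_17,
            selcea:::income_group_defaults("LLMIC")$enrolment_mean)
  wages <- function(grp, seeds) vapply(seeds, function(s)
    generate_country(s, grp)$unit_costs$facilitator_wage, numeric(1))
  seeds <- 1:6
  expect_gt(mean(wages("UMHIC", seeds)), mean(wages("LLMIC", seeds)))
})

test_that("portfolio has the requested composition and distinct countries", {
  pf <- generate_portfolio(10, 10, seed = 7)
  expect_length(pf, 20)
  grps <- vapply(pf, `[[`, "", "income_group")
  expect_equal(sum(grps == "LLMIC"), 10)
  expect_equal(sum(grps == "UMHIC"), 10)
  pops <- vapply(pf, function(p) sum(p$population), numeric(1))
  expect_equal(length(unique(pops)), 20)  # distinct sub-seeds
  single <- generate_portfolio(0, 1, seed = 7)
  expect_length(single, 1)
  expect_equal(single[[1]]$income_group, "UMHIC")
  expect_error(generate_portfolio(-1, 2, seed = 1))
  expect_error(generate_portfolio(0, 0, seed = 1))
})

test_that("serialization round-trips and reruns are byte-identical", {
  pf <- generate_portfolio(1, 1, seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_country_profile(pf[[1]], d1)
  back <- read_country_profile(d1)
  expect_equal(back$population, pf[[1]]$population, tolerance = 1e-12)
  expect_equal(back$dep_epi$incidence, pf[[1]]$dep_epi$incidence,
               tolerance = 1e-12)
  expect_equal(back$unit_costs$facilitator_wage,
               pf[[1]]$unit_costs$facilitator_wage, tolerance = 1e-12)
  expect_equal(back$income_group, pf[[1]]$income_group)
  # regenerated portfolio serializes to identical bytes
  write_country_profile(generate_portfolio(1, 1, seed = 7)[[1]], d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})
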