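# Distributions, Monte Carlo reproducibility, DSA, Spearman PSA and the
# threshold analysis, mostly on small analytic models.

test_that("distribution constructors validate and sample in-domain", {
  expect_error(param_distribution("x", "lognormal_rr", 0.8))       # no CI
  expect_error(param_distribution("x", "beta_proportion", 1.2))
  d <- param_distribution("rr", "lognormal_rr", 0.84, ci = c(0.75, 0.94))
  x <- withr::with_seed(1, sample_distribution(d, 500))
  expect_true(all(x > 0))
  b <- param_distribution("p", "beta_proportion", 0.05, cv = 0.2)
  y <- withr::with_seed(1, sample_distribution(b, 500))
  expect_true(all(y > 0 & y < 1))
  expect_equal(mean(y), 0.05, tolerance = 0.05)
  g <- param_distribution("c", "gamma_cost", 2, cv = 0.1,
                          lower = 1, upper = 3)
  z <- withr::with_seed(1, sample_distribution(g, 500))
  expect_true(all(z >= 1 & z <= 3))
})

test_that("degenerate distributions give zero-width intervals", {
  model <- function(values) c(out = 3 * values[["a"]] + values[["b"]])
  dists <- list(a = param_distribution("a", "fixed", 2),
                b = param_distribution("b", "fixed", 1))
  mc <- monte_carlo(model, dists, n = 25, seed = 4)
  expect_equal(unname(mc$ui["out", "lo"]), 7)
  expect_equal(unname(mc$ui["out", "hi"]), 7)
  expect_equal(unname(mc$point[["out"]]), 7)
})

test_that("monte_carlo is seed-reproducible and point sits at means", {
  model <- function(values) c(out = values[["a"]]^2)
  dists <- list(a = param_distribution("a", "gamma_cost", 2, cv = 0.2))
  m1 <- monte_carlo(model, dists, n = 200, seed = 9)
  m2 <- monte_carlo(model, dists, n = 200, seed = 9)
  expect_identical(m1$ui, m2$ui)
  expect_identical(m1$draws, m2$draws)
  expect_equal(unname(m1$point[["out"]]), 4)
  m3 <- monte_carlo(model, dists, n = 200, seed = 10)
  expect_false(identical(m1$ui, m3$ui))
  expect_error(monte_carlo(model, dists, n = 1, seed = 1))
})

test_that("lognormal sampling recovers analytic quantiles", {
  d <- param_distribution("rr", "lognormal_rr", 0.84, ci = c(0.75, 0.94))
  sdlog <- (log(0.94) - log(0.75)) / (2 * qnorm(0.975))
  x <- withr::with_seed(11, sample_distribution(d, 10000))
  expect_equal(unname(quantile(x, 0.025)),
               qlnorm(0.025, log(0.84), sdlog), tolerance = 0.02)
  expect_equal(unname(quantile(x, 0.975)),
               qlnorm(0.975, log(0.84), sdlog), tolerance = 0.02)
})

test_that("DSA gives zero range for ignored parameters and clips domains", {
  model <- function(values) c(out = values[["used"]] * 10)
  dists <- list(used = param_distribution("used", "gamma_cost", 5, cv = 0.2),
                ignored = param_distribution("ignored", "gamma_cost", 1,
                                             cv = 0.2))
  rep <- dsa_univariate(model, dists)
  expect_equal(rep$range[rep$parameter == "ignored"], 0)
  expect_equal(rep$range[rep$parameter == "used"], 10, tolerance = 1e-9)
  expect_equal(attr(rep, "baseline")[["out"]], 50)
  # +10% above an upper bound is clipped with a warning
  capped <- list(p = param_distribution("p", "beta_proportion", 0.95,
                                        cv = 0.02, upper = 1))
  expect_warning(dsa_univariate(function(v) c(out = v[["p"]]), capped),
                 "clipped")
})

test_that("tornado ranking orders parameters by output range", {
  model <- function(values) c(out = 5 * values[["big"]] + values[["small"]])
  dists <- list(big = param_distribution("big", "gamma_cost", 10, cv = 0.2),
                small = param_distribution("small", "gamma_cost", 10,
                                           cv = 0.2))
  rep <- dsa_univariate(model, dists)
  tr <- tornado_ranking(rep, "out")
  expect_equal(tr$parameter, c("big", "small"))
  expect_equal(tr$rank, 1:2)
  # invariant to registry ordering
  rep2 <- dsa_univariate(model, rev(dists))
  expect_equal(tornado_ranking(rep2, "out")$parameter, c("big", "small"))
  expect_error(tornado_ranking(rep, "nonexistent"))
})

test_that("Spearman PSA matches a brute-force rank-then-Pearson oracle", {
  set.seed(21)
  draws <- cbind(a = rnorm(40), b = runif(40), c = rexp(40))
  out <- draws[, "a"]^3 - 2 * draws[, "b"] + rnorm(40, sd = 0.1)
  got <- psa_spearman(draws, cbind(y = out))
  for (p in c("a", "b", "c")) {
    oracle <- cor(rank(draws[, p]), rank(out))  # plain Pearson on ranks
    expect_equal(got$r_s[got$parameter == p], oracle, tolerance = 1e-12)
  }
  # exact monotone relations and the undefined case
  x <- cbind(m = 1:30, const = rep(2, 30))
  expect_equal(psa_spearman(x, (1:30)^2)$r_s, c(1, NA_real_))
  expect_equal(psa_spearman(x[, "m", drop = FALSE], -(1:30))$r_s, -1)
  expect_error(psa_spearman(x[1:2, ], 1:2))
})

test_that("independent parameters show near-zero rank correlation", {
  set.seed(31)
  draws <- cbind(a = rnorm(2000))
  out <- rnorm(2000)
  expect_lt(abs(psa_spearman(draws, out)$r_s), 0.1)
})

test_that("threshold analysis finds interpolated ceiling crossings", {
  # analytic stand-in: ACER = 100 / (1 - f), undefined at f = 1
  model <- function(values = NULL, rr_reduction = 0) {
    c(acer_universal_all = if (rr_reduction >= 1) NA_real_ else
      100 / (1 - rr_reduction))
  }
  thr <- threshold_analysis(model, reductions = seq(0, 1, 0.01),
                            ceilings = c(universal = 5000))
  v <- thr$curve$acer
  expect_true(all(diff(v[!is.na(v)]) >= 0))
  expect_true(is.na(v[length(v)]))                # f = 1 undefined
  expect_equal(v[1], 100)                         # f = 0 is the base case
  expect_equal(thr$crossings$max_reduction, 1 - 100 / 5000,
               tolerance = 1e-10)
})
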