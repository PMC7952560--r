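test_that("MSS pmf matches closed forms and the recursion's first steps", {
  # no mutations: all mass at zero
  expect_equal(ld_pmf(0, 5)$pmf, c(1, 0, 0, 0, 0, 0))
  # p0 = exp(-m) exactly, for several m
  for (m in c(0.1, 1, 2, 8))
    expect_identical(ld_pmf(m, 0)$pmf[1], exp(-m))
  # one and two steps of the recursion, evaluated by hand:
  # p1 = m p0 / 2, p2 = (m/2)(p0/3 + p1/2) = e^-m (m/6 + m^2/8)
  for (m in c(0.5, 1, 3)) {
    p <- ld_pmf(m, 2)$pmf
    expect_equal(p[2], m * exp(-m) / 2)
    expect_equal(p[3], exp(-m) * (m / 6 + m^2 / 8))
  }
})

test_that("pmf is a deficient distribution whose tail deficit shrinks", {
  p <- ld_pmf(2, 200)$pmf
  expect_true(all(p >= 0))
  partial <- cumsum(p)
  expect_true(all(partial <= 1 + 1e-12))
  deficit <- 1 - partial
  expect_true(all(diff(deficit) <= 0))
  expect_lt(deficit[201], 0.02)  # -> 1 as r_max grows
  expect_error(ld_pmf(-1, 5), "non-negative")
  expect_error(ld_pmf(1, 2.5), "integer")
})

test_that("pmf head matches Monte-Carlo clone-size simulation", {
  sim <- simulate_fluctuation(mu = 1 / (2^20 - 1), n_final = 2^20,
                              n_cultures = 1e6, seed = 101)
  cnt <- sim$experiment$counts
  p <- ld_pmf(1, 3)$pmf
  for (r in 0:3)
    expect_equal(mean(cnt == r), p[r + 1], tolerance = 0.02)
})

test_that("MSS MLE handles boundaries and matches the grid-search oracle", {
  expect_equal(mss_mle(rep(0, 8)), 0)
  fixtures <- list(
    c(0, 0, 1, 0, 12, 2, 0, 1),
    c(0, 5, 0, 0, 0, 0, 1, 0, 0, 0),
    c(3, 1, 0, 7, 2, 0, 1, 25, 0, 4, 1, 0),
    rep(c(0, 1), 10),
    c(0, 0, 0, 150, 2, 1))
  for (cnt in fixtures) {
    m_hat <- mss_mle(cnt)
    oracle <- grid_mle(cnt)
    expect_equal(m_hat, oracle, tolerance = 1e-3)
    # appending a culture at the modal count stays on the oracle
    mode_cnt <- as.numeric(names(which.max(table(cnt))))
    cnt2 <- c(cnt, mode_cnt)
    expect_equal(mss_mle(cnt2), grid_mle(cnt2), tolerance = 1e-3)
  }
  expect_error(mss_mle(numeric(0)), "at least one")
})

test_that("P0 estimator follows its closed form and fails without zeros", {
  expect_equal(p0_estimate(c(0, 0, 0, 0)), 0)
  expect_equal(p0_estimate(c(0, 0, 5, 12)), -log(0.5))
  expect_error(p0_estimate(c(3, 7, 9)), "undefined")
})

test_that("Stewart CI follows the stated formula and shrinks with C", {
  ci <- confidence_interval(1, 24)
  sigma <- 1.225 / sqrt(24)
  expect_equal(ci[["sigma_ln_m"]], sigma)
  expect_equal(ci[["lower"]], exp(-1.96 * sigma))
  expect_equal(ci[["upper"]], exp(+1.96 * sigma))
  expect_equal(ci[["lower"]], 0.6125, tolerance = 1e-3)
  expect_equal(ci[["upper"]], 1.6327, tolerance = 1e-3)
  # interval collapses onto m_hat as C grows
  wide <- confidence_interval(1, 10)
  narrow <- confidence_interval(1, 1e8)
  expect_lt(diff(narrow[1:2]), diff(wide[1:2]))
  expect_equal(unname(narrow[["lower"]]), 1, tolerance = 1e-3)
  # asymmetric variant still brackets the point estimate, wider above
  asym <- confidence_interval(1, 24, asymmetric = TRUE)
  expect_lt(asym[["lower"]], 1)
  expect_gt(asym[["upper"]], 1)
  expect_gt(asym[["upper"]] - 1, 1 - asym[["lower"]])
  expect_error(confidence_interval(0, 24), "positive")
})

test_that("rates derive from m by division, with optional corrections", {
  exp1 <- fluctuation_experiment(c(2, 0, 3, 1), n_final = 1e7,
                                 plating_fraction = 0.5)
  est <- rate_from_m(2, exp1)
  expect_equal(est$mu, 2e-7)
  expect_equal(est$ci_low / est$mu,
               confidence_interval(2, 4)[["lower"]] / 2)
  # plating correction off by default: z ignored; on: (z-1)/(z log z) factor
  est_on <- rate_from_m(2, exp1, plating_correction = TRUE)
  z <- 0.5
  expect_equal(est_on$mu, 2 * (z - 1) / (z * log(z)) / 1e7)
  # per-generation variant divides by ln 2
  expect_equal(rate_from_m(2, exp1, per_generation = TRUE)$mu,
               2e-7 / log(2))
  # zero estimate: rate 0, CI undefined
  est0 <- rate_from_m(0, exp1)
  expect_equal(est0$mu, 0)
  expect_true(is.na(est0$ci_low))
})

test_that("fold changes reproduce the worked rate comparisons", {
  expect_equal(compare_rates(mutation_rate_estimate(3e-5),
                             mutation_rate_estimate(3e-5))$fold, 1)
  expect_equal(compare_rates(mutation_rate_estimate(2.7e-3),
                             mutation_rate_estimate(2.5e-5))$fold, 108)
  cmp <- compare_rates(mutation_rate_estimate(1.1e-2),
                       mutation_rate_estimate(1.6e-8))
  expect_equal(cmp$fold, 687500)
  expect_equal(cmp$fold_2sf, 690000)
  expect_warning(out <- compare_rates(mutation_rate_estimate(1e-3),
                                      mutation_rate_estimate(0)),
                 "undefined")
  expect_true(is.na(out$fold))
})

test_that("estimate_rate wires estimator choice through to the rate", {
  sim <- simulate_fluctuation(mu = 2e-7, n_final = 1e7, n_cultures = 48,
                              seed = 77)
  est <- estimate_rate(sim$experiment)
  expect_equal(est$method, "mss_mle")
  expect_equal(est$mu * 1e7, mss_mle(sim$experiment))
  est_p0 <- estimate_rate(sim$experiment, method = "p0")
  expect_equal(est_p0$mu * 1e7, p0_estimate(sim$experiment))
})
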