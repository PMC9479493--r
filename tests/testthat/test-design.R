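test_that("power_curve at a single n reproduces estimate_power exactly", {
  # the prefix evaluation consumes the identical RNG substreams
  sc <- scenario(rate_percent = 2, sem = 0.00134, t_days = 60,
                 n_per_group = 15, iterations = 300, seed = 9)
  expect_identical(power_curve(sc, 15)$power, estimate_power(sc)$power)
})

test_that("power_curve is internally consistent across sample sizes", {
  sc <- scenario(rate_percent = 3.5, sem = 0.00134, t_days = 90,
                 iterations = 500, seed = 21)
  curve <- power_curve(sc, 4:20)
  expect_identical(curve$n_per_group, 4:20)
  # common random numbers: any monotonicity violation is within MC noise
  viol <- diff(curve$power)
  expect_gte(min(viol), -3 * max(curve$mc_se))
  expect_error(power_curve(sc, 1), "n_values")
})

test_that("minimal sample size search honours floor, target and sentinel", {
  # overwhelming homogeneous effect (no slope variability) so that even the
  # smallest admissible design detects it
  over <- scenario(rate_percent = 50, cv_percent = 0, sem = 0.00054,
                   t_days = 180, m = 1, iterations = 200, seed = 2)
  res <- min_sample_size(over, n_min = 3, n_max = 20)
  expect_true(res$reached)
  expect_identical(res$n, 3L)  # search floor for an overwhelming effect

  hopeless <- scenario(rate_percent = 0.5, sem = 0.00134, t_days = 30, m = 1,
                       iterations = 200, seed = 2)
  res2 <- min_sample_size(hopeless, n_min = 3, n_max = 8)
  expect_false(res2$reached)
  expect_identical(res2$n, NA_integer_)
  expect_identical(nrow(res2$curve), 6L)
  # smoothed curve is monotone non-decreasing by construction
  expect_gte(min(diff(res2$curve$power_smoothed)), 0)
  expect_error(min_sample_size(over, power_target = 1.2), "power_target")
  expect_error(min_sample_size(over, n_min = 10, n_max = 5), "n_min")
})

test_that("minimal n tracks the analytic oracle inversion within 2 subjects", {
  sc <- scenario(rate_percent = 3.5, sem = 0.00134, t_days = 90, m = 1,
                 iterations = 2000, seed = 14)
  res <- min_sample_size(sc, n_min = 3, n_max = 40)
  with_n <- function(n) { s <- sc; s$n_per_group <- as.integer(n); s }
  oracle_n <- 3
  while (analytic_power_oracle(with_n(oracle_n)) < 0.8 && oracle_n < 40) {
    oracle_n <- oracle_n + 1
  }
  expect_true(res$reached)
  expect_lte(abs(res$n - oracle_n), 2)
})

test_that("scan-repetition trade-off is null without measurement error", {
  sc <- scenario(rate_percent = 2, sem = 0, t_days = 60, iterations = 300,
                 seed = 4)
  red <- sample_size_reduction(sc, 1, 2, n_max = 60)
  expect_true(red$computable)
  expect_identical(red$reduction_percent, 0)
  expect_error(sample_size_reduction(sc, 2, 2), "differ")
})

test_that("unreached searches give an explicit not-computable trade-off", {
  sc <- scenario(rate_percent = 0.5, sem = 0.00134, t_days = 30,
                 iterations = 200, seed = 4)
  red <- sample_size_reduction(sc, 1, 2, n_max = 8)
  expect_false(red$computable)
  expect_identical(red$reduction_percent, NA_real_)
})

test_that("power_grid enumerates the Cartesian product deterministically", {
  grid <- power_grid(rates = c(0.5, 2.0, 3.5), sems = c(0.00054, 0.00134),
                     t_days_values = 60, m_values = 1, n_values = 10,
                     iterations = 100, seed = 6)
  expect_identical(nrow(grid), 6L)
  expect_identical(names(grid), c("rate_percent", "sem", "t_days", "m",
                                  "n_per_group", "power", "mc_se", "seed"))
  expect_true(all(grid$power >= 0 & grid$power <= 1))
  grid2 <- power_grid(rates = c(0.5, 2.0, 3.5), sems = c(0.00054, 0.00134),
                      t_days_values = 60, m_values = 1, n_values = 10,
                      iterations = 100, seed = 6)
  expect_identical(grid, grid2)
  expect_error(power_grid(rates = numeric(0), sems = 1, t_days_values = 60,
                          m_values = 1, n_values = 10),
               "empty grid")
})

test_that("power is monotone in the design levers under common random numbers", {
  base <- function(...) {
    estimate_power(scenario(rate_percent = 2, sem = 0.00134, n_per_group = 15,
                            iterations = 600, seed = 33, ...))$power
  }
  tol <- 3 * sqrt(0.25 / 600)
  expect_gte(base(t_days = 120) + tol, base(t_days = 60))
  expect_gte(base(t_days = 90, m = 2) + tol, base(t_days = 90, m = 1))
  p_slow <- estimate_power(scenario(rate_percent = 0.5, sem = 0.00134,
                                    t_days = 90, n_per_group = 15,
                                    iterations = 600, seed = 33))$power
  expect_gte(base(t_days = 90) + tol, p_slow)
})

test_that("power is invariant in scans per session when there is no measurement error", {
  m1 <- estimate_power(scenario(rate_percent = 2, sem = 0, t_days = 60,
                                n_per_group = 15, iterations = 300, seed = 9,
                                m = 1))
  m3 <- estimate_power(scenario(rate_percent = 2, sem = 0, t_days = 60,
                                n_per_group = 15, iterations = 300, seed = 9,
                                m = 3))
  expect_identical(m1$power, m3$power)
})
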