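test_that("retest_matrix enforces the complete-design invariants", {
  expect_error(retest_matrix(matrix(0.3, nrow = 1, ncol = 2)), "2 subjects")
  expect_error(retest_matrix(matrix(0.3, nrow = 3, ncol = 1)), "2 measurement")
  bad <- matrix(c(0.3, 0.31, NA, 0.33), nrow = 2)
  expect_error(retest_matrix(bad), "complete design")
  expect_error(retest_matrix(matrix("a", 2, 2)), "numeric")
  m <- retest_matrix(cbind(c(0.30, 0.32), c(0.31, 0.33)))
  expect_s3_class(m, "retest_matrix")
})

test_that("ICC is 1 when within-subject variance is zero", {
  x <- cbind(c(0.30, 0.32, 0.34, 0.36), c(0.30, 0.32, 0.34, 0.36))
  r <- compute_icc(x)
  expect_identical(r$icc, 1)
  expect_identical(r$ci_low, 1)
  expect_identical(r$ci_high, 1)
  expect_identical(r$sem, 0)
})

test_that("ICC matches the hand-summed two-way ANOVA oracle on a worked example", {
  x <- rbind(c(0.30, 0.31), c(0.32, 0.33), c(0.34, 0.33), c(0.36, 0.38))
  r <- compute_icc(x)
  o <- oracle_icc_tables(x)
  expect_equal(r$icc, o$icc_agreement, tolerance = 1e-12)
  expect_equal(r$icc, 8 / 9, tolerance = 1e-12)  # frozen from the oracle
  expect_equal(r$ms_between_subjects, o$msr, tolerance = 1e-12)
  expect_equal(r$ms_between_measurements, o$msc, tolerance = 1e-12)
  expect_equal(r$ms_error, o$mse, tolerance = 1e-12)
})

test_that("ICC agrees with the brute-force oracle on random small matrices", {
  set.seed(404)
  for (rep in 1:40) {
    n <- sample(3:6, 1)
    k <- sample(2:4, 1)
    x <- random_retest_matrix(n, k)
    r <- compute_icc(x)
    o <- oracle_icc_tables(x)
    expect_lt(abs(r$icc - o$icc_agreement), 1e-10)
    expect_lte(r$ci_low, r$icc)
    expect_gte(r$ci_high, r$icc)
  }
})

test_that("absolute-agreement ICC penalises a systematic occasion shift", {
  base <- c(0.30, 0.32, 0.34, 0.33, 0.36)
  x <- cbind(base, base + 0.05)  # shift large relative to the spread
  r <- compute_icc(x)
  o <- oracle_icc_tables(x)
  expect_lt(r$icc, o$icc_consistency)
})

test_that("ICC is invariant under adding a constant to every cell", {
  set.seed(11)
  x <- random_retest_matrix(8, 3)
  r1 <- compute_icc(x)
  r2 <- compute_icc(unclass(x) + 0.1)
  expect_equal(r1$icc, r2$icc, tolerance = 1e-12)
  expect_equal(r1$ci_low, r2$ci_low, tolerance = 1e-10)
})

test_that("degenerate and invalid reliability inputs raise informative errors", {
  expect_error(compute_icc(matrix(0.3, 4, 2)), "identical")
  expect_error(compute_icc(cbind(c(0.3, 0.32), c(0.31, 0.33)), confidence = 1.2),
               "confidence")
})

test_that("SEM formula behaves at its limits and matches hand arithmetic", {
  expect_identical(compute_sem(0.123, k = 3, icc = 1), 0)
  expect_identical(compute_sem(0.123, k = 3, icc = 0), 0)
  # sqrt(0.001/(2-1) * 0.9 * 0.1), by hand
  expect_equal(compute_sem(0.001, k = 2, icc = 0.9), 0.009486832980505,
               tolerance = 1e-12)
  expect_equal(compute_sem(0.001, k = 2, icc = 0.9, variant = "literal"),
               0.001 * 0.9 * 0.1, tolerance = 1e-15)
  expect_error(compute_sem(0.001, k = 2, icc = 1.2), "icc")
  expect_error(compute_sem(0.001, k = 2, icc = -0.1), "icc")
  expect_error(compute_sem(-1, k = 2, icc = 0.5), "tss_within")
})

test_that("reliability bands use half-open intervals with boundaries rounding up", {
  expect_identical(classify_reliability(0.97), "excellent")
  expect_identical(classify_reliability(0.40), "poor")
  expect_identical(classify_reliability(-0.2), "poor")
  expect_identical(classify_reliability(c(0.50, 0.75, 0.90)),
                   c("moderate", "good", "excellent"))
  expect_identical(classify_reliability(c(0.4999, 0.7499, 0.8999)),
                   c("poor", "moderate", "good"))
  expect_error(classify_reliability(NaN), "finite")
})

test_that("fixture generator honours its shape, noise-free and seeding contracts", {
  m <- generate_retest_fixture(5, 3, 0.018, 0.006, 0.33, seed = 42)
  expect_identical(dim(m), c(5L, 3L))
  expect_identical(m, generate_retest_fixture(5, 3, 0.018, 0.006, 0.33, 42))
  noiseless <- generate_retest_fixture(6, 2, 0.018, 0, 0.33, seed = 1)
  expect_identical(compute_icc(noiseless)$icc, 1)
  expect_error(generate_retest_fixture(1, 2, 0.01, 0.01, 0.3, 1), "n_subj")
  expect_error(generate_retest_fixture(5, 2, -0.1, 0.01, 0.3, 1), "non-negative")
})

test_that("estimated ICC recovers the variance-component reliability", {
  # population reliability 0.018^2 / (0.018^2 + 0.006^2) = 0.9
  theo <- 0.018^2 / (0.018^2 + 0.006^2)
  big <- generate_retest_fixture(200, 2, 0.018, 0.006, 0.33, seed = 2024)
  r <- compute_icc(big)
  expect_gt(theo, r$ci_low)
  expect_lt(theo, r$ci_high)
  # mean estimate over independent fixtures converges on the identity
  iccs <- vapply(1:30, function(s) {
    compute_icc(generate_retest_fixture(120, 2, 0.018, 0.006, 0.33, s))$icc
  }, numeric(1))
  expect_lt(abs(mean(iccs) - theo), 0.01)
})

test_that("the packaged synthetic test-retest example analyses cleanly", {
  path <- system.file("extdata", "synthetic_retest_14x2.csv",
                      package = "dtipower")
  r <- compute_icc(read_retest_csv(path))
  expect_identical(r$n_subj, 14L)
  expect_identical(r$k, 2L)
  expect_equal(r$icc, oracle_icc_tables(read_retest_csv(path))$icc_agreement,
               tolerance = 1e-10)
  expect_identical(r$band, "excellent")
})

test_that("test-retest CSV round-trips through read and write", {
  m <- generate_retest_fixture(14, 2, 0.018, 0.006, 0.33, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_retest_csv(m, path)
  back <- read_retest_csv(path)
  expect_equal(unname(unclass(back)), unname(unclass(m)), tolerance = 1e-12)
  expect_equal(compute_icc(back)$icc, compute_icc(m)$icc, tolerance = 1e-10)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,a,b", "1,0.3,0.31"), bad)
  expect_error(read_retest_csv(bad), "subject")
})
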