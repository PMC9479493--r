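# Independent oracles used across the suite. Deliberately written in the
# dumbest possible style (explicit loops, textbook formulas) so they share
# no code path with the package implementation.

# Two-way ANOVA mean squares by direct summation, then the single-rater
# absolute-agreement ICC and, for comparison, the consistency-type ICC.
oracle_icc_tables <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  grand <- sum(x) / (n * k)
  ssr <- 0
  for (i in seq_len(n)) {
    ri <- sum(x[i, ]) / k
    ssr <- ssr + k * (ri - grand)^2
  }
  ssc <- 0
  for (j in seq_len(k)) {
    cj <- sum(x[, j]) / n
    ssc <- ssc + n * (cj - grand)^2
  }
  sst <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) sst <- sst + (x[i, j] - grand)^2
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  list(
    msr = msr, msc = msc, mse = mse,
    icc_agreement = (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)),
    icc_consistency = (msr - mse) / (msr + (k - 1) * mse)
  )
}

# Textbook pooled-variance two-sample t-test p-value.
oracle_pooled_t_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  ma <- sum(a) / na; mb <- sum(b) / nb
  ssa <- sum((a - ma)^2); ssb <- sum((b - mb)^2)
  s2p <- (ssa + ssb) / (na + nb - 2)
  tstat <- (ma - mb) / sqrt(s2p * (1 / na + 1 / nb))
  2 * stats::pt(-abs(tstat), na + nb - 2)
}

# Random complete test-retest matrix for property tests.
random_retest_matrix <- function(n_subj, k, between_sd = 0.02,
                                 error_sd = 0.008, grand_mean = 0.33) {
  truth <- stats::rnorm(n_subj, grand_mean, between_sd)
  retest_matrix(truth + matrix(stats::rnorm(n_subj * k, 0, error_sd),
                               nrow = n_subj))
}
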