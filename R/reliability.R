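#' Construct a test-retest matrix
#'
#' A complete test-retest design: one row per subject, one column per
#' measurement occasion, each cell a tract-averaged FA value (or any scalar
#' summary measured repeatedly under identical conditions).
#'
#' @param values Numeric matrix (or object coercible to one) with subjects in
#'   rows and measurement occasions in columns. At least 2 rows and 2 columns;
#'   all cells finite (missing cells are rejected, not imputed).
#' @return A numeric matrix of class `"retest_matrix"`.
#' @examples
#' retest_matrix(cbind(c(0.30, 0.32, 0.34), c(0.31, 0.33, 0.33)))
#' @export
retest_matrix <- function(values) {
  x <- as.matrix(values)
  if (!is.numeric(x)) {
    stop("test-retest values must be numeric", call. = FALSE)
  }
  storage.mode(x) <- "double"
  if (nrow(x) < 2L) {
    stop("a test-retest matrix needs at least 2 subjects (rows)", call. = FALSE)
  }
  if (ncol(x) < 2L) {
    stop("a test-retest matrix needs at least 2 measurement occasions (columns)",
         call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop("test-retest matrix contains missing or non-finite cells; ",
         "a complete design is required", call. = FALSE)
  }
  class(x) <- c("retest_matrix", class(x))
  x
}

#' Read a test-retest table from CSV
#'
#' Expects a header row `subject,meas_1,...,meas_k`, one row per subject,
#' decimal-point numbers, UTF-8.
#'
#' @param path Path to the CSV file.
#' @return A [retest_matrix()] with subject identifiers as row names.
#' @export
read_retest_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 3L || tolower(names(df)[1L]) != "subject") {
    stop("expected header 'subject,meas_1,...,meas_k' with k >= 2 in ", path,
         call. = FALSE)
  }
  meas <- names(df)[-1L]
  if (!all(grepl("^meas_[0-9]+$", meas))) {
    stop("measurement columns must be named meas_1, meas_2, ...; got: ",
         paste(meas, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(df[, -1L, drop = FALSE])
  rownames(x) <- as.character(df[[1L]])
  retest_matrix(x)
}

#' Write a test-retest table to CSV
#'
#' Inverse of [read_retest_csv()]: writes `subject,meas_1,...,meas_k`.
#'
#' @param matrix A [retest_matrix()].
#' @param path Output file path.
#' @export
write_retest_csv <- function(matrix, path) {
  x <- unclass(matrix)
  subj <- rownames(x)
  if (is.null(subj)) subj <- paste0("S", seq_len(nrow(x)))
  df <- data.frame(subject = subj, x, check.names = FALSE)
  names(df) <- c("subject", paste0("meas_", seq_len(ncol(x))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Intraclass correlation for test-retest reliability
#'
#' Single-rater, absolute-agreement ICC from the two-way mixed-effects model —
#' ICC(A,1) in the McGraw–Wong taxonomy — the specification appropriate when
#' the same scanner acquires every measurement and systematic shifts between
#' occasions should count against reliability. The confidence interval uses
#' the standard F-distribution approximation.
#'
#' Writing MSR, MSC and MSE for the between-subject, between-occasion and
#' residual mean squares of the two-way ANOVA with n subjects and k occasions,
#' \deqn{ICC(A,1) = \frac{MSR - MSE}{MSR + (k-1) MSE + \frac{k}{n}(MSC - MSE)}.}
#'
#' @param matrix A [retest_matrix()] (or coercible input).
#' @param confidence Confidence level for the interval, in (0, 1). Default 0.95.
#' @param sem_variant Interpretation of the SEM formula passed on to
#'   [compute_sem()]: `"sqrt"` (default) or `"literal"`.
#' @return An object of class `"icc_result"`: a list with `icc`, `ci_low`,
#'   `ci_high`, `confidence`, `n_subj`, `k`, `ms_between_subjects`,
#'   `ms_between_measurements`, `ms_error`, `tss_within`, `sem`, and the
#'   reliability `band` of the point estimate and of both CI bounds.
#' @examples
#' set.seed(1)
#' m <- generate_retest_fixture(n_subj = 14, k = 2, between_sd = 0.02,
#'                              error_sd = 0.004, grand_mean = 0.33, seed = 1)
#' compute_icc(m)
#' @export
compute_icc <- function(matrix, confidence = 0.95, sem_variant = c("sqrt", "literal")) {
  x <- if (inherits(matrix, "retest_matrix")) matrix else retest_matrix(matrix)
  sem_variant <- match.arg(sem_variant)
  if (!is.numeric(confidence) || length(confidence) != 1L ||
      confidence <= 0 || confidence >= 1) {
    stop("confidence must be a single number in (0, 1)", call. = FALSE)
  }
  n <- nrow(x)
  k <- ncol(x)

  grand <- mean(x)
  if (sum((x - grand)^2) == 0) {
    stop("degenerate test-retest matrix: all cells are identical, so total ",
         "variance is zero and the ICC is undefined", call. = FALSE)
  }
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ssr <- k * sum((row_means - grand)^2)            # between subjects
  ssc <- n * sum((col_means - grand)^2)            # between occasions
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  tss_within <- sum((x - row_means)^2)             # = ssc + sse

  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  alpha <- 1 - confidence
  if (abs(1 - icc) < 1e-12) {
    # zero within-subject variance: interval collapses to the point estimate
    ci <- c(icc, icc)
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, df1 = n - 1, df2 = v)
    f_u <- stats::qf(1 - alpha / 2, df1 = v, df2 = n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(min(lo, icc), max(hi, icc))
  }

  sem <- if (icc >= 0 && icc <= 1) {
    compute_sem(tss_within, k, icc, variant = sem_variant)
  } else {
    NA_real_
  }

  structure(
    list(
      icc = icc,
      ci_low = ci[1L],
      ci_high = ci[2L],
      confidence = confidence,
      n_subj = n,
      k = k,
      ms_between_subjects = msr,
      ms_between_measurements = msc,
      ms_error = mse,
      tss_within = tss_within,
      sem = sem,
      sem_variant = sem_variant,
      band = classify_reliability(icc),
      band_ci = c(low = classify_reliability(ci[1L]),
                  high = classify_reliability(ci[2L]))
    ),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("Test-retest reliability: ICC(A,1) = %.4f, %d%% CI [%.4f, %.4f]\n",
              x$icc, round(100 * x$confidence), x$ci_low, x$ci_high))
  cat(sprintf("  %d subjects, %d measurements each\n", x$n_subj, x$k))
  cat(sprintf("  band (point estimate): %s; band (CI): %s to %s\n",
              x$band, x$band_ci[["low"]], x$band_ci[["high"]]))
  cat(sprintf("  SEM (%s variant): %.6g\n", x$sem_variant, x$sem))
  invisible(x)
}

#' Standard error of measurement from ICC and within-subject sum of squares
#'
#' Converts a reliability estimate into the standard deviation of the
#' per-scan measurement error used by the trajectory simulation. The default
#' `"sqrt"` variant,
#' \deqn{SEM = \sqrt{\frac{TSS}{k-1} \cdot ICC \cdot (1 - ICC)},}
#' keeps the result in FA units (TSS is in squared FA units). The `"literal"`
#' variant returns the plain product \eqn{\frac{TSS}{k-1} \cdot ICC \cdot
#' (1-ICC)} without the radical; it is retained because the defining formula
#' can be read either way, but its units are squared and it is not the
#' default. Both variants vanish at ICC = 0 and ICC = 1.
#'
#' @param tss_within Total within-subject sum of squares (squared FA units),
#'   non-negative.
#' @param k Number of measurements per subject, at least 2.
#' @param icc Reliability estimate in \[0, 1\].
#' @param variant `"sqrt"` (default) or `"literal"`.
#' @return Non-negative scalar; FA units under `"sqrt"`.
#' @examples
#' compute_sem(0.001, k = 2, icc = 0.9)
#' @export
compute_sem <- function(tss_within, k, icc, variant = c("sqrt", "literal")) {
  variant <- match.arg(variant)
  if (!is.numeric(icc) || length(icc) != 1L || is.na(icc) || icc < 0 || icc > 1) {
    stop("icc must be a single value in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || k < 2) {
    stop("k must be a single count >= 2", call. = FALSE)
  }
  if (!is.numeric(tss_within) || length(tss_within) != 1L || tss_within < 0) {
    stop("tss_within must be a single non-negative value", call. = FALSE)
  }
  prod <- (tss_within / (k - 1)) * icc * (1 - icc)
  switch(variant, sqrt = sqrt(prod), literal = prod)
}

#' Classify an ICC value into a reliability band
#'
#' Bands follow the convention common in reliability reporting: poor below
#' 0.50, moderate in \[0.50, 0.75), good in \[0.75, 0.90), excellent at 0.90
#' and above. Intervals are half-open with boundary values assigned to the
#' higher band; negative ICC estimates are classified poor.
#'
#' @param icc Finite ICC value (vectorised).
#' @return Character vector with levels poor/moderate/good/excellent.
#' @examples
#' classify_reliability(c(0.4, 0.75, 0.97))
#' @export
classify_reliability <- function(icc) {
  if (any(!is.finite(icc))) {
    stop("icc must be finite", call. = FALSE)
  }
  bands <- c("poor", "moderate", "good", "excellent")
  bands[findInterval(icc, c(0.50, 0.75, 0.90)) + 1L]
}

#' Generate a synthetic test-retest data set
#'
#' Draws a complete subjects-by-occasions grid from the one-way random-effects
#' model: subject true values are Normal(`grand_mean`, `between_sd`) and each
#' cell adds independent Normal(0, `error_sd`) measurement error. The implied
#' population reliability is `between_sd^2 / (between_sd^2 + error_sd^2)`.
#' Serves as a synthetic stand-in for a real test-retest cohort when only its
#' variance components are known.
#'
#' @param n_subj Number of subjects (rows), at least 2.
#' @param k Measurements per subject (columns), at least 2.
#' @param between_sd Between-subject SD of true values (FA units), >= 0.
#' @param error_sd Per-measurement error SD (FA units), >= 0.
#' @param grand_mean Population mean (FA units).
#' @param seed Integer seed; the output is reproducible given the seed.
#' @return A [retest_matrix()] of dimension `n_subj` by `k`.
#' @examples
#' generate_retest_fixture(5, 3, 0.018, 0.006, 0.33, seed = 42)
#' @export
generate_retest_fixture <- function(n_subj, k, between_sd, error_sd, grand_mean,
                                    seed) {
  if (!is.numeric(n_subj) || length(n_subj) != 1L || n_subj < 2) {
    stop("n_subj must be a single count >= 2", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || k < 2) {
    stop("k must be a single count >= 2", call. = FALSE)
  }
  if (between_sd < 0 || error_sd < 0) {
    stop("between_sd and error_sd must be non-negative", call. = FALSE)
  }
  n_subj <- as.integer(n_subj)
  k <- as.integer(k)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  truth <- stats::rnorm(n_subj, grand_mean, between_sd)
  noise <- matrix(stats::rnorm(n_subj * k, 0, error_sd), nrow = n_subj)
  x <- truth + noise
  rownames(x) <- paste0("S", seq_len(n_subj))
  retest_matrix(x)
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
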