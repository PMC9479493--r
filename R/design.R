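#' Power curve over a range of sample sizes (common random numbers)
#'
#' Estimates power for every per-group sample size in `n_values` from one
#' simulation pass. Each Monte Carlo iteration draws a single cohort of
#' `max(n_values)` subjects per group and evaluates every smaller design on
#' the leading subset of that cohort, so all sample sizes share the same
#' random numbers: differences along the curve reflect the design, not
#' Monte Carlo noise. The per-n estimates are each unbiased and identical in
#' distribution to [estimate_power()] at that n.
#'
#' @param scenario A [scenario()]; its `n_per_group` is ignored.
#' @param n_values Integer vector of per-group sample sizes, all >= 2.
#' @return A data frame of class `"power_curve"` with columns `n_per_group`,
#'   `power`, `mc_se`.
#' @export
power_curve <- function(scenario, n_values) {
  stopifnot(inherits(scenario, "scenario"))
  n_values <- sort(unique(as.integer(n_values)))
  if (length(n_values) < 1L || any(n_values < 2L)) {
    stop("n_values must contain sample sizes >= 2", call. = FALSE)
  }
  n_max <- max(n_values)
  iters <- scenario$iterations
  alpha <- scenario$alpha
  no_decline <- decrease_model(0, 0, scenario$decrease$anchor_fa)
  df <- 2 * n_values - 2
  tcrit <- stats::qt(1 - alpha / 2, df)
  n_sig <- integer(length(n_values))

  old <- .save_rng()
  on.exit(.restore_rng(old))
  for (i in seq_len(iters)) {
    set.seed(.derive_seed(scenario$seed, i))
    pat <- .group_changes(.sim_group(n_max, scenario$patient_group,
                                     scenario$decrease, scenario$error,
                                     scenario$t_days, scenario$m))
    ctl <- .group_changes(.sim_group(n_max, scenario$control_group,
                                     no_decline, scenario$error,
                                     scenario$t_days, scenario$m))
    # prefix sums give pooled t statistics for every n at once
    ca <- cumsum(pat)[n_values];  ca2 <- cumsum(pat^2)[n_values]
    cb <- cumsum(ctl)[n_values];  cb2 <- cumsum(ctl^2)[n_values]
    ssa <- ca2 - ca^2 / n_values
    ssb <- cb2 - cb^2 / n_values
    s2p <- (ssa + ssb) / df
    tstat <- (ca / n_values - cb / n_values) / sqrt(s2p * 2 / n_values)
    n_sig <- n_sig + (abs(tstat) > tcrit)
  }
  power <- n_sig / iters
  structure(
    data.frame(n_per_group = n_values,
               power = power,
               mc_se = sqrt(power * (1 - power) / iters)),
    class = c("power_curve", "data.frame")
  )
}

#' Minimal per-group sample size for a target power
#'
#' Evaluates the power curve on an integer grid of sample sizes with common
#' random numbers, smooths it with isotonic (monotone non-decreasing)
#' regression to absorb residual Monte Carlo jitter, and returns the
#' smallest n whose smoothed power reaches the target. If no n in the search
#' range qualifies, the result says so explicitly (`reached = FALSE`,
#' `n = NA`) rather than clamping to the bound.
#'
#' @param scenario A [scenario()]; its `n_per_group` is ignored.
#' @param power_target Target power, in (0, 1). Default 0.8.
#' @param n_min,n_max Search bounds (step 1), `2 <= n_min <= n_max`.
#' @return Object of class `"sample_size_result"`: list with `n`, `reached`,
#'   `power_target`, `power_at_n`, `curve` (data frame `n_per_group`,
#'   `power`, `power_smoothed`, `mc_se`) and `seed`.
#' @examples
#' sc <- scenario(rate_percent = 3.5, sem = 0.00134, t_days = 90, m = 1,
#'                iterations = 500, seed = 1)
#' min_sample_size(sc, n_max = 30)
#' @export
min_sample_size <- function(scenario, power_target = 0.8,
                            n_min = 3L, n_max = 100L) {
  stopifnot(inherits(scenario, "scenario"))
  if (!is.numeric(power_target) || power_target <= 0 || power_target >= 1) {
    stop("power_target must lie strictly between 0 and 1", call. = FALSE)
  }
  n_min <- as.integer(n_min); n_max <- as.integer(n_max)
  if (n_min < 2L || n_min > n_max) {
    stop("need 2 <= n_min <= n_max", call. = FALSE)
  }
  grid <- n_min:n_max
  curve <- power_curve(scenario, grid)
  smoothed <- stats::isoreg(curve$n_per_group, curve$power)$yf
  curve$power_smoothed <- smoothed
  curve <- curve[, c("n_per_group", "power", "power_smoothed", "mc_se")]
  hit <- which(smoothed >= power_target)
  reached <- length(hit) > 0L
  structure(
    list(n = if (reached) grid[hit[1L]] else NA_integer_,
         reached = reached,
         power_target = power_target,
         power_at_n = if (reached) smoothed[hit[1L]] else NA_real_,
         curve = curve,
         seed = scenario$seed),
    class = "sample_size_result"
  )
}

#' @export
print.sample_size_result <- function(x, ...) {
  if (x$reached) {
    cat(sprintf("Minimal sample size: n = %d per group reaches power %.3f (target %.2f)\n",
                x$n, x$power_at_n, x$power_target))
  } else {
    cat(sprintf("Target power %.2f not reached for any n in %d..%d\n",
                x$power_target, min(x$curve$n_per_group),
                max(x$curve$n_per_group)))
  }
  invisible(x)
}

#' Sample-size saving from additional scans per session
#'
#' Quantifies the repeated-scan trade-off: the relative reduction in the
#' minimal per-group sample size needed for the target power when the number
#' of scans per session changes from `m_from` to `m_to`, i.e.
#' `100 * (n_min(m_from) - n_min(m_to)) / n_min(m_from)` percent.
#'
#' @param scenario A [scenario()]; its `m` and `n_per_group` are ignored.
#' @param m_from,m_to Scans per session in the two designs (`m_from != m_to`).
#' @param power_target,n_min,n_max Passed to [min_sample_size()].
#' @return Object of class `"scan_tradeoff"`: list with `reduction_percent`
#'   (NA if either search did not reach the target), `computable`, `n_from`,
#'   `n_to`, `m_from`, `m_to` and both `"sample_size_result"` objects.
#' @export
sample_size_reduction <- function(scenario, m_from = 1L, m_to = 2L,
                                  power_target = 0.8, n_min = 3L,
                                  n_max = 100L) {
  stopifnot(inherits(scenario, "scenario"))
  m_from <- as.integer(m_from); m_to <- as.integer(m_to)
  if (m_from == m_to) stop("m_from and m_to must differ", call. = FALSE)
  with_m <- function(m) {
    s <- scenario; s$m <- m; class(s) <- "scenario"; s
  }
  res_from <- min_sample_size(with_m(m_from), power_target, n_min, n_max)
  res_to <- min_sample_size(with_m(m_to), power_target, n_min, n_max)
  computable <- res_from$reached && res_to$reached
  structure(
    list(reduction_percent = if (computable) {
           100 * (res_from$n - res_to$n) / res_from$n
         } else NA_real_,
         computable = computable,
         n_from = res_from$n,
         n_to = res_to$n,
         m_from = m_from,
         m_to = m_to,
         result_from = res_from,
         result_to = res_to),
    class = "scan_tradeoff"
  )
}

#' @export
print.scan_tradeoff <- function(x, ...) {
  if (x$computable) {
    cat(sprintf("Moving from %d to %d scan(s)/session: required n %d -> %d (%.1f%% reduction)\n",
                x$m_from, x$m_to, x$n_from, x$n_to, x$reduction_percent))
  } else {
    cat(sprintf("Not computable: target power not reached at m = %d and/or m = %d within the search range\n",
                x$m_from, x$m_to))
  }
  invisible(x)
}

#' Power over a grid of scenario settings
#'
#' Runs [estimate_power()] for every cell of the Cartesian product of the
#' supplied decline rates, measurement uncertainties, follow-up intervals,
#' scans per session and sample sizes — the tabular counterpart of the usual
#' power-versus-design figure panels. Each cell runs on its own seed derived
#' deterministically from the master seed, so the grid is exactly
#' reproducible and independent of evaluation order.
#'
#' @param rates Annual FA decrease rates, percent per year.
#' @param sems Per-scan SEM values (FA units).
#' @param t_days_values Follow-up intervals in days.
#' @param m_values Scans per session.
#' @param n_values Per-group sample sizes.
#' @param patient_group,control_group [group_distribution()]s.
#' @param cv_percent Between-subject CV of the decrease rate, percent.
#' @param alpha Significance level.
#' @param iterations Monte Carlo iterations per cell.
#' @param seed Master seed for the whole grid.
#' @return Data frame of class `"power_grid"` with one row per cell and
#'   columns `rate_percent`, `sem`, `t_days`, `m`, `n_per_group`, `power`,
#'   `mc_se`, `seed`.
#' @examples
#' power_grid(rates = c(2, 3.5), sems = 0.00134, t_days_values = 90,
#'            m_values = 1, n_values = 12, iterations = 200, seed = 1)
#' @export
power_grid <- function(rates, sems, t_days_values, m_values, n_values,
                       patient_group = group_distribution(0.326, 0.018),
                       control_group = group_distribution(0.339, 0.023),
                       cv_percent = 67, alpha = 0.05, iterations = 2000L,
                       seed = 101L) {
  dims <- list(rates = rates, sems = sems, t_days_values = t_days_values,
               m_values = m_values, n_values = n_values)
  empty <- vapply(dims, length, 1L) == 0L
  if (any(empty)) {
    stop("empty grid dimension(s): ", paste(names(dims)[empty], collapse = ", "),
         call. = FALSE)
  }
  cells <- expand.grid(n_per_group = sort(unique(as.integer(n_values))),
                       m = sort(unique(as.integer(m_values))),
                       t_days = sort(unique(t_days_values)),
                       sem = sort(unique(sems)),
                       rate_percent = sort(unique(rates)),
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[, c("rate_percent", "sem", "t_days", "m", "n_per_group")]
  out <- cells
  out$power <- NA_real_
  out$mc_se <- NA_real_
  out$seed <- NA_integer_
  for (i in seq_len(nrow(cells))) {
    cell_seed <- .derive_seed(seed, i)
    sc <- scenario(patient_group = patient_group,
                   control_group = control_group,
                   rate_percent = cells$rate_percent[i],
                   cv_percent = cv_percent,
                   sem = cells$sem[i],
                   t_days = cells$t_days[i],
                   m = cells$m[i],
                   n_per_group = cells$n_per_group[i],
                   alpha = alpha,
                   iterations = iterations,
                   seed = cell_seed)
    est <- estimate_power(sc)
    out$power[i] <- est$power
    out$mc_se[i] <- est$mc_standard_error
    out$seed[i] <- cell_seed
  }
  rownames(out) <- NULL
  class(out) <- c("power_grid", "data.frame")
  out
}
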