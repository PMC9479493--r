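#' Define a simulated two-group longitudinal study scenario
#'
#' Bundles every input of one Monte Carlo power calculation: the two groups'
#' baseline FA distributions, the patients' annual decline model, the
#' per-scan measurement error, the follow-up interval, scans per session,
#' per-group sample size, significance level, iteration count and master
#' seed. The patient decline percentage is anchored at the patient group
#' mean FA unless a `decrease_model` is supplied directly.
#'
#' @param patient_group [group_distribution()] of the patient group.
#' @param control_group [group_distribution()] of the control group
#'   (simulated with zero decline).
#' @param rate_percent Mean annual FA decrease of patients, percent per year.
#' @param cv_percent Between-subject CV of the decrease rate, percent.
#' @param sem Per-scan measurement error SD (FA units).
#' @param t_days Days between baseline and follow-up session. Values outside
#'   30–180 days are allowed with a warning (the typical range in
#'   longitudinal imaging studies).
#' @param m Scans per session, >= 1.
#' @param n_per_group Subjects per group, >= 2.
#' @param alpha Two-sided significance level, in (0, 1).
#' @param iterations Monte Carlo iterations, >= 1.
#' @param seed Master seed (integer); every random draw of the scenario is a
#'   deterministic function of it.
#' @param decrease Optional [decrease_model()] overriding
#'   `rate_percent`/`cv_percent` (use for subject-anchored decline).
#' @return An object of class `"scenario"`.
#' @examples
#' scenario(rate_percent = 2, sem = 0.00054, t_days = 30, m = 2,
#'          n_per_group = 20, seed = 1)
#' @export
scenario <- function(patient_group = group_distribution(0.326, 0.018),
                     control_group = group_distribution(0.339, 0.023),
                     rate_percent = 2.0,
                     cv_percent = 67,
                     sem = 0.00054,
                     t_days = 90,
                     m = 1L,
                     n_per_group = 20L,
                     alpha = 0.05,
                     iterations = 2000L,
                     seed = 101L,
                     decrease = NULL) {
  stopifnot(inherits(patient_group, "group_distribution"),
            inherits(control_group, "group_distribution"))
  if (is.null(decrease)) {
    decrease <- decrease_model(rate_percent, cv_percent,
                               anchor_fa = patient_group$mean_fa)
  }
  stopifnot(inherits(decrease, "decrease_model"))
  if (!is.numeric(n_per_group) || n_per_group < 2) {
    stop("n_per_group must be at least 2", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.numeric(iterations) || iterations < 1) {
    stop("iterations must be at least 1", call. = FALSE)
  }
  if (!is.numeric(m) || m < 1) {
    stop("m (scans per session) must be at least 1", call. = FALSE)
  }
  if (!is.numeric(t_days) || length(t_days) != 1L || t_days <= 0) {
    stop("t_days must be a single positive number", call. = FALSE)
  }
  if (t_days < 30 || t_days > 180) {
    warning("t_days = ", t_days, " is outside the 30-180 day range typical ",
            "of longitudinal DTI studies", call. = FALSE)
  }
  structure(
    list(patient_group = patient_group,
         control_group = control_group,
         decrease = decrease,
         error = error_model(sem),
         t_days = t_days,
         m = as.integer(m),
         n_per_group = as.integer(n_per_group),
         alpha = alpha,
         iterations = as.integer(iterations),
         seed = as.integer(seed)),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat("Two-group longitudinal FA study scenario\n")
  cat(sprintf("  patients:  FA ~ N(%.3f, %.3f), decline %.2f %%/yr (CV %.0f%%, %s-anchored)\n",
              x$patient_group$mean_fa, x$patient_group$sd_fa,
              x$decrease$annual_rate_percent, x$decrease$cv_percent,
              x$decrease$anchor))
  cat(sprintf("  controls:  FA ~ N(%.3f, %.3f), no decline\n",
              x$control_group$mean_fa, x$control_group$sd_fa))
  cat(sprintf("  per-scan SEM %.5f | follow-up at %g d | %d scan(s)/session\n",
              x$error$sem, x$t_days, x$m))
  cat(sprintf("  n = %d/group | alpha = %g | %d iterations | seed %d\n",
              x$n_per_group, x$alpha, x$iterations, x$seed))
  invisible(x)
}

#' Two-sided independent-samples t-test p-value
#'
#' Pooled-variance (Student) two-sample t-test by default, the conventional
#' choice for equal group sizes; `welch = TRUE` switches to the Welch
#' unequal-variance test.
#'
#' @param changes_a,changes_b Numeric vectors of per-subject change scores,
#'   each of length >= 2.
#' @param welch Use Welch's test instead of the pooled test.
#' @return Two-sided p-value.
#' @examples
#' two_sample_t(c(0.1, 0.2, 0.3, 0.4), c(0.3, 0.4, 0.5, 0.6))
#' @export
two_sample_t <- function(changes_a, changes_b, welch = FALSE) {
  if (length(changes_a) < 2L || length(changes_b) < 2L) {
    stop("each group needs at least 2 change scores", call. = FALSE)
  }
  if (stats::var(changes_a) == 0 && stats::var(changes_b) == 0) {
    stop("degenerate input: both groups have zero variance, ",
         "the t statistic is undefined", call. = FALSE)
  }
  stats::t.test(changes_a, changes_b, var.equal = !welch)$p.value
}

# Derive a substream seed (< 2^31) from a master seed and an index; doubles
# stay exact well below 2^53 here.
.derive_seed <- function(master, index) {
  as.integer((abs(as.double(master)) * 69069 + as.double(index) * 104729) %%
               2147483629)
}

#' Run one Monte Carlo iteration of a scenario
#'
#' Draws one synthetic cohort (patients with decline, controls without) from
#' the current RNG stream, observes baseline and follow-up sessions with `m`
#' scans each, computes per-subject change scores and returns the two-sided
#' group-comparison p-value. Seed management is the caller's job (see
#' [estimate_power()]); repeated calls from the same RNG state give the same
#' p-value.
#'
#' @param scenario A [scenario()].
#' @param welch Use Welch's t-test instead of the pooled test.
#' @return Two-sided p-value of the group comparison.
#' @export
run_iteration <- function(scenario, welch = FALSE) {
  stopifnot(inherits(scenario, "scenario"))
  no_decline <- decrease_model(0, 0, scenario$decrease$anchor_fa)
  pat <- .sim_group(scenario$n_per_group, scenario$patient_group,
                    scenario$decrease, scenario$error, scenario$t_days,
                    scenario$m)
  ctl <- .sim_group(scenario$n_per_group, scenario$control_group,
                    no_decline, scenario$error, scenario$t_days, scenario$m)
  two_sample_t(.group_changes(pat), .group_changes(ctl), welch = welch)
}

#' Simulate one full synthetic cohort as a long table
#'
#' Diagnostic view of a single iteration: every simulated scan of every
#' subject of both groups, one row per scan.
#'
#' @param scenario A [scenario()].
#' @return Data frame with columns `group` ("patient"/"control"), `subject`,
#'   `session` ("baseline"/"followup"), `t_days`, `scan_index`, `fa_value`.
#' @export
simulate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(.derive_seed(scenario$seed, 1L))
  no_decline <- decrease_model(0, 0, scenario$decrease$anchor_fa)
  sims <- list(
    patient = .sim_group(scenario$n_per_group, scenario$patient_group,
                         scenario$decrease, scenario$error, scenario$t_days,
                         scenario$m),
    control = .sim_group(scenario$n_per_group, scenario$control_group,
                         no_decline, scenario$error, scenario$t_days,
                         scenario$m)
  )
  n <- scenario$n_per_group
  m <- scenario$m
  one_session <- function(group, scans, session, t_days) {
    data.frame(group = group,
               subject = rep(seq_len(n), times = m),
               session = session,
               t_days = t_days,
               scan_index = rep(seq_len(m), each = n),
               fa_value = as.vector(scans))
  }
  out <- rbind(
    one_session("patient", sims$patient$scans_bl, "baseline", 0),
    one_session("patient", sims$patient$scans_fu, "followup", scenario$t_days),
    one_session("control", sims$control$scans_bl, "baseline", 0),
    one_session("control", sims$control$scans_fu, "followup", scenario$t_days)
  )
  out[order(out$group, out$subject, out$session, out$scan_index), ,
      drop = FALSE]
}

#' Estimate statistical power by Monte Carlo simulation
#'
#' Runs the scenario's full simulation pipeline `iterations` times — each
#' iteration draws fresh patient and control cohorts, simulates both
#' sessions, and tests the group difference in FA change — and estimates
#' power as the proportion of iterations with p strictly below `alpha`.
#' Each iteration runs on its own RNG substream derived from the master
#' seed, so the estimate does not depend on how iterations are scheduled.
#'
#' @param scenario A [scenario()].
#' @param welch Use Welch's t-test instead of the pooled test.
#' @return An object of class `"power_estimate"`: list with `power`,
#'   `n_significant`, `iterations`, `mc_standard_error`
#'   (binomial SE `sqrt(power (1-power) / iterations)`), `alpha`, `seed`,
#'   and the `scenario`.
#' @examples
#' sc <- scenario(rate_percent = 3.5, sem = 0.00134, t_days = 90, m = 1,
#'                n_per_group = 12, iterations = 200, seed = 1)
#' estimate_power(sc)
#' @export
estimate_power <- function(scenario, welch = FALSE) {
  stopifnot(inherits(scenario, "scenario"))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  n_sig <- 0L
  for (i in seq_len(scenario$iterations)) {
    set.seed(.derive_seed(scenario$seed, i))
    p <- run_iteration(scenario, welch = welch)
    if (p < scenario$alpha) n_sig <- n_sig + 1L
  }
  power <- n_sig / scenario$iterations
  structure(
    list(power = power,
         n_significant = n_sig,
         iterations = scenario$iterations,
         mc_standard_error = sqrt(power * (1 - power) / scenario$iterations),
         alpha = scenario$alpha,
         seed = scenario$seed,
         scenario = scenario),
    class = "power_estimate"
  )
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("Monte Carlo power estimate: %.3f (%d/%d significant, MC SE %.4f)\n",
              x$power, x$n_significant, x$iterations, x$mc_standard_error))
  cat(sprintf("  alpha = %g, seed = %d\n", x$alpha, x$seed))
  invisible(x)
}

#' Closed-form approximate power (noncentral-t oracle)
#'
#' Independent analytic check on the Monte Carlo engine. The per-subject
#' change score is normal in each group: patients have mean
#' \eqn{\mu_\beta t/365} and variance
#' \eqn{\sigma_\beta^2 (t/365)^2 + 2\,SEM^2/m}; controls have mean 0 and
#' variance \eqn{2\,SEM^2/m}. Approximate power of the two-sided pooled
#' t-test is then the tail mass of a noncentral t distribution with
#' noncentrality \eqn{\delta / \sqrt{(v_{pat}+v_{ctl})/n}} and
#' \eqn{2n-2} degrees of freedom. Exact when the group variances are equal;
#' a close approximation otherwise (equal group sizes).
#'
#' @param scenario A [scenario()].
#' @return Approximate power in \[0, 1\]; equals `alpha` when the effect is
#'   null and 1 in the zero-variance limit with a non-null effect.
#' @export
analytic_power_oracle <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  p <- .slope_params(scenario$decrease)
  t_yr <- scenario$t_days / DAYS_PER_YEAR
  delta <- abs(p$mu) * t_yr
  sem <- scenario$error$sem
  v_pat <- (p$sigma * t_yr)^2 + 2 * sem^2 / scenario$m
  v_ctl <- 2 * sem^2 / scenario$m
  if (delta == 0) {
    return(scenario$alpha)
  }
  if (v_pat + v_ctl == 0) {
    return(1)
  }
  n <- scenario$n_per_group
  df <- 2 * n - 2
  ncp <- delta / sqrt((v_pat + v_ctl) / n)
  tcrit <- stats::qt(1 - scenario$alpha / 2, df)
  (1 - stats::pt(tcrit, df, ncp)) + stats::pt(-tcrit, df, ncp)
}
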