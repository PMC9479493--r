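#' Group-level baseline FA distribution
#'
#' Mean and standard deviation of tract-averaged baseline FA in one study
#' group; baseline values of simulated subjects are drawn from this normal
#' law.
#'
#' @param mean_fa Group mean FA, in (0, 1).
#' @param sd_fa Between-subject SD of FA, > 0.
#' @return An object of class `"group_distribution"`.
#' @examples
#' group_distribution(0.326, 0.018)  # ALS patient group
#' group_distribution(0.339, 0.023)  # healthy control group
#' @export
group_distribution <- function(mean_fa, sd_fa) {
  stopifnot(is.numeric(mean_fa), length(mean_fa) == 1L,
            is.numeric(sd_fa), length(sd_fa) == 1L)
  if (!(mean_fa > 0 && mean_fa < 1)) {
    stop("mean_fa must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!(sd_fa > 0)) {
    stop("sd_fa must be positive", call. = FALSE)
  }
  structure(list(mean_fa = mean_fa, sd_fa = sd_fa),
            class = "group_distribution")
}

#' Annual FA decline model
#'
#' Parameterises the subject-specific linear FA decline as a percentage of a
#' baseline anchor per year. A subject's slope is drawn from a normal law
#' with mean \eqn{\mu_\beta = -(rate/100) \cdot anchor} FA units per year and
#' SD \eqn{\sigma_\beta = (cv/100) \cdot |\mu_\beta|}. A rate of 0 encodes no
#' decline: every subject gets slope exactly 0 with no variability (the
#' healthy-control case).
#'
#' The percentage is anchored at a group-level FA (`anchor_fa`, typically the
#' patient group mean) so that the slope distribution is a single group-level
#' normal law; setting `anchor = "subject"` instead scales each subject's
#' slope by their own true baseline.
#'
#' @param annual_rate_percent Mean annual FA decrease in percent per year,
#'   >= 0.
#' @param cv_percent Between-subject coefficient of variation of the decrease
#'   rate, in percent, >= 0.
#' @param anchor_fa Baseline FA level the percentage applies to (FA units).
#' @param anchor `"group"` (default) or `"subject"`.
#' @return An object of class `"decrease_model"`.
#' @examples
#' decrease_model(2.0, 67, 0.326)
#' @export
decrease_model <- function(annual_rate_percent, cv_percent = 67,
                           anchor_fa = 0.326, anchor = c("group", "subject")) {
  anchor <- match.arg(anchor)
  stopifnot(is.numeric(annual_rate_percent), length(annual_rate_percent) == 1L,
            is.numeric(cv_percent), length(cv_percent) == 1L,
            is.numeric(anchor_fa), length(anchor_fa) == 1L)
  if (annual_rate_percent < 0) {
    stop("annual_rate_percent must be >= 0 (0 encodes no decline)",
         call. = FALSE)
  }
  if (cv_percent < 0) {
    stop("cv_percent must be >= 0", call. = FALSE)
  }
  structure(list(annual_rate_percent = annual_rate_percent,
                 cv_percent = cv_percent,
                 anchor_fa = anchor_fa,
                 anchor = anchor),
            class = "decrease_model")
}

#' Per-scan measurement error model
#'
#' The per-scan measurement error is Normal(0, `sem`), with `sem` the
#' standard error of measurement estimated from test-retest data (see
#' [compute_icc()] and [compute_sem()]).
#'
#' @param sem Standard deviation of per-scan error (FA units), >= 0.
#' @return An object of class `"error_model"`.
#' @examples
#' error_model(0.00054)  # low measurement uncertainty
#' error_model(0.00134)  # high measurement uncertainty
#' @export
error_model <- function(sem) {
  stopifnot(is.numeric(sem), length(sem) == 1L)
  if (sem < 0) stop("sem must be >= 0", call. = FALSE)
  structure(list(sem = sem), class = "error_model")
}

# Calendar-year conversion used throughout (days per year).
DAYS_PER_YEAR <- 365

.slope_params <- function(decrease) {
  mu <- -(decrease$annual_rate_percent / 100) * decrease$anchor_fa
  sigma <- (decrease$cv_percent / 100) * abs(mu)
  list(mu = mu, sigma = sigma)
}

#' Draw synthetic subjects
#'
#' Draws `n` subjects' true baseline FA values from the group distribution
#' and their true annual slopes from the decline model. With a decline rate
#' of 0 the slope is exactly 0 for every subject (no random draw is
#' consumed for slopes in that case).
#'
#' @param group A [group_distribution()].
#' @param decrease A [decrease_model()].
#' @param n Number of subjects to draw.
#' @return A data frame with columns `true_baseline_fa` (FA units) and
#'   `slope` (FA units per year, negative for decline).
#' @examples
#' set.seed(7)
#' draw_subject(group_distribution(0.326, 0.018), decrease_model(2, 67, 0.326))
#' @export
draw_subject <- function(group, decrease, n = 1L) {
  stopifnot(inherits(group, "group_distribution"),
            inherits(decrease, "decrease_model"),
            n >= 1)
  n <- as.integer(n)
  baseline <- stats::rnorm(n, group$mean_fa, group$sd_fa)
  if (decrease$annual_rate_percent == 0) {
    slope <- rep(0, n)
  } else {
    p <- .slope_params(decrease)
    slope <- stats::rnorm(n, p$mu, p$sigma)
    if (decrease$anchor == "subject") {
      slope <- slope * baseline / decrease$anchor_fa
    }
  }
  data.frame(true_baseline_fa = baseline, slope = slope)
}

#' Observe one scanning session
#'
#' Evaluates a subject's true FA at `t_days` after baseline on the linear
#' trajectory and simulates `m` repeated scans, each with independent
#' Normal(0, sem) measurement error.
#'
#' @param subject One subject: a list or one-row data frame with
#'   `true_baseline_fa` and `slope`.
#' @param t_days Days since the baseline session, >= 0.
#' @param m Number of scans acquired at this session, >= 1.
#' @param error An [error_model()].
#' @return A list of class `"session_observation"` with `t_days` and `scans`
#'   (numeric vector of length `m`).
#' @examples
#' set.seed(7)
#' s <- draw_subject(group_distribution(0.326, 0.018), decrease_model(2))
#' observe_session(s, t_days = 90, m = 2, error = error_model(0.00134))
#' @export
observe_session <- function(subject, t_days, m, error) {
  stopifnot(inherits(error, "error_model"))
  if (!is.numeric(t_days) || length(t_days) != 1L || t_days < 0) {
    stop("t_days must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(m) || length(m) != 1L || m < 1) {
    stop("m (scans per session) must be at least 1", call. = FALSE)
  }
  m <- as.integer(m)
  truth <- subject$true_baseline_fa[1L] +
    subject$slope[1L] * t_days / DAYS_PER_YEAR
  scans <- truth + stats::rnorm(m, 0, error$sem)
  structure(list(t_days = t_days, scans = scans),
            class = "session_observation")
}

#' Session mean FA
#'
#' Arithmetic mean of the repeated scans of one session; averaging `m` scans
#' reduces the measurement-error variance by a factor of `m`.
#'
#' @param obs A `"session_observation"` (or any list with a `scans` vector).
#' @return Scalar FA value.
#' @export
session_mean <- function(obs) {
  if (length(obs$scans) < 1L) {
    stop("session has no scans", call. = FALSE)
  }
  mean(obs$scans)
}

#' Per-subject longitudinal FA change
#'
#' Change score entering the group comparison: follow-up session mean minus
#' baseline session mean. The baseline session must be at day 0 and the
#' follow-up strictly after it.
#'
#' @param baseline Baseline `"session_observation"` (`t_days` must be 0).
#' @param followup Follow-up `"session_observation"` (`t_days` > 0).
#' @return Scalar FA change (negative for decline).
#' @export
subject_change <- function(baseline, followup) {
  if (baseline$t_days != 0) {
    stop("baseline session must be at t_days = 0", call. = FALSE)
  }
  if (followup$t_days <= baseline$t_days) {
    stop("follow-up session must be after the baseline session", call. = FALSE)
  }
  session_mean(followup) - session_mean(baseline)
}

# Vectorised cohort simulation for one group: draws n subjects and both
# sessions' per-scan errors from the current RNG stream. Draw order (fixed,
# part of the reproducibility contract): baselines, slopes (if rate > 0),
# baseline-session errors, follow-up-session errors.
.sim_group <- function(n, group, decrease, error, t_days, m) {
  subj <- draw_subject(group, decrease, n)
  eps_bl <- matrix(stats::rnorm(n * m, 0, error$sem), nrow = n)
  eps_fu <- matrix(stats::rnorm(n * m, 0, error$sem), nrow = n)
  true_fu <- subj$true_baseline_fa + subj$slope * t_days / DAYS_PER_YEAR
  list(subjects = subj,
       scans_bl = subj$true_baseline_fa + eps_bl,
       scans_fu = true_fu + eps_fu)
}

.group_changes <- function(sim) {
  rowMeans(sim$scans_fu) - rowMeans(sim$scans_bl)
}
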