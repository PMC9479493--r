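#' Packaged default study parameters
#'
#' The parameter set used throughout the package's examples and defaults:
#' tract-averaged corticospinal-tract FA descriptives for an 80-patient ALS
#' group and a 50-subject healthy control group, the two measurement
#' uncertainty levels estimated from 14-subject test-retest data under two
#' acquisition protocols, the three studied annual decline rates, and the
#' standard design settings. Each value carries a provenance note describing
#' what it summarises.
#'
#' @return A list with elements `patient_mean`, `patient_sd`, `control_mean`,
#'   `control_sd`, `sem_low`, `sem_high`, `rates`, `cv_percent`, `alpha`,
#'   `iterations`, `t_days_options`, `m_options`, `provenance` (named
#'   character vector).
#' @examples
#' fa_defaults()$sem_low
#' @export
fa_defaults <- function() {
  list(
    patient_mean = 0.326,
    patient_sd = 0.018,
    control_mean = 0.339,
    control_sd = 0.023,
    sem_low = 0.00054,
    sem_high = 0.00134,
    rates = c(0.5, 2.0, 3.5),
    cv_percent = 67,
    alpha = 0.05,
    iterations = 2000L,
    t_days_options = c(30, 60, 90, 120, 180),
    m_options = 1:3,
    provenance = c(
      patient_mean = "mean CST FA of 80 patients with ALS (3T)",
      patient_sd = "between-subject SD of CST FA, ALS group",
      control_mean = "mean CST FA of 50 healthy controls (3T)",
      control_sd = "between-subject SD of CST FA, control group",
      sem_low = "SEM of CST FA, 62-direction 1.5T protocol (ICC 0.97)",
      sem_high = "SEM of CST FA, 52-direction 1.5T protocol (ICC 0.91)",
      rates = "slow / intermediate / fast annual FA decline in ALS, %/yr",
      cv_percent = "between-subject CV of the annual decline rate",
      alpha = "two-sided significance level of the group comparison",
      iterations = "Monte Carlo iterations per power estimate",
      t_days_options = "studied baseline-to-follow-up intervals, days",
      m_options = "studied scans-per-session counts"
    )
  )
}

# scalar scenario config schema: key -> validator
.scenario_schema <- function() {
  pos <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
  nneg <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0
  count <- function(lo) function(x) {
    is.numeric(x) && length(x) == 1L && is.finite(x) && x >= lo && x == round(x)
  }
  list(
    patient_mean = function(x) pos(x) && x < 1,
    patient_sd = pos,
    control_mean = function(x) pos(x) && x < 1,
    control_sd = pos,
    rate_percent = nneg,
    cv_percent = nneg,
    sem = nneg,
    t_days = pos,
    m = count(1),
    n_per_group = count(2),
    alpha = function(x) is.numeric(x) && length(x) == 1L && x > 0 && x < 1,
    iterations = count(1),
    seed = function(x) is.numeric(x) && length(x) == 1L && x == round(x)
  )
}

.default_scenario_config <- function() {
  d <- fa_defaults()
  list(patient_mean = d$patient_mean, patient_sd = d$patient_sd,
       control_mean = d$control_mean, control_sd = d$control_sd,
       rate_percent = 2.0, cv_percent = d$cv_percent, sem = d$sem_low,
       t_days = 90, m = 1L, n_per_group = 20L, alpha = d$alpha,
       iterations = d$iterations, seed = 101L)
}

#' Load and validate a scenario configuration
#'
#' Reads a YAML key-value document describing a [scenario()], applies
#' programmatic overrides (command-line flags win over file values, file
#' values win over defaults), validates every key against the schema, and
#' returns the resolved scenario. Unknown keys are rejected by name, as are
#' values violating a field's invariant. With no file and no overrides the
#' result is the package default scenario (intermediate 2.0 %/yr decline,
#' low measurement uncertainty, 90-day interval, one scan per session,
#' n = 20 per group).
#'
#' Recognised keys: `patient_mean`, `patient_sd`, `control_mean`,
#' `control_sd`, `rate_percent`, `cv_percent`, `sem`, `t_days`, `m`,
#' `n_per_group`, `alpha`, `iterations`, `seed`.
#'
#' @param path Path to a YAML config file, or `NULL` for defaults only.
#' @param overrides Named list of keys overriding the file.
#' @return A resolved [scenario()].
#' @examples
#' load_config(overrides = list(rate_percent = 3.5, n_per_group = 12))
#' @export
load_config <- function(path = NULL, overrides = list()) {
  schema <- .scenario_schema()
  cfg <- .default_scenario_config()
  apply_layer <- function(cfg, layer, origin) {
    if (length(layer) == 0L) return(cfg)
    if (is.null(names(layer)) || any(names(layer) == "")) {
      stop("all ", origin, " entries must be named", call. = FALSE)
    }
    unknown <- setdiff(names(layer), names(schema))
    if (length(unknown) > 0L) {
      stop("unknown ", origin, " key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    for (key in names(layer)) {
      val <- layer[[key]]
      if (!schema[[key]](val)) {
        stop("invalid value for '", key, "': ", deparse(val), call. = FALSE)
      }
      cfg[[key]] <- val
    }
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    cfg <- apply_layer(cfg, yaml::read_yaml(path), "config")
  }
  cfg <- apply_layer(cfg, overrides, "override")
  scenario(
    patient_group = group_distribution(cfg$patient_mean, cfg$patient_sd),
    control_group = group_distribution(cfg$control_mean, cfg$control_sd),
    rate_percent = cfg$rate_percent,
    cv_percent = cfg$cv_percent,
    sem = cfg$sem,
    t_days = cfg$t_days,
    m = cfg$m,
    n_per_group = cfg$n_per_group,
    alpha = cfg$alpha,
    iterations = cfg$iterations,
    seed = cfg$seed
  )
}

#' Dump a scenario back to a YAML config file
#'
#' Inverse of [load_config()]: writing a scenario and reloading the file
#' yields identical parameters.
#'
#' @param scenario A [scenario()].
#' @param path Output path.
#' @export
write_config <- function(scenario, path) {
  stopifnot(inherits(scenario, "scenario"))
  cfg <- list(
    patient_mean = scenario$patient_group$mean_fa,
    patient_sd = scenario$patient_group$sd_fa,
    control_mean = scenario$control_group$mean_fa,
    control_sd = scenario$control_group$sd_fa,
    rate_percent = scenario$decrease$annual_rate_percent,
    cv_percent = scenario$decrease$cv_percent,
    sem = scenario$error$sem,
    t_days = scenario$t_days,
    m = scenario$m,
    n_per_group = scenario$n_per_group,
    alpha = scenario$alpha,
    iterations = scenario$iterations,
    seed = scenario$seed
  )
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' Write a power grid to CSV
#'
#' Fixed header `rate_percent,sem,t_days,m,n_per_group,power,mc_se,seed`,
#' 15-significant-digit numbers, newline-terminated; no timestamps, so two
#' writes of identical rows are byte-identical.
#'
#' @param rows A `"power_grid"` data frame (see [power_grid()]).
#' @param path Output path.
#' @export
write_power_csv <- function(rows, path) {
  cols <- c("rate_percent", "sem", "t_days", "m", "n_per_group", "power",
            "mc_se", "seed")
  if (nrow(rows) == 0L || !all(cols %in% names(rows))) {
    stop("rows must be a non-empty power grid with columns ",
         paste(cols, collapse = ","), call. = FALSE)
  }
  num <- function(x) sprintf("%.15g", x)
  lines <- c(
    paste(cols, collapse = ","),
    sprintf("%s,%s,%s,%d,%d,%s,%s,%d",
            num(rows$rate_percent), num(rows$sem), num(rows$t_days),
            as.integer(rows$m), as.integer(rows$n_per_group),
            num(rows$power), num(rows$mc_se), as.integer(rows$seed))
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a power grid written by [write_power_csv()]
#'
#' @param path CSV path.
#' @return A `"power_grid"` data frame.
#' @export
read_power_csv <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("power_grid", "data.frame")
  out
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run exactly — the resolved
#' parameters, the master seed, the package version and a timestamp — as a
#' YAML document next to the outputs.
#'
#' @param params Named list of fully resolved run parameters (a scenario's
#'   fields, or a grid specification including every swept dimension).
#' @param seed Master seed of the run.
#' @param path Output path.
#' @param command Optional name of the command that produced the run.
#' @return The manifest list, invisibly.
#' @export
emit_manifest <- function(params, seed, path, command = NULL) {
  manifest <- list(
    tool = "dtipower",
    version = as.character(utils::packageVersion("dtipower")),
    command = command,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = as.integer(seed),
    parameters = params
  )
  manifest <- manifest[!vapply(manifest, is.null, logical(1L))]
  yaml::write_yaml(manifest, path, precision = 15L)
  invisible(manifest)
}

#' Flatten a scenario into a plain named list
#'
#' Convenience for manifests and logging: every field of a [scenario()] as a
#' flat named list of scalars.
#'
#' @param scenario A [scenario()].
#' @return Named list.
#' @export
scenario_params <- function(scenario) {
  list(
    patient_mean = scenario$patient_group$mean_fa,
    patient_sd = scenario$patient_group$sd_fa,
    control_mean = scenario$control_group$mean_fa,
    control_sd = scenario$control_group$sd_fa,
    rate_percent = scenario$decrease$annual_rate_percent,
    cv_percent = scenario$decrease$cv_percent,
    anchor = scenario$decrease$anchor,
    anchor_fa = scenario$decrease$anchor_fa,
    sem = scenario$error$sem,
    t_days = scenario$t_days,
    m = scenario$m,
    n_per_group = scenario$n_per_group,
    alpha = scenario$alpha,
    iterations = scenario$iterations,
    seed = scenario$seed
  )
}
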