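# Simulation configuration: the study-design knobs of the synthetic
# cohort generator, with validation and YAML round-trip.

default_task_params <- function() {
  list(
    gait = list(
      duration = 12, amp_hc = 0.30, amp_pd = 0.24, amp_between_cv = 0.25,
      amp_within_cv = 0.10, cadence_hc = 1.8, cadence_pd = 1.6,
      cadence_sd = 0.12, cadence_session_sd = 0.05, noise_sd = 0.05
    ),
    balance = list(
      duration = 30, sway_amp = 0.05, sway_between_cv = 0.3,
      tremor_amp_hc = 0.01, tremor_amp_pd = 0.05, tremor_between_cv = 0.4,
      tremor_freq_range = c(4, 7), noise_sd = 0.02
    ),
    voice = list(
      duration = 10, f0_mean = 160, f0_sd = 25, amplitude = 0.5,
      shimmer_hc = 0.03, shimmer_pd = 0.06, jitter_hc = 0.004,
      jitter_pd = 0.008, level_between_cv = 0.3, f0_session_sd = 2
    ),
    tapping = list(
      duration = 20, iti_hc = 0.20, iti_pd = 0.35, iti_between_sd = 0.03,
      iti_within_sd_hc = 0.02, iti_within_sd_pd = 0.05,
      iti_session_sd = 0.015,
      miss_prob_hc = 0.05, miss_prob_pd = 0.15,
      scatter_hc = 8, scatter_pd = 16,
      geometry = list(left = c(60, 400, 160, 500),
                      right = c(200, 400, 300, 500))
    )
  )
}

#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic cohort
#' generator. The same object drives both tiers: the feature-table tier
#' with explicit variance components (for statistics unit tests) and the
#' raw-recording tier (for end-to-end runs).
#'
#' @param n_pd,n_hc number of PD and HC subjects
#' @param age_range inclusive age range in years
#' @param recordings_per_subject sessions per subject and task
#' @param schedule list with `gap_hours` (mean inter-session gap) and
#'   `jitter` (log-normal sdlog); gaps are drawn log-normal so hour-, day-,
#'   week- and month-scale retest lags are all populated
#' @param mu baseline feature mean
#' @param group_shift standardized PD-vs-HC shift delta (scalar, or named
#'   per feature for the feature-table tier)
#' @param var_between,var_within subject-level and residual variance
#'   components; the generating test-retest ICC is
#'   `var_between / (var_between + var_within)`
#' @param drift_slope per-repetition mean change (scalar, or named vector
#'   `c(PD = , HC = )` for a group-specific learning/motivation drift)
#' @param medication_effects named mean shifts for the PD medication
#'   states `c(before = , after = , best = )`
#' @param med_fraction fraction of PD sessions expanded into within-day
#'   before/after/best triplets in the recording tier
#' @param features feature names for the feature-table tier
#' @param tasks tasks generated by the recording tier
#' @param task_params per-task signal archetype parameters; defaults from
#'   `default_task_params()` are merged with any overrides
#' @param fs_motion,fs_voice sampling rates (Hz) of the accelerometer and
#'   audio payloads
#' @param seed integer seed; identical seed and config give bit-identical
#'   output
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_pd = 60, n_hc = 60, age_range = c(35, 75),
                       recordings_per_subject = 6,
                       schedule = list(gap_hours = 24, jitter = 1.5),
                       mu = 0, group_shift = 0.5,
                       var_between = 1, var_within = 1,
                       drift_slope = 0,
                       medication_effects = c(before = 0, after = 0, best = 0),
                       med_fraction = 0.5,
                       features = "f1",
                       tasks = c("gait", "balance", "voice", "tapping"),
                       task_params = list(),
                       fs_motion = 100, fs_voice = 16000,
                       seed = 1L) {
  if (!is_count(n_pd) || !is_count(n_hc) || n_pd + n_hc < 1)
    stop_bad_arg("n_pd and n_hc must be non-negative counts")
  if (length(age_range) != 2 || age_range[1] >= age_range[2])
    stop_bad_arg("age_range must be (low, high) with low < high")
  if (!is_count(recordings_per_subject) || recordings_per_subject < 1)
    stop_bad_arg("recordings_per_subject must be a positive count")
  if (!is.numeric(var_between) || var_between < 0)
    stop_bad_arg("var_between must be >= 0")
  if (!is.numeric(var_within) || var_within <= 0)
    stop_bad_arg("var_within must be > 0")
  bad <- setdiff(tasks, c("gait", "balance", "voice", "tapping"))
  if (length(bad)) stop_bad_arg("unsupported task(s): %s",
                                paste(bad, collapse = ", "))
  tp <- default_task_params()
  for (tk in names(task_params)) {
    if (!tk %in% names(tp)) stop_bad_arg("unsupported task name: %s", tk)
    tp[[tk]][names(task_params[[tk]])] <- task_params[[tk]]
  }
  structure(list(
    n_pd = as.integer(n_pd), n_hc = as.integer(n_hc),
    age_range = as.numeric(age_range),
    recordings_per_subject = as.integer(recordings_per_subject),
    schedule = schedule, mu = mu, group_shift = group_shift,
    var_between = var_between, var_within = var_within,
    drift_slope = drift_slope,
    medication_effects = medication_effects,
    med_fraction = med_fraction, features = features, tasks = tasks,
    task_params = tp, fs_motion = fs_motion, fs_voice = fs_voice,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_pd, "PD +", x$n_hc, "HC subjects,",
      x$recordings_per_subject, "sessions each;",
      "true ICC =", round(x$var_between / (x$var_between + x$var_within), 3),
      "; seed =", x$seed, "\n")
  invisible(x)
}

#' Read a simulation configuration from YAML
#'
#' Keys mirror the arguments of [sim_config()]; missing keys take the
#' defaults.
#'
#' @param path YAML file path
#' @return `sim_config` object
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop_bad_arg("unknown config key(s): %s",
                                paste(bad, collapse = ", "))
  for (nm in c("group_shift", "medication_effects", "drift_slope")) {
    if (!is.null(raw[[nm]]) && is.list(raw[[nm]]))
      raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(sim_config, raw)
}

true_icc <- function(config) {
  config$var_between / (config$var_between + config$var_within)
}

group_value <- function(param, diagnosis) {
  if (length(param) == 1 || is.null(names(param))) return(param[[1]])
  unname(param[[diagnosis]])
}
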