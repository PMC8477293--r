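# Raw-recording tier of the synthetic cohort: signal archetypes per task.
# The archetypes do not aim at physiological realism; they drive the
# downstream feature extractors with controllable statistics:
#   gait    - gravity-offset composite sinusoid at the subject's cadence
#   balance - low-frequency postural sway + 4-7 Hz tremor (PD-scaled)
#   voice   - cycle-synthesized harmonic source with per-cycle amplitude
#             (shimmer) and period (jitter) perturbation
#   tapping - alternating-button tap events with subject-level inter-tap
#             interval, spatial scatter and miss probability

synth_gait <- function(p, fs, amp, cadence, noise_sd) {
  t <- seq(0, p$duration - 1 / fs, by = 1 / fs)
  phase <- runif(3, 0, 2 * pi)
  y <- 1 + amp * (sin(2 * pi * cadence * t + phase[1]) +
                    0.4 * sin(4 * pi * cadence * t + phase[1])) +
    rnorm(length(t), 0, noise_sd)
  x <- 0.4 * amp * sin(pi * cadence * t + phase[2]) +
    rnorm(length(t), 0, noise_sd)
  z <- 0.3 * amp * sin(pi * cadence * t + phase[3]) +
    rnorm(length(t), 0, noise_sd)
  data.frame(t = t, x = x, y = y, z = z)
}

synth_balance <- function(p, fs, sway, tremor_amp, tremor_freq, noise_sd) {
  t <- seq(0, p$duration - 1 / fs, by = 1 / fs)
  phase <- runif(4, 0, 2 * pi)
  sway_sig <- sway * (sin(2 * pi * 0.3 * t + phase[1]) +
                        0.6 * sin(2 * pi * 0.7 * t + phase[2]))
  trem <- tremor_amp * sin(2 * pi * tremor_freq * t + phase[3])
  x <- sway_sig + trem + rnorm(length(t), 0, noise_sd)
  y <- 1 + 0.6 * sway_sig + 0.8 * trem + rnorm(length(t), 0, noise_sd)
  z <- 0.4 * sway_sig + 0.5 * trem + rnorm(length(t), 0, noise_sd)
  data.frame(t = t, x = x, y = y, z = z)
}

synth_voice <- function(p, fs, f0, shimmer, jitter, amplitude) {
  t0 <- 1 / f0
  n_cycles <- ceiling(p$duration / t0) + 2
  periods <- t0 * (1 + rnorm(n_cycles, 0, jitter * sqrt(pi) / 2))
  periods <- pmax(periods, t0 / 2)
  amps <- 1 + rnorm(n_cycles, 0, shimmer * sqrt(pi) / 2)
  amps <- pmax(amps, 0.1)
  starts <- cumsum(c(0, periods))
  ts <- seq(0, p$duration - 1 / fs, by = 1 / fs)
  cyc <- findInterval(ts, starts)
  phi <- (ts - starts[cyc]) / periods[cyc]
  amplitude * amps[cyc] * (sin(2 * pi * phi) + 0.25 * sin(4 * pi * phi))
}

synth_tapping <- function(p, iti_mean, iti_sd, miss_prob, scatter) {
  max_n <- ceiling(p$duration / max(iti_mean / 4, 1e-3)) + 10
  gaps <- pmax(rnorm(max_n, iti_mean, iti_sd), 0.05)
  times <- cumsum(gaps)
  times <- times[times <= p$duration]
  n <- length(times)
  if (n == 0) return(data.frame(t = numeric(0), x = numeric(0),
                                y = numeric(0)))
  geom <- p$geometry
  centers <- rbind(
    c((geom$left[1] + geom$left[3]) / 2, (geom$left[2] + geom$left[4]) / 2),
    c((geom$right[1] + geom$right[3]) / 2, (geom$right[2] + geom$right[4]) / 2))
  side <- rep(c(1L, 2L), length.out = n)          # alternating fingers
  xy <- centers[side, , drop = FALSE] +
    matrix(rnorm(2 * n, 0, scatter), ncol = 2)
  miss <- runif(n) < miss_prob
  # a miss is displaced vertically, clear of both button boxes
  xy[miss, 2] <- xy[miss, 2] + sample(c(-1, 1), sum(miss), TRUE) * 150
  data.frame(t = times, x = xy[, 1], y = xy[, 2])
}

subject_signal_params <- function(config, diagnosis) {
  tp <- config$task_params
  pd <- diagnosis == "PD"
  lcv <- function(mean, cv) mean * rlnorm(1, -log(1 + cv^2) / 2,
                                          sqrt(log(1 + cv^2)))
  list(
    gait = list(
      amp = lcv(if (pd) tp$gait$amp_pd else tp$gait$amp_hc,
                tp$gait$amp_between_cv),
      cadence = max(0.8, rnorm(1, if (pd) tp$gait$cadence_pd
                               else tp$gait$cadence_hc,
                               tp$gait$cadence_sd))),
    balance = list(
      sway = lcv(tp$balance$sway_amp, tp$balance$sway_between_cv),
      tremor_amp = lcv(if (pd) tp$balance$tremor_amp_pd
                       else tp$balance$tremor_amp_hc,
                       tp$balance$tremor_between_cv),
      tremor_freq = runif(1, tp$balance$tremor_freq_range[1],
                          tp$balance$tremor_freq_range[2])),
    voice = list(
      f0 = max(80, rnorm(1, tp$voice$f0_mean, tp$voice$f0_sd)),
      shimmer = lcv(if (pd) tp$voice$shimmer_pd else tp$voice$shimmer_hc,
                    tp$voice$level_between_cv),
      jitter = lcv(if (pd) tp$voice$jitter_pd else tp$voice$jitter_hc,
                   tp$voice$level_between_cv)),
    tapping = list(
      iti = max(0.08, rnorm(1, if (pd) tp$tapping$iti_pd
                            else tp$tapping$iti_hc,
                            tp$tapping$iti_between_sd)),
      iti_sd = if (pd) tp$tapping$iti_within_sd_pd
               else tp$tapping$iti_within_sd_hc,
      miss_prob = if (pd) tp$tapping$miss_prob_pd else tp$tapping$miss_prob_hc,
      scatter = if (pd) tp$tapping$scatter_pd else tp$tapping$scatter_hc)
  )
}

make_recording <- function(config, subj, task, timestamp, state, sp) {
  tp <- config$task_params[[task]]
  fs <- if (task == "voice") config$fs_voice
        else if (task == "tapping") NA_real_ else config$fs_motion
  # session-level parameter jitter keeps within-subject variance (and so
  # downstream feature ICC) below 1 even for low-noise features
  payload <- switch(task,
    gait = {
      amp <- sp$gait$amp * rlnorm(1, 0, tp$amp_within_cv)
      cad <- max(0.8, sp$gait$cadence + rnorm(1, 0, tp$cadence_session_sd))
      synth_gait(tp, fs, amp, cad, tp$noise_sd)
    },
    balance = synth_balance(tp, fs, sp$balance$sway,
                            sp$balance$tremor_amp * rlnorm(1, 0, 0.1),
                            sp$balance$tremor_freq, tp$noise_sd),
    voice = synth_voice(tp, fs,
                        max(80, sp$voice$f0 + rnorm(1, 0, tp$f0_session_sd)),
                        sp$voice$shimmer, sp$voice$jitter, tp$amplitude),
    tapping = {
      iti <- max(0.08, sp$tapping$iti + rnorm(1, 0, tp$iti_session_sd))
      ev <- synth_tapping(tp, iti, sp$tapping$iti_sd,
                          sp$tapping$miss_prob, sp$tapping$scatter)
      assign_buttons(ev, tp$geometry)
    })
  list(record_id = NA_character_, subject_id = subj$subject_id,
       task = task, timestamp = timestamp, medication_state = state,
       sampling_rate = fs, payload = payload)
}

#' Simulate raw task recordings and a cohort table
#'
#' Generates the recording tier of the synthetic cohort: per subject and
#' task, sessions on a log-normal schedule; for PD subjects a configurable
#' fraction of sessions expands into a within-day medication triplet
#' (before / after / best, one hour apart). Subject-level signal
#' parameters (cadence, tremor amplitude, F0, perturbation levels,
#' inter-tap interval, ...) are drawn with between-subject variance so the
#' test-retest ICC of downstream features is controllable; group scaling
#' of these parameters produces the PD-vs-HC shifts.
#'
#' @param config a [sim_config()] object
#' @return list with `cohort` (tibble: `subject_id`, `age`, `sex`,
#'   `diagnosis`), `recordings` (list of recording objects: `record_id`,
#'   `subject_id`, `task`, `timestamp` hours, `medication_state`,
#'   `sampling_rate`, `payload`), and `manifest` (tibble summary, one row
#'   per recording)
#' @export
simulate_recordings <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, "recordings"), {
    cohort <- simulate_cohort_table(config)
    states <- c("before", "after", "best")
    recs <- list()
    for (i in seq_len(nrow(cohort))) {
      subj <- cohort[i, ]
      sp <- subject_signal_params(config, subj$diagnosis)
      for (task in config$tasks) {
        hours <- schedule_hours(config, config$recordings_per_subject)
        for (s in seq_along(hours)) {
          triplet <- subj$diagnosis == "PD" &&
            runif(1) < config$med_fraction
          if (triplet) {
            for (j in 1:3) {
              recs[[length(recs) + 1L]] <-
                make_recording(config, subj, task,
                               hours[s] + (j - 1) * 1.0, states[j], sp)
            }
          } else {
            recs[[length(recs) + 1L]] <-
              make_recording(config, subj, task, hours[s], "none", sp)
          }
        }
      }
    }
    for (r in seq_along(recs)) recs[[r]]$record_id <- sprintf("R%06d", r)
    list(cohort = cohort[, c("subject_id", "age", "sex", "diagnosis")],
         recordings = recs, manifest = records_manifest(recs))
  })
}

#' Manifest of a recording collection
#'
#' @param recordings list of recording objects
#' @return tibble: `record_id`, `subject_id`, `task`, `timestamp`,
#'   `medication_state`
#' @export
records_manifest <- function(recordings) {
  dplyr::bind_rows(purrr::map(recordings, function(r)
    tibble::tibble(record_id = r$record_id, subject_id = r$subject_id,
                   task = r$task, timestamp = r$timestamp,
                   medication_state = r$medication_state)))
}

#' Write a recording collection to the on-disk layout
#'
#' One directory per task holding `recordings.jsonl` (one JSON object per
#' recording; accelerometer payloads as arrays of `{t, x, y, z}`, tapping
#' payloads as arrays of `{t, x, y, button}`) and, for voice, PCM 16-bit
#' mono WAVs under `audio/`. `cohort.csv` and `manifest.csv` sit at the
#' top level.
#'
#' @param sim result of [simulate_recordings()]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_recordings <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$cohort, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  by_task <- split(sim$recordings,
                   vapply(sim$recordings, `[[`, "", "task"))
  for (task in names(by_task)) {
    tdir <- file.path(dir, task)
    dir.create(tdir, showWarnings = FALSE)
    if (task == "voice") dir.create(file.path(tdir, "audio"),
                                    showWarnings = FALSE)
    con <- file(file.path(tdir, "recordings.jsonl"), "w")
    for (r in by_task[[task]]) {
      meta <- list(record_id = r$record_id, subject_id = r$subject_id,
                   task = r$task, timestamp = r$timestamp,
                   medication_state = r$medication_state,
                   sampling_rate = r$sampling_rate)
      if (task == "voice") {
        wav <- file.path(tdir, "audio", paste0(r$record_id, ".wav"))
        write_wav(r$payload, r$sampling_rate, wav)
        meta$audio <- file.path("audio", paste0(r$record_id, ".wav"))
      } else {
        meta$payload <- r$payload
      }
      writeLines(jsonlite::toJSON(meta, dataframe = "rows",
                                  auto_unbox = TRUE, digits = NA), con)
    }
    close(con)
  }
  invisible(dir)
}

#' Read a recording collection from the on-disk layout
#'
#' Inverse of [write_recordings()]. Unparseable JSON lines become
#' recordings with a `NULL` payload (flagged and excluded during
#' cleaning).
#'
#' @param dir directory written by [write_recordings()]
#' @return list with `cohort`, `recordings`, `manifest` as in
#'   [simulate_recordings()]
#' @export
read_recordings <- function(dir) {
  cohort <- tibble::as_tibble(
    utils::read.csv(file.path(dir, "cohort.csv"),
                    colClasses = c(subject_id = "character")))
  recs <- list()
  for (task in c("gait", "balance", "voice", "tapping")) {
    f <- file.path(dir, task, "recordings.jsonl")
    if (!file.exists(f)) next
    for (line in readLines(f, warn = FALSE)) {
      meta <- tryCatch(jsonlite::fromJSON(line), error = function(e) NULL)
      if (is.null(meta)) {
        recs[[length(recs) + 1L]] <- list(record_id = NA_character_,
                                          task = task, payload = NULL)
        next
      }
      payload <- if (!is.null(meta$audio)) {
        wav <- tryCatch(read_wav(file.path(dir, task, meta$audio)),
                        error = function(e) NULL)
        if (is.null(wav)) NULL else wav$samples
      } else meta$payload
      recs[[length(recs) + 1L]] <- list(
        record_id = meta$record_id, subject_id = meta$subject_id,
        task = meta$task, timestamp = meta$timestamp,
        medication_state = meta$medication_state,
        sampling_rate = meta$sampling_rate, payload = payload)
    }
  }
  list(cohort = cohort, recordings = recs,
       manifest = records_manifest(
         recs[!vapply(recs, function(r) is.null(r$payload), logical(1))]))
}
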