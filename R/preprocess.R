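# Cohort cleaning, record windowing, and repetition indexing.

#' Cohort cleaning configuration
#'
#' @param age_min,age_max inclusive age limits in years (defaults 35-75)
#' @param required_fields demographic fields that must be non-missing
#' @return list of class `clean_config`
#' @export
clean_config <- function(age_min = 35, age_max = 75,
                         required_fields = c("age", "sex", "diagnosis")) {
  if (age_min >= age_max) stop_bad_arg("age_min must be < age_max")
  structure(list(age_min = age_min, age_max = age_max,
                 required_fields = required_fields),
            class = "clean_config")
}

payload_corrupted <- function(r) {
  p <- r$payload
  if (is.null(p)) return(TRUE)
  if (is.data.frame(p)) {
    if (nrow(p) == 0) return(TRUE)
    num <- p[vapply(p, is.numeric, logical(1))]
    return(any(!vapply(num, function(col) all(is.finite(col)), logical(1))))
  }
  if (is.numeric(p)) return(length(p) == 0 || any(!is.finite(p)))
  TRUE
}

#' Clean a cohort and its recordings
#'
#' Applies the demographic inclusion rules — all required fields present
#' and age within `[age_min, age_max]` — and drops recordings with empty
#' or corrupted payloads (unparseable, zero-length, or containing
#' non-finite samples). Every exclusion is logged with a reason code;
#' retained rows are never altered.
#'
#' @param cohort tibble with `subject_id`, `age`, `sex`, `diagnosis`
#' @param recordings list of recording objects
#' @param cfg a [clean_config()]
#' @return list: `cohort` (retained subjects), `recordings` (retained
#'   records of retained subjects), `exclusions` (tibble `id`, `unit`
#'   subject/record, `reason`)
#' @export
clean_cohort <- function(cohort, recordings, cfg = clean_config()) {
  excl <- list()
  miss <- rep(FALSE, nrow(cohort))
  for (f in cfg$required_fields) {
    v <- cohort[[f]]
    miss_f <- is.null(v) | is.na(v) | (is.character(v) & !nzchar(v))
    for (i in which(miss_f & !miss))
      excl[[length(excl) + 1L]] <- tibble::tibble(
        id = cohort$subject_id[i], unit = "subject",
        reason = paste0("missing_", f))
    miss <- miss | miss_f
  }
  age_bad <- !miss & (cohort$age < cfg$age_min | cohort$age > cfg$age_max)
  for (i in which(age_bad))
    excl[[length(excl) + 1L]] <- tibble::tibble(
      id = cohort$subject_id[i], unit = "subject",
      reason = "age_out_of_range")
  keep_subj <- cohort$subject_id[!miss & !age_bad]
  kept_recs <- list()
  for (r in recordings) {
    if (payload_corrupted(r)) {
      excl[[length(excl) + 1L]] <- tibble::tibble(
        id = r$record_id %||% NA_character_, unit = "record",
        reason = "corrupted_payload")
    } else if (!(r$subject_id %in% keep_subj)) {
      excl[[length(excl) + 1L]] <- tibble::tibble(
        id = r$record_id, unit = "record", reason = "subject_excluded")
    } else {
      kept_recs[[length(kept_recs) + 1L]] <- r
    }
  }
  out_cohort <- cohort[cohort$subject_id %in% keep_subj, , drop = FALSE]
  if (nrow(out_cohort) == 0) warning("no subjects retained after cleaning")
  list(cohort = out_cohort, recordings = kept_recs,
       exclusions = if (length(excl)) dplyr::bind_rows(excl)
                    else tibble::tibble(id = character(0),
                                        unit = character(0),
                                        reason = character(0)))
}

#' Task windowing rules
#'
#' The per-task analysis windows, in seconds from record start, half-open
#' `[start, end)`: gait keeps the first 10 s (shorter records are
#' rejected), balance keeps `[5, 20)` of the 30 s record, voice keeps
#' `[2, 8)` of the 10 s phonation, tapping is analysed untrimmed over its
#' 20 s.
#'
#' @param task one of gait/balance/voice/tapping
#' @return list `start`, `end` (`NA` end = untrimmed), `min_duration`
#' @export
task_window_spec <- function(task) {
  switch(task,
    gait = list(start = 0, end = 10, min_duration = 10),
    balance = list(start = 5, end = 20, min_duration = 20),
    voice = list(start = 2, end = 8, min_duration = 8),
    tapping = list(start = 0, end = NA_real_, min_duration = 0),
    stop_bad_arg("unsupported task name: %s", task))
}

record_duration <- function(r) {
  p <- r$payload
  if (is.data.frame(p) && "t" %in% names(p)) {
    if (r$task == "tapping") return(if (nrow(p)) max(p$t) else 0)
    return(nrow(p) / r$sampling_rate)
  }
  if (is.numeric(p)) return(length(p) / r$sampling_rate)
  0
}

#' Window a recording to its task analysis segment
#'
#' Applies [task_window_spec()]. Windowing is idempotent: an
#' already-windowed record is returned unchanged. Records shorter than
#' the task's minimum duration are rejected.
#'
#' @param rec recording object
#' @return the windowed record (with `windowed = TRUE` and `t` rebased to
#'   0), or `NULL` with attribute handling left to the caller when the
#'   record is too short; use [window_records()] for logged batch
#'   windowing
#' @export
window_record <- function(rec) {
  if (isTRUE(rec$windowed)) return(rec)
  spec <- task_window_spec(rec$task)
  dur <- record_duration(rec)
  if (dur < spec$min_duration) return(NULL)
  p <- rec$payload
  if (rec$task == "tapping") {
    rec$windowed <- TRUE
    return(rec)
  }
  if (is.data.frame(p)) {
    keep <- p$t >= spec$start & p$t < spec$end
    p <- p[keep, , drop = FALSE]
    p$t <- p$t - spec$start
    rownames(p) <- NULL
  } else {
    i0 <- floor(spec$start * rec$sampling_rate) + 1L
    i1 <- floor(spec$end * rec$sampling_rate)
    p <- p[i0:min(i1, length(p))]
  }
  rec$payload <- p
  rec$windowed <- TRUE
  rec
}

#' Window a list of recordings, logging rejections
#'
#' @param recordings list of recording objects
#' @return list: `recordings` (windowed survivors), `rejected` (tibble
#'   `record_id`, `reason`)
#' @export
window_records <- function(recordings) {
  out <- list(); rej <- list()
  for (r in recordings) {
    w <- window_record(r)
    if (is.null(w)) {
      rej[[length(rej) + 1L]] <- tibble::tibble(
        record_id = r$record_id, reason = "insufficient length")
    } else out[[length(out) + 1L]] <- w
  }
  list(recordings = out,
       rejected = if (length(rej)) dplyr::bind_rows(rej)
                  else tibble::tibble(record_id = character(0),
                                      reason = character(0)))
}

#' Attach repetition indices and elapsed time
#'
#' Per subject and task, records are ranked chronologically (baseline =
#' 1) and the elapsed time from baseline is computed in hours. Duplicate
#' timestamps are broken stably by `record_id`, with a warning. The
#' result is invariant to the input row order.
#'
#' @param manifest tibble with `record_id`, `subject_id`, `task`,
#'   `timestamp` (hours)
#' @return `manifest` plus `repetition_index` and `elapsed_hours`,
#'   ordered by subject, task, repetition
#' @export
index_repetitions <- function(manifest) {
  stopifnot(all(c("record_id", "subject_id", "task", "timestamp")
                %in% names(manifest)))
  dups <- manifest |>
    dplyr::count(.data$subject_id, .data$task, .data$timestamp) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dups) > 0)
    warning(sprintf("%d duplicate timestamps; ties broken by record_id",
                    nrow(dups)))
  manifest |>
    dplyr::arrange(.data$subject_id, .data$task, .data$timestamp,
                   .data$record_id) |>
    dplyr::group_by(.data$subject_id, .data$task) |>
    dplyr::mutate(repetition_index = dplyr::row_number(),
                  elapsed_hours = .data$timestamp - .data$timestamp[1]) |>
    dplyr::ungroup()
}

#' Subjects eligible for the longitudinal models
#'
#' Subjects with at least 4 repetitions after baseline (repetition index
#' reaching 5) for the given task.
#'
#' @param manifest indexed manifest from [index_repetitions()]
#' @param task task name (default: evaluate per task)
#' @param min_reps required repetition count (default 5)
#' @return character vector of subject ids (single task) or a tibble
#'   `task`, `subject_id` when `task` is `NULL`
#' @export
eligible_for_longitudinal <- function(manifest, task = NULL, min_reps = 5) {
  m <- manifest |>
    dplyr::group_by(.data$task, .data$subject_id) |>
    dplyr::summarise(n_reps = max(.data$repetition_index), .groups = "drop") |>
    dplyr::filter(.data$n_reps >= min_reps)
  if (is.null(task)) return(m[, c("task", "subject_id")])
  m$subject_id[m$task == task]
}
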