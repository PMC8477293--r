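# End-to-end orchestration: simulate -> clean/window/index -> extract ->
# screen -> reliability -> longitudinal -> report.

#' Extract features from a windowed recording collection
#'
#' Dispatches each recording to its task's extractor and joins the
#' resulting long-format rows with the indexed manifest and cohort
#' demographics.
#'
#' @param recordings list of windowed recording objects
#' @param manifest indexed manifest ([index_repetitions()])
#' @param cohort cleaned cohort tibble
#' @return long-format feature table: `record_id`, `feature`, `value`,
#'   `subject_id`, `task`, `timestamp`, `medication_state`,
#'   `repetition_index`, `elapsed_hours`, `diagnosis`, `age`, `sex`
#' @export
extract_features <- function(recordings, manifest, cohort) {
  rows <- purrr::map(recordings, function(r) {
    switch(r$task,
      gait = extract_gait_features(r$payload, r$sampling_rate, r$record_id),
      balance = extract_balance_features(r$payload, r$sampling_rate,
                                         r$record_id),
      voice = extract_voice_features(r$payload, r$sampling_rate,
                                     r$record_id),
      tapping = extract_tapping_features(r$payload, r$record_id))
  })
  feats <- dplyr::bind_rows(rows)
  feats |>
    dplyr::inner_join(manifest, by = "record_id") |>
    dplyr::inner_join(cohort, by = "subject_id")
}

baseline_matrix <- function(feature_table) {
  base <- feature_table[feature_table$repetition_index == 1L, ]
  wide <- tidyr::pivot_wider(
    base[, c("subject_id", "feature", "value")],
    names_from = "feature", values_from = "value",
    values_fn = function(v) v[1])
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$subject_id
  m
}

#' Longitudinal model battery for selected features
#'
#' Runs the four designs on each feature: repetition (diagnosis x
#' repetition mixed ANOVA), repetition adjusted for age and sex, elapsed
#' time as a continuous within-subject regressor (adjusted), and the
#' PD-only medication model. Only subjects with complete 5-repetition
#' profiles enter the repetition designs; the medication model uses PD
#' subjects with all three states.
#'
#' @param feature_table joined feature table from [extract_features()]
#' @param features character vector of features to model
#' @param n_within repetition levels (default 5)
#' @return tibble: `feature`, `model` (repetition / repetition_adj /
#'   elapsed_time / medication), `effect`, `stratum`, `sum_sq`, `df`,
#'   `F`, `p`, `p_gg`
#' @export
longitudinal_battery <- function(feature_table, features, n_within = 5) {
  out <- list()
  for (f in features) {
    d <- feature_table[feature_table$feature == f &
                       is.finite(feature_table$value), ]
    d5 <- d[d$repetition_index <= n_within, ]
    res <- list()
    res$repetition <- tryCatch(rm_anova(d5, n_within), error = function(e) NULL)
    res$repetition_adj <- tryCatch(
      rm_anova_covariates(d5, n_within), error = function(e) NULL)
    res$elapsed_time <- tryCatch(
      elapsed_time_model(d5), error = function(e) NULL)
    dmed <- d[d$diagnosis == "PD" &
              d$medication_state %in% c("before", "after", "best"), ]
    res$medication <- tryCatch(
      medication_model(dmed), error = function(e) NULL)
    for (mn in names(res)) {
      if (is.null(res[[mn]])) next
      tb <- res[[mn]]
      tb$feature <- f; tb$model <- mn
      out[[length(out) + 1L]] <- tb
    }
  }
  dplyr::bind_rows(out)
}

#' Mean ICC of the top features at the first versus last scheme
#'
#' For each task and scheme family, the mean ICC over the selected top
#' features at the family's first scheme (rep2 / hour) versus its last
#' (rep5 / month), averaged over groups — the summary used to judge
#' reliability decay over repetitions and time lags.
#'
#' @param icc_results output of [icc_by_scheme()]
#' @param top_features output of [select_top_features()]
#' @return tibble: `task`, `family`, `first_scheme`, `last_scheme`,
#'   `mean_icc_first`, `mean_icc_last`
#' @export
summarize_mean_icc <- function(icc_results, top_features) {
  empty <- tibble::tibble(task = character(0), family = character(0),
                          first_scheme = character(0),
                          last_scheme = character(0),
                          mean_icc_first = numeric(0),
                          mean_icc_last = numeric(0))
  if (!nrow(icc_results) || !nrow(top_features)) return(empty)
  icc_results$task <- sub("\\..*$", "", icc_results$feature)
  pairs <- list(repetition = c("rep2", "rep5"), time = c("hour", "month"))
  rows <- list()
  for (fam in names(pairs)) {
    sel <- top_features$feature[top_features$family == fam]
    sub <- icc_results[icc_results$feature %in% sel &
                       icc_results$family == fam, ]
    if (!nrow(sub)) next
    agg <- sub |>
      dplyr::group_by(.data$task, .data$scheme) |>
      dplyr::summarise(mean_icc = mean(.data$icc, na.rm = TRUE),
                       .groups = "drop")
    for (tk in unique(agg$task)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        task = tk, family = fam,
        first_scheme = pairs[[fam]][1], last_scheme = pairs[[fam]][2],
        mean_icc_first = agg$mean_icc[agg$task == tk &
                                        agg$scheme == pairs[[fam]][1]][1],
        mean_icc_last = agg$mean_icc[agg$task == tk &
                                       agg$scheme == pairs[[fam]][2]][1])
    }
  }
  dplyr::bind_rows(rows)
}

write_stage <- function(tbl, dir, name) {
  if (!is.null(dir)) {
    utils::write.csv(tbl, file.path(dir, name), row.names = FALSE)
  }
  invisible(tbl)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes every stage in order: recording simulation, cohort cleaning,
#' windowing, repetition indexing, feature extraction, redundancy
#' filtering, baseline screening, ICC reliability across all pairing
#' schemes, top-feature selection, mean-ICC summaries, and the
#' longitudinal model battery. All stage outputs are returned and,
#' when `out_dir` is given, written as CSV plus a Markdown report.
#'
#' @param config a [sim_config()]; `seed` overrides the config seed
#' @param out_dir optional output directory
#' @param seed optional integer overriding `config$seed`
#' @param verbose print stage progress to stderr
#' @return list of stage outputs: `config`, `cohort`, `exclusions`,
#'   `manifest`, `feature_table`, `retained_features`, `screen`, `icc`,
#'   `top_features`, `mean_icc`, `longitudinal`, `report`
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         seed = NULL, verbose = FALSE) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  say("simulating recordings")
  sim <- simulate_recordings(config)
  say("cleaning cohort")
  cl <- clean_cohort(sim$cohort, sim$recordings)
  say("windowing records")
  win <- window_records(cl$recordings)
  excl <- dplyr::bind_rows(
    cl$exclusions,
    if (nrow(win$rejected))
      tibble::tibble(id = win$rejected$record_id, unit = "record",
                     reason = win$rejected$reason))
  manifest <- index_repetitions(records_manifest(win$recordings))
  write_stage(excl, out_dir, "exclusions.csv")
  write_stage(manifest, out_dir, "clean_manifest.csv")

  say("extracting features from ", length(win$recordings), " recordings")
  ft <- extract_features(win$recordings, manifest, cl$cohort)
  write_stage(ft, out_dir, "features.csv")

  say("redundancy filtering")
  bm <- baseline_matrix(ft)
  retained <- dedup_features(bm, seed = config$seed)
  ft_kept <- ft[ft$feature %in% retained, ]

  say("baseline screening")
  screen <- screen_features(ft_kept)
  write_stage(screen, out_dir, "screen.csv")
  signif_feats <- screen$feature[screen$significant]

  say("ICC reliability for ", length(signif_feats), " screened features")
  icc <- icc_by_scheme(ft_kept[ft_kept$feature %in% signif_feats, ])
  write_stage(icc, out_dir, "icc.csv")
  top <- select_top_features(icc)
  write_stage(top, out_dir, "top_features.csv")
  mean_icc <- summarize_mean_icc(icc, top)
  write_stage(mean_icc, out_dir, "mean_icc.csv")

  say("longitudinal models")
  longi <- longitudinal_battery(ft_kept, unique(top$feature))
  write_stage(longi, out_dir, "longitudinal.csv")

  report <- pipeline_report(cl$cohort, excl, screen, mean_icc, longi)
  if (!is.null(out_dir))
    writeLines(report, file.path(out_dir, "report.md"))
  say("done")
  list(config = config, cohort = cl$cohort, exclusions = excl,
       manifest = manifest, feature_table = ft_kept,
       retained_features = retained, screen = screen, icc = icc,
       top_features = top, mean_icc = mean_icc, longitudinal = longi,
       report = report)
}

count_sig <- function(longi, model, effect) {
  sub <- longi[longi$model == model & longi$effect == effect, ]
  sprintf("%d out of %d", sum(sub$p < 0.05, na.rm = TRUE),
          sum(is.finite(sub$p)))
}

#' Assemble the Markdown run report
#'
#' @param cohort cleaned cohort tibble
#' @param excl exclusion log
#' @param screen screening table
#' @param mean_icc mean-ICC summary table
#' @param longi longitudinal effect table
#' @return character vector of Markdown lines
#' @export
pipeline_report <- function(cohort, excl, screen, mean_icc, longi) {
  task_of <- function(f) sub("\\..*$", "", f)
  lines <- c(
    "# Digital-biomarker reliability pipeline report", "",
    sprintf("Cohort: %d PD + %d HC subjects retained (%d exclusions).",
            sum(cohort$diagnosis == "PD"),
            sum(cohort$diagnosis == "HC"), nrow(excl)), "",
    "## Baseline screening", "")
  for (tk in unique(task_of(screen$feature))) {
    s <- screen[task_of(screen$feature) == tk, ]
    lines <- c(lines, sprintf(
      "- %s: %d out of %d features significant at baseline (P<.05)",
      tk, sum(s$significant), nrow(s)))
  }
  lines <- c(lines, "", "## Test-retest reliability (top features)", "")
  if (nrow(mean_icc)) {
    for (i in seq_len(nrow(mean_icc))) {
      r <- mean_icc[i, ]
      lines <- c(lines, sprintf(
        "- %s / %s family: mean ICC %.2f at %s vs %.2f at %s",
        r$task, r$family, r$mean_icc_first, r$first_scheme,
        r$mean_icc_last, r$last_scheme))
    }
  }
  lines <- c(lines, "", "## Longitudinal effects (top features)", "")
  if (nrow(longi)) {
    lines <- c(lines,
      sprintf("- diagnosis main effect: %s features",
              count_sig(longi, "repetition", "diagnosis")),
      sprintf("- repetition main effect: %s features",
              count_sig(longi, "repetition", "repetition")),
      sprintf("- diagnosis-by-repetition interaction: %s features",
              count_sig(longi, "repetition", "diagnosis:repetition")),
      sprintf("- elapsed-time main effect: %s features",
              count_sig(longi, "elapsed_time", "time")),
      sprintf("- medication effect (PD): %s features",
              count_sig(longi, "medication", "medication")))
  }
  lines
}
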