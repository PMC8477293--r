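# Mixed between/within repeated-measures ANOVA, computed by explicit
# projection-based sums of squares in two error strata:
#   between-subject stratum : subject means       ~ [covariates +] diagnosis
#   within-subject stratum  : subject-centered    ~ within factor (+ its
#                             deviations            diagnosis interaction)
# Subject-mean SS are rescaled by the number of within levels so that the
# strata add up to the total sum of squares of the raw observations.

rss_of <- function(X, y) {
  if (is.null(X)) return(sum(y^2))
  fit <- lm.fit(X, y)
  sum(fit$residuals^2)
}

rank_of <- function(X) if (is.null(X)) 0L else qr(X)$rank

#' Greenhouse-Geisser epsilon
#'
#' Sphericity-correction factor computed from the pooled within-group
#' covariance matrix of the within-subject level profiles:
#' `eps = tr(M)^2 / ((k-1) tr(M^2))` where `M` is the double-centered
#' covariance matrix. Bounded in `[1/(k-1), 1]`.
#'
#' @param profiles numeric matrix, one row per subject, one column per
#'   within-subject level
#' @param groups optional grouping factor for pooling the covariance
#' @return epsilon in `[1/(k-1), 1]`
#' @export
gg_epsilon <- function(profiles, groups = NULL) {
  k <- ncol(profiles)
  if (k < 2) return(1)
  if (is.null(groups)) groups <- factor(rep(1, nrow(profiles)))
  groups <- droplevels(factor(groups))
  covs <- lapply(levels(groups), function(g) {
    m <- profiles[groups == g, , drop = FALSE]
    if (nrow(m) < 2) return(NULL)
    list(S = cov(m), df = nrow(m) - 1)
  })
  covs <- covs[!vapply(covs, is.null, logical(1))]
  if (!length(covs)) return(1)
  S <- Reduce(`+`, lapply(covs, function(cc) cc$S * cc$df)) /
    sum(vapply(covs, function(cc) cc$df, numeric(1)))
  J <- diag(k) - matrix(1 / k, k, k)
  M <- J %*% S %*% J
  tr <- sum(diag(M))
  tr2 <- sum(M * M)
  if (tr2 <= 0) return(1)
  eps <- tr^2 / ((k - 1) * tr2)
  min(max(eps, 1 / (k - 1)), 1)
}

prepare_profiles <- function(data, within_col, n_within, value_col = "value") {
  # median-aggregate duplicates, keep complete profiles only
  key <- paste(data$subject_id, data[[within_col]], sep = "\r")
  if (!anyDuplicated(key)) {
    agg <- tibble::tibble(subject_id = data$subject_id,
                          within = data[[within_col]],
                          value = data[[value_col]])
    names(agg)[2] <- within_col
    agg <- agg[order(agg$subject_id, agg[[within_col]]), ]
  } else {
    agg <- data |>
      dplyr::group_by(.data$subject_id, .data[[within_col]]) |>
      dplyr::summarise(value = median(.data[[value_col]]), .groups = "drop")
  }
  counts <- table(agg$subject_id)
  complete <- names(counts)[counts == n_within]
  dropped <- setdiff(unique(as.character(data$subject_id)), complete)
  agg <- agg[agg$subject_id %in% complete, ]
  list(agg = agg, complete = complete, dropped = dropped)
}

anova_row <- function(effect, ss, df, ms_err, df_err, eps = NA_real_) {
  f <- if (df > 0 && ms_err > 0) (ss / df) / ms_err else NA_real_
  p <- if (is.finite(f)) pf(f, df, df_err, lower.tail = FALSE) else NA_real_
  p_gg <- if (is.finite(f) && is.finite(eps))
    pf(f, eps * df, eps * df_err, lower.tail = FALSE) else NA_real_
  tibble::tibble(effect = effect, sum_sq = ss, df = df, F = f, p = p,
                 p_gg = p_gg)
}

between_stratum <- function(subj_tbl, k_within, covariates = NULL) {
  # subj_tbl: subject_id, diagnosis, m (subject mean), optional age/sex.
  # Partial (Type-II) SS: each term assessed against the model holding all
  # other between-subject terms.
  m <- subj_tbl$m
  n <- length(m)
  terms <- list()
  X_full <- matrix(1, n, 1)
  cov_cols <- list()
  if (!is.null(covariates)) {
    for (cv in covariates) {
      v <- subj_tbl[[cv]]
      if (is.character(v) || is.factor(v)) {
        v <- as.numeric(factor(v)) - 1
      }
      if (sd(v) == 0) {
        warning(sprintf("covariate '%s' is constant; dropped", cv))
        next
      }
      cov_cols[[cv]] <- v - mean(v)
    }
  }
  has_groups <- length(unique(subj_tbl$diagnosis)) >= 2
  diag_col <- if (has_groups)
    as.numeric(subj_tbl$diagnosis == sort(unique(subj_tbl$diagnosis))[1])
  else NULL
  base_cols <- c(list(intercept = rep(1, n)), cov_cols)
  if (has_groups) all_cols <- c(base_cols, list(diagnosis = diag_col))
  else all_cols <- base_cols
  X_all <- do.call(cbind, all_cols)
  rss_full <- rss_of(X_all, m)
  df_err <- n - rank_of(X_all)
  rows <- list()
  test_terms <- c(names(cov_cols), if (has_groups) "diagnosis")
  for (tm in test_terms) {
    X_red <- do.call(cbind, all_cols[setdiff(names(all_cols), tm)])
    ss <- (rss_of(X_red, m) - rss_full) * k_within
    rows[[tm]] <- list(effect = tm, ss = max(ss, 0), df = 1L)
  }
  list(rows = rows, ss_err = rss_full * k_within, df_err = df_err)
}

#' Mixed-design repeated-measures ANOVA: diagnosis x repetition
#'
#' Two-stratum repeated-measures ANOVA with a between-subject factor
#' `diagnosis` and a within-subject factor `repetition` (levels
#' `1..n_within`), including their interaction. Between-subject effects are
#' tested against subjects-within-groups; within-subject effects against
#' the repetition-by-subjects-within-groups residual. Unequal group sizes
#' are handled with partial sums of squares in the between stratum.
#' Greenhouse-Geisser-corrected p-values (`p_gg`) are reported alongside
#' the uncorrected ones for within-stratum effects.
#'
#' Subjects with incomplete repetition profiles are dropped (listed in the
#' `dropped_subjects` attribute); duplicate observations within
#' subject-by-repetition cells are aggregated by their median.
#'
#' @param data tibble with columns `subject_id`, `diagnosis`,
#'   `repetition_index`, `value` (plus `age`, `sex` for
#'   [rm_anova_covariates()])
#' @param n_within number of repetition levels required per subject
#'   (default 5)
#' @param covariates optional character vector of subject-level covariate
#'   columns adjusted for in the between stratum
#' @return tibble with one row per effect: `effect`, `stratum`, `sum_sq`,
#'   `df`, `F`, `p`, `p_gg`; error rows carry `F = p = NA`. Attributes:
#'   `dropped_subjects`, `gg_epsilon`.
#' @export
rm_anova <- function(data, n_within = 5, covariates = NULL) {
  stopifnot(all(c("subject_id", "diagnosis", "repetition_index", "value")
                %in% names(data)))
  data <- data[data$repetition_index %in% seq_len(n_within), ]
  prep <- prepare_profiles(data, "repetition_index", n_within)
  agg <- prep$agg
  if (length(prep$complete) < 4)
    stop_bad_arg("need at least 4 subjects with complete profiles")
  subj_info <- data |>
    dplyr::distinct(.data$subject_id, .keep_all = TRUE) |>
    dplyr::filter(.data$subject_id %in% prep$complete)
  agg <- dplyr::arrange(agg, .data$subject_id, .data$repetition_index)
  wide <- matrix(agg$value, ncol = n_within, byrow = TRUE)
  subj_ids <- unique(agg$subject_id)
  rownames(wide) <- subj_ids
  subj_info <- subj_info[match(subj_ids, subj_info$subject_id), ]
  g <- factor(subj_info$diagnosis)
  n_groups <- nlevels(droplevels(g))

  subj_tbl <- tibble::tibble(subject_id = subj_ids,
                             diagnosis = as.character(g),
                             m = rowMeans(wide))
  for (cv in covariates) subj_tbl[[cv]] <- subj_info[[cv]]
  bw <- between_stratum(subj_tbl, n_within, covariates)

  # within stratum: deviations from subject means
  dev <- as.vector(t(wide - rowMeans(wide)))      # subject-major, rep-minor
  rep_f <- factor(rep(seq_len(n_within), times = length(subj_ids)))
  diag_f <- factor(rep(as.character(g), each = n_within))
  X_rep <- model.matrix(~rep_f)
  rss0 <- sum(dev^2)
  rss_rep <- rss_of(X_rep, dev)
  ss_rep <- rss0 - rss_rep
  df_rep <- n_within - 1L
  if (n_groups >= 2) {
    X_int <- model.matrix(~ rep_f + diag_f:rep_f)
    X_int <- X_int[, qr(X_int)$pivot[seq_len(qr(X_int)$rank)], drop = FALSE]
    rss_int <- rss_of(X_int, dev)
    ss_int <- rss_rep - rss_int
    df_int <- (n_groups - 1L) * (n_within - 1L)
    rss_w_err <- rss_int
  } else {
    ss_int <- NA_real_; df_int <- 0L
    rss_w_err <- rss_rep
  }
  df_w_err <- (length(subj_ids) - n_groups) * (n_within - 1L)
  ms_w_err <- rss_w_err / df_w_err
  eps <- gg_epsilon(wide, g)

  ms_b_err <- bw$ss_err / n_within / bw$df_err  # on subject-mean scale
  rows <- list()
  for (tm in bw$rows) {
    rows[[length(rows) + 1L]] <-
      cbind(anova_row(tm$effect, tm$ss, tm$df,
                      ms_b_err * n_within, bw$df_err),
            stratum = "between")
  }
  rows[[length(rows) + 1L]] <- cbind(
    tibble::tibble(effect = "subjects(error)", sum_sq = bw$ss_err,
                   df = bw$df_err, F = NA_real_, p = NA_real_,
                   p_gg = NA_real_), stratum = "between")
  rows[[length(rows) + 1L]] <- cbind(
    anova_row("repetition", ss_rep, df_rep, ms_w_err, df_w_err, eps),
    stratum = "within")
  if (n_groups >= 2) {
    rows[[length(rows) + 1L]] <- cbind(
      anova_row("diagnosis:repetition", ss_int, df_int, ms_w_err,
                df_w_err, eps), stratum = "within")
  }
  rows[[length(rows) + 1L]] <- cbind(
    tibble::tibble(effect = "repetition:subjects(error)",
                   sum_sq = rss_w_err, df = df_w_err, F = NA_real_,
                   p = NA_real_, p_gg = NA_real_), stratum = "within")
  out <- dplyr::bind_rows(rows)
  attr(out, "dropped_subjects") <- prep$dropped
  attr(out, "gg_epsilon") <- eps
  out
}

#' @rdname rm_anova
#' @export
rm_anova_covariates <- function(data, n_within = 5,
                                covariates = c("age", "sex")) {
  rm_anova(data, n_within = n_within, covariates = covariates)
}

#' Mixed ANOVA with elapsed time as a continuous within-subject regressor
#'
#' Between-subject stratum as in [rm_anova()] (diagnosis, optionally
#' adjusted for age and sex); in the within-subject stratum the elapsed
#' time from baseline (hours) enters as a continuous regressor, centered
#' within subject, with a diagnosis-by-time interaction.
#'
#' @param data tibble with `subject_id`, `diagnosis`, `value`,
#'   `elapsed_hours` (plus covariate columns)
#' @param covariates subject-level covariates for the between stratum
#' @param min_obs minimum observations per retained subject (default 2)
#' @return effect table as in [rm_anova()] (no `p_gg`: the continuous
#'   regressor has a single numerator df)
#' @export
elapsed_time_model <- function(data, covariates = c("age", "sex"),
                               min_obs = 2) {
  stopifnot(all(c("subject_id", "diagnosis", "value", "elapsed_hours")
                %in% names(data)))
  counts <- table(data$subject_id)
  keep <- names(counts)[counts >= min_obs]
  dropped <- setdiff(names(counts), keep)
  d <- data[data$subject_id %in% keep, ]
  if (length(keep) < 4)
    stop_bad_arg("need at least 4 subjects with >= %d observations", min_obs)
  d <- dplyr::arrange(d, .data$subject_id, .data$elapsed_hours)
  subj_info <- d |> dplyr::distinct(.data$subject_id, .keep_all = TRUE)
  g <- factor(subj_info$diagnosis)
  n_groups <- nlevels(droplevels(g))
  m_i <- tapply(d$value, d$subject_id, mean)[as.character(subj_info$subject_id)]
  n_obs_i <- as.vector(counts[as.character(subj_info$subject_id)])
  k_eff <- mean(n_obs_i)

  subj_tbl <- tibble::tibble(subject_id = subj_info$subject_id,
                             diagnosis = as.character(g), m = as.vector(m_i))
  for (cv in covariates) subj_tbl[[cv]] <- subj_info[[cv]]
  bw <- between_stratum(subj_tbl, k_eff, covariates)

  # within stratum: center value and time within subject
  d <- d |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(dev = .data$value - mean(.data$value),
                  t_c = .data$elapsed_hours - mean(.data$elapsed_hours)) |>
    dplyr::ungroup()
  if (all(abs(d$t_c) < 1e-12)) {
    time_ok <- FALSE
    warning("no within-subject time spread; time effects skipped")
  } else time_ok <- TRUE
  rows <- list()
  for (tm in bw$rows) {
    rows[[length(rows) + 1L]] <- cbind(
      anova_row(tm$effect, tm$ss, tm$df, bw$ss_err / bw$df_err, bw$df_err),
      stratum = "between")
  }
  rows[[length(rows) + 1L]] <- cbind(
    tibble::tibble(effect = "subjects(error)", sum_sq = bw$ss_err,
                   df = bw$df_err, F = NA_real_, p = NA_real_,
                   p_gg = NA_real_), stratum = "between")
  if (time_ok) {
    diag_num <- as.numeric(factor(d$diagnosis)) - 1
    rss0 <- sum(d$dev^2)
    X_t <- cbind(d$t_c)
    rss_t <- rss_of(X_t, d$dev)
    ss_t <- rss0 - rss_t
    if (n_groups >= 2) {
      X_ti <- cbind(d$t_c, d$t_c * diag_num)
      rss_ti <- rss_of(X_ti, d$dev)
      ss_ti <- rss_t - rss_ti
      df_ti <- n_groups - 1L
      rss_err <- rss_ti
    } else {
      ss_ti <- NA_real_; df_ti <- 0L; rss_err <- rss_t
    }
    df_err <- sum(n_obs_i - 1) - 1L - df_ti
    ms_err <- rss_err / df_err
    rows[[length(rows) + 1L]] <- cbind(
      anova_row("time", ss_t, 1L, ms_err, df_err), stratum = "within")
    if (n_groups >= 2) {
      rows[[length(rows) + 1L]] <- cbind(
        anova_row("diagnosis:time", ss_ti, df_ti, ms_err, df_err),
        stratum = "within")
    }
    rows[[length(rows) + 1L]] <- cbind(
      tibble::tibble(effect = "time:subjects(error)", sum_sq = rss_err,
                     df = df_err, F = NA_real_, p = NA_real_,
                     p_gg = NA_real_), stratum = "within")
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "dropped_subjects") <- dropped
  out
}

#' One-within-factor repeated-measures ANOVA for medication states
#'
#' PD-only design with the within-subject factor medication state
#' (before, after, best). Each subject contributes one value per state,
#' the median over that subject's records in that state; subjects missing
#' a state are excluded and listed in the `dropped_subjects` attribute.
#'
#' @param data tibble with `subject_id`, `medication_state`, `value`
#' @param states the three required state labels
#' @return effect table: medication effect tested against the
#'   state-by-subject residual, with Greenhouse-Geisser-corrected `p_gg`
#' @export
medication_model <- function(data,
                             states = c("before", "after", "best")) {
  stopifnot(all(c("subject_id", "medication_state", "value")
                %in% names(data)))
  d <- data[data$medication_state %in% states, ]
  d$medication_state <- factor(d$medication_state, levels = states)
  prep <- prepare_profiles(d, "medication_state", length(states))
  agg <- prep$agg
  if (length(prep$complete) < 3)
    stop_bad_arg("need at least 3 subjects with all medication states")
  agg <- dplyr::arrange(agg, .data$subject_id, .data$medication_state)
  k <- length(states)
  wide <- matrix(agg$value, ncol = k, byrow = TRUE)
  n <- nrow(wide)
  grand <- mean(wide)
  ss_subj <- k * sum((rowMeans(wide) - grand)^2)
  ss_state <- n * sum((colMeans(wide) - grand)^2)
  ss_tot <- sum((wide - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_state
  df_state <- k - 1L
  df_err <- (n - 1L) * (k - 1L)
  eps <- gg_epsilon(wide)
  out <- dplyr::bind_rows(
    cbind(tibble::tibble(effect = "subjects", sum_sq = ss_subj,
                         df = n - 1L, F = NA_real_, p = NA_real_,
                         p_gg = NA_real_), stratum = "between"),
    cbind(anova_row("medication", ss_state, df_state,
                    ss_err / df_err, df_err, eps), stratum = "within"),
    cbind(tibble::tibble(effect = "medication:subjects(error)",
                         sum_sq = ss_err, df = df_err, F = NA_real_,
                         p = NA_real_, p_gg = NA_real_), stratum = "within"))
  attr(out, "dropped_subjects") <- prep$dropped
  attr(out, "gg_epsilon") <- eps
  out
}
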