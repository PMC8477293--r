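# Feature-table tier of the synthetic cohort: repeated feature values
# with explicit variance components,
#   y_ijk = mu + delta 1[PD] + b_i + lambda_g (k - 1) + m_state + eps_ijk,
#   b_i ~ N(0, var_between),  eps_ijk ~ N(0, var_within),
# so the generating test-retest ICC is var_between/(var_between+var_within)
# and the generating baseline Cohen d is delta (when the total variance is
# standardized to 1).

simulate_cohort_table <- function(config) {
  n <- config$n_pd + config$n_hc
  ids <- sprintf("S%04d", seq_len(n))
  tibble::tibble(
    subject_id = ids,
    diagnosis = c(rep("PD", config$n_pd), rep("HC", config$n_hc)),
    age = round(runif(n, config$age_range[1], config$age_range[2])),
    sex = sample(c("male", "female"), n, replace = TRUE)
  )
}

schedule_hours <- function(config, k) {
  s <- config$schedule
  sdlog <- s$jitter %||% 1.5
  meanlog <- log(s$gap_hours %||% 24) - sdlog^2 / 2
  gaps <- rlnorm(k - 1, meanlog, sdlog)
  start <- runif(1, 0, 24)
  cumsum(c(start, gaps))
}

#' Simulate a long-format feature table with known variance components
#'
#' Generates repeated feature values for a PD/HC cohort under the additive
#' variance-component model described in the package vignette: a
#' standardized group shift, a subject-level random effect, an optional
#' per-repetition drift (optionally group-specific, injecting a
#' diagnosis-by-repetition interaction), medication-state shifts for PD
#' subjects, and residual noise. Session timestamps follow the log-normal
#' inter-session schedule so every retest-lag window is populated.
#'
#' PD subjects' records cycle through the medication states
#' before/after/best by repetition index; HC records carry state `none`.
#'
#' @param config a [sim_config()] object
#' @return tibble with columns `subject_id`, `diagnosis`, `age`, `sex`,
#'   `task`, `record_id`, `feature`, `repetition_index`, `timestamp`
#'   (hours from study start), `elapsed_hours`, `medication_state`,
#'   `value`
#' @export
simulate_feature_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, "feature_table"), {
    cohort <- simulate_cohort_table(config)
    n <- nrow(cohort)
    k <- config$recordings_per_subject
    feats <- config$features
    nf <- length(feats)
    med <- config$medication_effects
    is_pd <- cohort$diagnosis == "PD"

    # session schedule: per-subject start + log-normal gaps (hours)
    s <- config$schedule
    sdlog <- s$jitter %||% 1.5
    meanlog <- log(s$gap_hours %||% 24) - sdlog^2 / 2
    hours <- matrix(0, nrow = k, ncol = n)
    hours[1, ] <- runif(n, 0, 24)
    if (k > 1)
      hours[-1, ] <- matrix(rlnorm(n * (k - 1), meanlog, sdlog),
                            nrow = k - 1)
    hours <- apply(hours, 2, cumsum)
    if (k == 1) hours <- matrix(hours, nrow = 1)
    elapsed <- sweep(hours, 2, hours[1, ])

    # medication states: PD records cycle before/after/best by repetition
    states <- c("before", "after", "best")
    st_pd <- states[(seq_len(k) - 1) %% 3 + 1]
    st <- matrix("none", nrow = k, ncol = n)
    st[, is_pd] <- st_pd
    m_shift <- matrix(0, nrow = k, ncol = n)
    m_shift[, is_pd] <- med[st_pd]

    lam <- vapply(cohort$diagnosis, function(g)
      group_value(config$drift_slope, g), numeric(1))
    gs <- config$group_shift
    delta <- if (is.null(names(gs))) rep(gs[[1]], nf) else rep(0, nf)
    if (!is.null(names(gs))) {
      hit <- feats %in% names(gs)
      delta[hit] <- unlist(gs)[feats[hit]]
    }

    b <- matrix(rnorm(n * nf, 0, sqrt(config$var_between)), nrow = n)
    eps <- array(rnorm(n * k * nf, 0, sqrt(config$var_within)),
                 dim = c(k, n, nf))
    # y[rep, subject, feature]
    vals <- config$mu + eps
    for (fi in seq_len(nf)) {
      vals[, , fi] <- vals[, , fi] +
        matrix(delta[fi] * is_pd + b[, fi], nrow = k, ncol = n,
               byrow = TRUE) +
        outer(seq_len(k) - 1, lam) + m_shift
    }
    rec_ids <- sprintf("%s_r%02d",
                       rep(cohort$subject_id, each = k),
                       rep(seq_len(k), times = n))
    per_rec <- function(x) rep(as.vector(x), times = nf)
    tibble::tibble(
      subject_id = per_rec(matrix(rep(cohort$subject_id, each = k), k)),
      diagnosis = per_rec(matrix(rep(cohort$diagnosis, each = k), k)),
      age = per_rec(matrix(rep(cohort$age, each = k), k)),
      sex = per_rec(matrix(rep(cohort$sex, each = k), k)),
      task = "synthetic",
      record_id = rep(rec_ids, times = nf),
      feature = rep(feats, each = n * k),
      repetition_index = rep(rep(seq_len(k), times = n), times = nf),
      timestamp = per_rec(hours),
      elapsed_hours = per_rec(elapsed),
      medication_state = per_rec(st),
      value = as.vector(vals))
  })
}
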