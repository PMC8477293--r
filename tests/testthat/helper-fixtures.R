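# Shared fixture builders. All fixtures are constructed in code; tests
# freeze expected values computed from independent oracles.

# balanced 2-group x k-repetition long table with known cell structure
balanced_rm_fixture <- function(n_per_group = 4, k = 5, seed = 42,
                                delta = 0.5, rep_slope = 0.2) {
  set.seed(seed)
  d <- expand.grid(subject_id = sprintf("s%02d", seq_len(2 * n_per_group)),
                   repetition_index = seq_len(k),
                   stringsAsFactors = FALSE)
  d$diagnosis <- ifelse(
    as.integer(sub("s", "", d$subject_id)) <= n_per_group, "PD", "HC")
  d$value <- rnorm(nrow(d)) + delta * (d$diagnosis == "PD") +
    rep_slope * d$repetition_index
  d
}

# independent sums-of-squares oracle for the balanced mixed design,
# computed from cell means (no lm/aov machinery)
cell_means_anova_oracle <- function(d, k = 5) {
  subj <- sort(unique(d$subject_id))
  subj_mean <- tapply(d$value, d$subject_id, mean)[subj]
  subj_group <- tapply(d$diagnosis, d$subject_id, `[`, 1)[subj]
  grand <- mean(d$value)
  group_mean <- tapply(d$value, d$diagnosis, mean)
  rep_mean <- tapply(d$value, d$repetition_index, mean)
  cell_mean <- tapply(d$value, list(d$diagnosis, d$repetition_index), mean)
  n_g <- table(subj_group)
  ss_diag <- k * sum(n_g * (group_mean[names(n_g)] - grand)^2)
  ss_subj <- k * sum((subj_mean - group_mean[subj_group])^2)
  n_subj <- length(subj)
  ss_rep <- n_subj * sum((rep_mean - grand)^2)
  ss_cells <- sum(outer(as.vector(n_g), rep(1, k)) *
                    (cell_mean - grand)^2)
  ss_int <- ss_cells - ss_diag - ss_rep
  # residual: y - subj mean - cell mean + group mean
  resid <- d$value - subj_mean[d$subject_id] -
    cell_mean[cbind(d$diagnosis, as.character(d$repetition_index))] +
    group_mean[d$diagnosis]
  list(diagnosis = ss_diag, subjects = ss_subj, repetition = ss_rep,
       interaction = ss_int, error = sum(resid^2))
}

# recording object helpers
motion_record <- function(payload, task, fs = 100, id = "R1",
                          subject = "S1", timestamp = 0, state = "none") {
  list(record_id = id, subject_id = subject, task = task,
       timestamp = timestamp, medication_state = state,
       sampling_rate = fs, payload = payload)
}

sine_payload <- function(freq, dur, fs = 100, amp = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  data.frame(t = t, x = amp * sin(2 * pi * freq * t),
             y = amp * sin(2 * pi * freq * t), z = 0 * t)
}

# event-stream helper with default button geometry
tap_stream <- function(t, x, y,
                       geometry = list(left = c(60, 400, 160, 500),
                                       right = c(200, 400, 300, 500))) {
  assign_buttons(data.frame(t = t, x = x, y = y), geometry)
}

# brute-force two-sided Mann-Whitney p by direct pair counting over all
# group labelings (independent of the package's rank-sum implementation)
mw_permutation_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    g1 <- pooled[idx]; g2 <- pooled[-idx]
    sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  mid <- n1 * length(y) / 2
  all_u <- apply(utils::combn(length(pooled), n1), 2, u_of)
  mean(abs(all_u - mid) >= abs(u_obs - mid) - 1e-12)
}
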