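# Gait and balance feature extraction from windowed tri-axial
# accelerometer recordings (g units, fixed sampling rate).

#' Derived motion signals
#'
#' From a windowed tri-axial acceleration record derives the vector
#' magnitude signal `a`, per-axis position by double integration (with
#' linear detrend and a 0.3 Hz high-pass between the integration steps to
#' bound drift), velocity and acceleration along the path traced by the
#' integrated position.
#'
#' @param payload data frame with columns `t`, `x`, `y`, `z`
#' @param fs sampling rate in Hz
#' @return list: `x`, `y`, `z`, `a` (magnitude), `pos` (n x 3 matrix),
#'   `path_velocity`, `path_acceleration`, `fs`
#' @export
derive_motion <- function(payload, fs) {
  stopifnot(all(c("x", "y", "z") %in% names(payload)))
  x <- payload$x; y <- payload$y; z <- payload$z
  a <- sqrt(x^2 + y^2 + z^2)
  pos <- vapply(list(x, y, z), function(ax) double_integrate(ax, fs),
                numeric(length(x)))
  dpos <- apply(pos, 2, function(p) c(diff(p), 0) * fs)
  path_v <- sqrt(rowSums(dpos^2))
  path_a <- c(diff(path_v), 0) * fs
  list(x = x, y = y, z = z, a = a, pos = pos,
       path_velocity = path_v, path_acceleration = path_a, fs = fs)
}

highpass <- function(x, fs, f_c = 0.3) {
  if (length(x) < 12) return(x - mean(x))
  bf <- signal::butter(2, f_c / (fs / 2), type = "high")
  as.numeric(signal::filtfilt(bf, x))
}

double_integrate <- function(acc, fs, f_c = 0.3) {
  acc <- acc - mean(acc)
  v <- cumsum(acc) / fs
  v <- highpass(v - linear_trend(v), fs, f_c)
  p <- cumsum(v) / fs
  highpass(p - linear_trend(p), fs, f_c)
}

linear_trend <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  fit <- lm.fit(cbind(1, t), x)
  as.numeric(cbind(1, t) %*% fit$coefficients)
}

#' Step detection from a gait window
#'
#' Band-passes the magnitude signal to the locomotor band (0.5-3 Hz) and
#' picks peaks with a minimum inter-peak distance of 0.3 s and a height of
#' at least a quarter of the filtered signal's standard deviation above
#' zero. Returns the step event times in seconds from window start.
#'
#' @param signal numeric acceleration series (magnitude recommended)
#' @param fs sampling rate in Hz
#' @param lb locomotor band in Hz
#' @param min_step_sec minimum step interval in seconds
#' @return numeric vector of step times (possibly empty)
#' @export
detect_steps <- function(signal, fs, lb = c(0.5, 3), min_step_sec = 0.3) {
  x <- signal - mean(signal)
  if (sd(x) == 0) return(numeric(0))
  bf <- signal::butter(2, lb / (fs / 2), type = "pass")
  xf <- as.numeric(signal::filtfilt(bf, x))
  thr <- 0.25 * sd(xf)
  n <- length(xf)
  is_peak <- c(FALSE, xf[2:(n - 1)] > xf[1:(n - 2)] &
                      xf[2:(n - 1)] >= xf[3:n], FALSE) & xf > thr
  cand <- which(is_peak)
  if (!length(cand)) return(numeric(0))
  min_gap <- round(min_step_sec * fs)
  keep <- cand[1]
  for (i in cand[-1]) {
    if (i - keep[length(keep)] >= min_gap) keep <- c(keep, i)
    else if (xf[i] > xf[keep[length(keep)]]) keep[length(keep)] <- i
  }
  (keep - 1) / fs
}

#' Stride interval features
#'
#' A stride spans two successive steps of the same foot, i.e. the interval
#' between alternate step events. `MSI` is the mean stride interval and
#' `strideCov` the coefficient of variation (SD/mean) of the stride
#' intervals. Requires at least 4 detected steps.
#'
#' @param step_series strictly increasing step event times (s)
#' @return list with `MSI` and `strideCov` (both `NA` when < 4 steps)
#' @export
stride_features <- function(step_series) {
  if (length(step_series) < 4)
    return(list(MSI = NA_real_, strideCov = NA_real_))
  strides <- diff(step_series, lag = 2)
  msi <- mean(strides)
  list(MSI = msi,
       strideCov = if (msi > 0 && length(strides) >= 2)
         sd(strides) / msi else NA_real_)
}

#' Sample-moment features of a windowed series
#'
#' Standard descriptive features used throughout the accelerometer feature
#' families: mean, minimum, interquartile range, skewness, excess
#' kurtosis, zero-crossing rate (sign changes per second, after mean
#' removal) and root mean square (after mean removal).
#'
#' @param x numeric series
#' @param fs sampling rate in Hz (needed for `zcr`)
#' @return named list; `skew`/`kur` are `NA` for a constant series
#' @export
moment_features <- function(x, fs) {
  ok <- is.finite(x)
  x <- x[ok]
  n <- length(x)
  if (n < 4) stop_bad_arg("series too short for moment features")
  xc <- x - mean(x)
  const <- sd(x) == 0
  sgn <- sign(xc[xc != 0])
  zc <- if (length(sgn) > 1) sum(diff(sgn) != 0) else 0
  list(mean = mean(x), min = min(x),
       iqr = unname(diff(quantile(x, c(0.25, 0.75)))),
       skew = if (const) NA_real_ else e1071::skewness(x, type = 2),
       kur = if (const) NA_real_ else e1071::kurtosis(x, type = 2),
       zcr = zc / (n / fs),
       rms = sqrt(mean(xc^2)))
}

motion_row <- function(record_id, name, value) {
  tibble::tibble(record_id = record_id, feature = name,
                 value = as.numeric(value %||% NA_real_))
}

spectral_feature_rows <- function(record_id, prefix, x, fs) {
  sp <- welch_psd(x, fs)
  ss <- spectral_summaries(sp)
  nyq <- max(sp$freq)
  bands <- list(post = c(0, 3.5), trem = c(4, 7), Power = c(3.5, 15),
                TotalPower = c(3.5, 15), VHF = c(7, nyq))
  rows <- purrr::imap(bands, function(b, nm)
    motion_row(record_id, paste0(prefix, ".", nm),
               band_power(sp, f_lo = b[1], f_hi = min(b[2], nyq))))
  rows <- c(rows, purrr::imap(ss, function(v, nm)
    motion_row(record_id, paste0(prefix, ".", nm), v)))
  dplyr::bind_rows(rows)
}

#' Gait features from one windowed recording
#'
#' Extracts the curated gait feature family: moment features of the
#' magnitude signal, freeze-index metrics, peak-frequency summaries,
#' stride-interval features from detected steps, and moment features of
#' the integrated path velocity and path acceleration. Feature names are
#' namespaced `gait.<feature>.<signal>`.
#'
#' @param payload data frame `t`, `x`, `y`, `z` (windowed, g units)
#' @param fs sampling rate in Hz
#' @param record_id identifier attached to the output rows
#' @return tibble `record_id`, `feature`, `value`
#' @export
extract_gait_features <- function(payload, fs, record_id = NA_character_) {
  dm <- derive_motion(payload, fs)
  rows <- list()
  for (sig in c("a", "y")) {
    mm <- moment_features(dm[[sig]], fs)
    for (nm in names(mm))
      rows[[length(rows) + 1L]] <-
        motion_row(record_id, paste0("gait.", nm, ".", sig), mm[[nm]])
  }
  fz <- freeze_metrics(dm$a, fs)
  for (nm in names(fz))
    rows[[length(rows) + 1L]] <-
      motion_row(record_id, paste0("gait.", nm, ".a"), fz[[nm]])
  ss <- spectral_summaries(dm$a, fs)
  for (nm in c("frec_peak", "PeakEnerg", "F50"))
    rows[[length(rows) + 1L]] <-
      motion_row(record_id, paste0("gait.", nm, ".a"), ss[[nm]])
  steps <- detect_steps(dm$a, fs)
  st <- stride_features(steps)
  rows[[length(rows) + 1L]] <- motion_row(record_id, "gait.MSI", st$MSI)
  rows[[length(rows) + 1L]] <- motion_row(record_id, "gait.strideCov",
                                          st$strideCov)
  for (sig in c("path_velocity", "path_acceleration")) {
    short <- if (sig == "path_velocity") "vel" else "pacc"
    mm <- moment_features(dm[[sig]], fs)
    for (nm in c("rms", "iqr"))
      rows[[length(rows) + 1L]] <-
        motion_row(record_id, paste0("gait.", nm, ".", short), mm[[nm]])
  }
  dplyr::bind_rows(rows)
}

#' Balance features from one windowed recording
#'
#' Postural-sway and tremor spectral features per axis: band powers
#' (postural 0-3.5 Hz, tremor 4-7 Hz, 3.5-15 Hz `Power`/`TotalPower`,
#' very-high-frequency above 7 Hz), spectral summaries (`F50`, `CFREQ`,
#' `FRQD`, `frec_peak`, `PeakEnerg`, `RHL`) and `rms`/`iqr` moments, for
#' the magnitude signal and the mediolateral axis. Names are namespaced
#' `bal.<feature>.<signal>`.
#'
#' @inheritParams extract_gait_features
#' @return tibble `record_id`, `feature`, `value`
#' @export
extract_balance_features <- function(payload, fs, record_id = NA_character_) {
  dm <- derive_motion(payload, fs)
  rows <- list()
  for (sig in c("a", "x")) {
    rows[[length(rows) + 1L]] <-
      spectral_feature_rows(record_id, paste0("bal.", sig), dm[[sig]], fs)
    mm <- moment_features(dm[[sig]], fs)
    for (nm in c("rms", "iqr"))
      rows[[length(rows) + 1L]] <-
        motion_row(record_id, paste0("bal.", nm, ".", sig), mm[[nm]])
  }
  dplyr::bind_rows(rows)
}
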