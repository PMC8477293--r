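# Sustained-phonation feature extraction: fundamental frequency and
# cycle-level perturbation (shimmer, jitter), a closed-phase proxy, and
# mel-frequency cepstral summaries.

frame_matrix <- function(x, frame, hop) {
  n <- length(x)
  if (n < frame) return(NULL)
  starts <- seq(1, n - frame + 1, by = hop)
  matrix(x[outer(seq_len(frame) - 1L, starts, `+`)], nrow = frame)
}

#' Fundamental-frequency and cycle tracks of a phonation
#'
#' Frame-wise F0 by the normalized autocorrelation peak within the
#' 75-500 Hz pitch range (40 ms frames, 20 ms hop); a frame is voiced when
#' the peak autocorrelation ratio reaches `voicing_threshold`. Cycle-level
#' period and peak-amplitude tracks are then obtained by F0-guided peak
#' picking on the waveform: one positive peak per glottal cycle, with a
#' minimum peak distance of 80% of the median period.
#'
#' @param waveform numeric mono samples in `[-1, 1]`
#' @param fs sampling rate in Hz
#' @param f_range pitch search range in Hz (default 75-500)
#' @param voicing_threshold autocorrelation peak ratio for the voicing
#'   decision (default 0.45)
#' @return list: `f0_track` (Hz, `NA` on unvoiced frames), `voiced`
#'   (logical per frame), `peak_times` (s), `amplitude_track` (per-cycle
#'   peak amplitude), `period_track` (s per cycle). All tracks empty/`NA`
#'   for fully unvoiced input.
#' @export
extract_f0 <- function(waveform, fs, f_range = c(75, 500),
                       voicing_threshold = 0.45) {
  frame <- round(0.040 * fs); hop <- round(0.020 * fs)
  fm <- frame_matrix(waveform, frame, hop)
  if (is.null(fm)) stop_bad_arg("waveform shorter than one analysis frame")
  fm <- sweep(fm, 2, colMeans(fm))
  # linear (non-circular) autocorrelation needs frame + max lag samples
  nfft <- 2^ceiling(log2(frame + ceiling(fs / f_range[1]) + 1))
  padded <- rbind(fm, matrix(0, nfft - frame, ncol(fm)))
  spec <- mvfft(padded)
  acf <- Re(mvfft(spec * Conj(spec), inverse = TRUE)) / nfft
  lag_min <- max(2L, floor(fs / f_range[2]))
  lag_max <- min(frame - 1L, ceiling(fs / f_range[1]))
  r0 <- acf[1, ]
  ratio <- sweep(acf[(lag_min + 1):(lag_max + 1), , drop = FALSE], 2,
                 pmax(r0, .Machine$double.eps), `/`)
  best <- apply(ratio, 2, which.max)
  best_r <- ratio[cbind(best, seq_along(best))]
  voiced <- is.finite(best_r) & best_r >= voicing_threshold & r0 > 0
  lag <- best + lag_min - 1L
  # parabolic interpolation of the autocorrelation peak
  lag_i <- vapply(seq_along(lag), function(j) {
    l <- lag[j]
    if (!voiced[j] || l <= lag_min || l >= lag_max) return(as.numeric(l))
    y1 <- acf[l, j]; y2 <- acf[l + 1, j]; y3 <- acf[l + 2, j]
    den <- y1 - 2 * y2 + y3
    if (abs(den) < .Machine$double.eps) return(as.numeric(l))
    l + 0.5 * (y1 - y3) / den
  }, numeric(1))
  f0 <- ifelse(voiced, fs / lag_i, NA_real_)
  if (!any(voiced)) {
    return(list(f0_track = f0, voiced = voiced, peak_times = numeric(0),
                amplitude_track = numeric(0), period_track = numeric(0)))
  }
  med_f0 <- median(f0[voiced])
  min_gap <- max(2L, round(0.8 * fs / med_f0))
  x <- waveform
  n <- length(x)
  thr <- 0.2 * quantile(abs(x), 0.95)
  is_peak <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] &
                      x[2:(n - 1)] >= x[3:n], FALSE) & x > thr
  cand <- which(is_peak)
  if (length(cand) > 1) {
    keep <- cand[1]
    for (i in cand[-1]) {
      if (i - keep[length(keep)] >= min_gap) keep <- c(keep, i)
      else if (x[i] > x[keep[length(keep)]]) keep[length(keep)] <- i
    }
  } else keep <- cand
  # sub-sample refinement of peak time and height (parabolic fit through
  # the peak and its neighbours) so cycle periods are not quantized to
  # the sample grid
  pk_t <- (keep - 1) / fs
  pk_a <- x[keep]
  inner <- keep > 1 & keep < n
  if (any(inner)) {
    i <- keep[inner]
    y1 <- x[i - 1]; y2 <- x[i]; y3 <- x[i + 1]
    den <- y1 - 2 * y2 + y3
    dt <- ifelse(abs(den) > .Machine$double.eps, 0.5 * (y1 - y3) / den, 0)
    dt <- pmin(pmax(dt, -0.5), 0.5)
    pk_t[inner] <- (i - 1 + dt) / fs
    pk_a[inner] <- y2 - 0.25 * (y1 - y3) * dt
  }
  list(f0_track = f0, voiced = voiced,
       peak_times = pk_t,
       amplitude_track = pk_a,
       period_track = diff(pk_t))
}

#' Cycle-to-cycle perturbation features
#'
#' Relative mean absolute consecutive difference of the per-cycle
#' amplitude (shimmer) and period (jitter) tracks, and the 95th percentile
#' of the amplitude track. Both perturbation measures are scale-invariant
#' and non-negative; at least `min_cycles` cycles are required.
#'
#' @param amplitude_track per-cycle peak amplitudes
#' @param period_track per-cycle periods in seconds
#' @param min_cycles minimum number of cycles (default 10)
#' @return list `shimmer`, `jitter`, `p95`
#' @export
perturbation_features <- function(amplitude_track, period_track,
                                  min_cycles = 10) {
  na <- list(shimmer = NA_real_, jitter = NA_real_, p95 = NA_real_)
  if (length(amplitude_track) < min_cycles ||
      length(period_track) < min_cycles - 1) return(na)
  a <- amplitude_track; tt <- period_track
  shimmer <- mean(abs(diff(a))) / mean(a)
  jitter <- mean(abs(diff(tt))) / mean(tt)
  list(shimmer = shimmer, jitter = jitter,
       p95 = unname(quantile(a, 0.95)))
}

#' Closed-phase fraction proxy ("glottis quotient close")
#'
#' Fraction of each glottal cycle during which the absolute waveform is
#' below 10% of that cycle's peak amplitude, averaged over cycles. This is
#' a proxy for the closed-glottis quotient computed directly from the
#' acoustic waveform rather than from glottal inverse filtering; output
#' metadata labels it as such.
#'
#' @param waveform numeric mono samples
#' @param fs sampling rate in Hz
#' @param peak_times per-cycle peak times from [extract_f0()]
#' @return fraction in `[0, 1]`, `NA` with fewer than 4 cycle peaks
#' @export
gqc_proxy <- function(waveform, fs, peak_times) {
  if (length(peak_times) < 4) return(NA_real_)
  idx <- round(peak_times * fs) + 1
  fracs <- vapply(seq_len(length(idx) - 1), function(i) {
    seg <- waveform[idx[i]:(idx[i + 1] - 1)]
    pk <- max(abs(seg))
    if (pk == 0) return(NA_real_)
    mean(abs(seg) < 0.1 * pk)
  }, numeric(1))
  mean(fracs, na.rm = TRUE)
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

mel_filterbank <- function(n_filters, nfft, fs) {
  mels <- seq(hz_to_mel(0), hz_to_mel(fs / 2), length.out = n_filters + 2)
  hz <- mel_to_hz(mels)
  bins <- floor((nfft + 1) * hz / fs)
  fb <- matrix(0, n_filters, nfft %/% 2 + 1)
  for (m in seq_len(n_filters)) {
    lo <- bins[m]; ce <- bins[m + 1]; hi <- bins[m + 2]
    for (k in seq(lo, hi)) {
      if (k < ce && ce > lo) fb[m, k + 1] <- (k - lo) / (ce - lo)
      else if (k >= ce && hi > ce) fb[m, k + 1] <- (hi - k) / (hi - ce)
    }
  }
  fb
}

dct_ii_matrix <- function(n_out, n_in) {
  outer(0:(n_out - 1), 0:(n_in - 1), function(i, j)
    cos(pi * i * (2 * j + 1) / (2 * n_in))) * sqrt(2 / n_in)
}

#' Mel-frequency cepstral coefficients
#'
#' 13 MFCCs per frame (25 ms frames, 10 ms hop, Hamming window, 26
#' triangular mel filters up to Nyquist, orthogonality-scaled DCT-II of
#' the log filterbank energies), plus the framewise log energy and
#' first/second temporal derivatives (2-frame regression deltas).
#'
#' @param waveform numeric mono samples
#' @param fs sampling rate in Hz
#' @param n_mfcc number of cepstral coefficients (default 13)
#' @param n_filters number of mel filters (default 26)
#' @return list: `mfcc` (coefficients x frames), `log_energy` (per
#'   frame), `delta`, `delta2` (same shape as `mfcc`)
#' @export
mfcc <- function(waveform, fs, n_mfcc = 13, n_filters = 26) {
  frame <- round(0.025 * fs); hop <- round(0.010 * fs)
  fm <- frame_matrix(waveform, frame, hop)
  if (is.null(fm)) return(NULL)
  log_energy <- log(pmax(colSums(fm^2), .Machine$double.xmin))
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(frame) - 1) / (frame - 1))
  fm <- fm * w
  nfft <- 2^ceiling(log2(frame))
  padded <- rbind(fm, matrix(0, nfft - frame, ncol(fm)))
  pow <- Mod(mvfft(padded))^2 / nfft
  pow <- pow[seq_len(nfft %/% 2 + 1), , drop = FALSE]
  fb <- mel_filterbank(n_filters, nfft, fs)
  melE <- log(pmax(fb %*% pow, .Machine$double.xmin))
  D <- dct_ii_matrix(n_mfcc, n_filters)
  cc <- D %*% melE
  delta_of <- function(m) {
    nf <- ncol(m)
    if (nf < 5) return(m * 0)
    pad <- cbind(m[, 1], m[, 1], m, m[, nf], m[, nf])
    (2 * (pad[, 5:(nf + 4), drop = FALSE] - pad[, 1:nf, drop = FALSE]) +
       (pad[, 4:(nf + 3), drop = FALSE] - pad[, 2:(nf + 1), drop = FALSE])) / 10
  }
  d1 <- delta_of(cc)
  list(mfcc = cc, log_energy = log_energy, delta = d1, delta2 = delta_of(d1))
}

#' Cepstral summary features of a phonation
#'
#' Temporal means of the 13 MFCCs (`c_mean.0` .. `c_mean.12`), of the
#' framewise log energy, and of the first and second log-energy
#' derivatives.
#'
#' @inheritParams mfcc
#' @return named list, or all-`NA` when the waveform is shorter than one
#'   frame
#' @export
cepstral_features <- function(waveform, fs) {
  mf <- mfcc(waveform, fs)
  if (is.null(mf)) {
    out <- as.list(rep(NA_real_, 16))
    names(out) <- c(paste0("c_mean.", 0:12), "log.energy",
                    "log.denergy", "log.d2energy")
    return(out)
  }
  means <- rowMeans(mf$mfcc)
  le <- mf$log_energy
  d1 <- if (length(le) > 1) diff(le) else 0
  d2 <- if (length(d1) > 1) diff(d1) else 0
  out <- c(as.list(means), mean(le), mean(abs(d1)), mean(abs(d2)))
  names(out) <- c(paste0("c_mean.", 0:12), "log.energy",
                  "log.denergy", "log.d2energy")
  out
}

#' Voice features from one trimmed phonation window
#'
#' Runs the F0/cycle tracker, perturbation features, the closed-phase
#' proxy and the cepstral summaries; emits long-format rows namespaced
#' `voice.*`. The closed-phase proxy is emitted as `voice.gqc_proxy` to
#' flag that it is an acoustic-waveform proxy.
#'
#' @param waveform numeric mono samples
#' @param fs sampling rate in Hz
#' @param record_id identifier attached to the output rows
#' @return tibble `record_id`, `feature`, `value`
#' @export
extract_voice_features <- function(waveform, fs, record_id = NA_character_) {
  tr <- extract_f0(waveform, fs)
  pert <- perturbation_features(tr$amplitude_track, tr$period_track)
  vals <- list(
    shbd = pert$shimmer, jitter = pert$jitter, p95 = pert$p95,
    gqc_proxy = gqc_proxy(waveform, fs, tr$peak_times),
    f0_mean = if (any(tr$voiced)) mean(tr$f0_track[tr$voiced]) else NA_real_,
    f0_sd = if (sum(tr$voiced) > 1) sd(tr$f0_track[tr$voiced]) else NA_real_)
  vals <- c(vals, cepstral_features(waveform, fs))
  dplyr::bind_rows(purrr::imap(vals, function(v, nm)
    tibble::tibble(record_id = record_id, feature = paste0("voice.", nm),
                   value = as.numeric(v %||% NA_real_))))
}
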