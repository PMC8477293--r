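# Spectral estimation for accelerometer windows.
#
# Welch's averaged periodogram (Hann window, 50% overlap, 5 s segments)
# is the production estimator; it trades the exact Parseval identity of
# the full-length rectangular periodogram for variance reduction on the
# short, noisy windows produced by phone sensors.

#' Welch power spectral density
#'
#' One-sided PSD of a uniformly sampled series, averaged over
#' Hann-windowed segments with 50% overlap. The PSD is a density
#' (units^2 per Hz): summing `psd * df` over all frequencies approximates
#' the variance of the (detrended) signal.
#'
#' @param x numeric series
#' @param fs sampling rate (Hz)
#' @param segment_sec segment length in seconds (default 5); shortened to
#'   the full series when the series is shorter
#' @param detrend remove the series mean first (default TRUE)
#' @return list with `freq` (Hz) and `psd` (one-sided density)
#' @export
welch_psd <- function(x, fs, segment_sec = 5, detrend = TRUE) {
  n <- length(x)
  if (n < 8) stop_bad_arg("series too short for spectral estimation")
  if (detrend) x <- x - mean(x)
  nseg <- min(n, round(segment_sec * fs))
  step <- max(1, floor(nseg / 2))
  starts <- seq(1, n - nseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  u <- sum(w^2)                                # window power normalization
  nfreq <- floor(nseg / 2)
  acc <- numeric(nfreq + 1)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(fft(seg))^2 / (u * fs)
    half <- sp[seq_len(nfreq + 1)]
    acc <- acc + half
  }
  psd <- acc / length(starts)
  # fold negative frequencies into the one-sided density
  if (nseg %% 2 == 0) {
    psd[2:nfreq] <- 2 * psd[2:nfreq]
  } else {
    psd[2:(nfreq + 1)] <- 2 * psd[2:(nfreq + 1)]
  }
  list(freq = (0:nfreq) * fs / nseg, psd = psd)
}

#' Band power from a PSD
#'
#' Integrates the one-sided PSD over the half-open band `(f_lo, f_hi]` by
#' the rectangle rule on the PSD bins, so that adjacent bands partition
#' the spectrum without double counting.
#'
#' @param x numeric series (or a precomputed PSD list with `freq`, `psd`)
#' @param fs sampling rate (ignored when `x` is a PSD list)
#' @param f_lo,f_hi band edges in Hz; must satisfy
#'   `0 <= f_lo < f_hi <= fs/2`
#' @param ... passed on to [welch_psd()]
#' @return band power in signal units squared
#' @export
band_power <- function(x, fs = NULL, f_lo, f_hi, ...) {
  sp <- if (is.list(x) && all(c("freq", "psd") %in% names(x))) x
        else welch_psd(x, fs, ...)
  nyq <- max(sp$freq)
  if (f_lo < 0 || f_hi <= f_lo || f_hi > nyq + 1e-9)
    stop_bad_arg("band [%g, %g] outside (0, Nyquist=%g]", f_lo, f_hi, nyq)
  df <- sp$freq[2] - sp$freq[1]
  # half-open (f_lo, f_hi] so that adjacent bands partition the spectrum
  sel <- sp$freq > f_lo & sp$freq <= f_hi
  sum(sp$psd[sel]) * df
}

#' Spectral summary features
#'
#' Distribution summaries of the PSD mass over frequency: `F50` (median
#' frequency: 50% of total power below), `CFREQ` (power-weighted mean
#' frequency, the spectral centroid), `FRQD` (power-weighted SD around
#' CFREQ, the dispersion of the spectrum), `frec_peak` and `PeakEnerg`
#' (location and height of the PSD maximum), and `RHL` (ratio of power
#' above 4 Hz to power in 0.15-3.5 Hz).
#'
#' @param x numeric series or PSD list
#' @param fs sampling rate in Hz
#' @param ... passed to [welch_psd()]
#' @return named list; all elements `NA` for an all-zero signal
#' @export
spectral_summaries <- function(x, fs = NULL, ...) {
  sp <- if (is.list(x) && all(c("freq", "psd") %in% names(x))) x
        else welch_psd(x, fs, ...)
  f <- sp$freq; p <- sp$psd
  tot <- sum(p)
  if (!is.finite(tot) || tot <= 0) {
    return(list(F50 = NA_real_, CFREQ = NA_real_, FRQD = NA_real_,
                frec_peak = NA_real_, PeakEnerg = NA_real_, RHL = NA_real_))
  }
  cum <- cumsum(p) / tot
  # first frequency bin at which half the total power is contained;
  # symmetric leakage around a spectral line then leaves F50 on the line
  F50 <- f[which(cum >= 0.5)[1]]
  cfreq <- sum(f * p) / tot
  frqd <- sqrt(sum((f - cfreq)^2 * p) / tot)
  ipk <- which.max(p)
  dfq <- f[2] - f[1]
  nyq <- max(f)
  lf <- band_power(sp, f_lo = 0.15, f_hi = 3.5)
  hf <- band_power(sp, f_lo = 4, f_hi = nyq)
  rhl <- if (lf > 0) hf / lf else NA_real_
  list(F50 = F50, CFREQ = cfreq, FRQD = frqd,
       frec_peak = f[ipk], PeakEnerg = p[ipk], RHL = rhl)
}

#' Freeze-index metrics for gait
#'
#' `FreezeInd` is the ratio of accelerometer power in the freezing band
#' (3-8 Hz) to the locomotor band (0.5-3 Hz); `RatioPower` is their sum.
#' The individual band powers are returned as `FB_power` and `LB_power`.
#'
#' @param x windowed gait series (or PSD list)
#' @param fs sampling rate in Hz
#' @param fb,lb band limits in Hz
#' @param ... passed to [welch_psd()]
#' @return named list; `FreezeInd` is `NA` when the locomotor power is 0
#' @export
freeze_metrics <- function(x, fs = NULL, fb = c(3, 8), lb = c(0.5, 3), ...) {
  sp <- if (is.list(x) && all(c("freq", "psd") %in% names(x))) x
        else welch_psd(x, fs, ...)
  fbp <- band_power(sp, f_lo = fb[1], f_hi = fb[2])
  lbp <- band_power(sp, f_lo = lb[1], f_hi = lb[2])
  list(FreezeInd = if (lbp > 0) fbp / lbp else NA_real_,
       RatioPower = fbp + lbp, FB_power = fbp, LB_power = lbp)
}
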