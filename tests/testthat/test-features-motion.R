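# Spectral, freeze-index, step and moment features from accelerometer
# windows.

fs <- 100
t15 <- seq(0, 15 - 1 / fs, by = 1 / fs)

test_that("band power matches the analytic sine power and an FFT oracle", {
  x <- sin(2 * pi * 5 * t15)
  expect_lt(abs(band_power(x, fs, 4, 7) - 0.5) / 0.5, 0.05)
  expect_equal(band_power(rep(0, 1500), fs, 4, 7), 0)
  expect_error(band_power(x, fs, 40, 60), "Nyquist")
  # full-length rectangular periodogram oracle for a two-tone signal
  x2 <- 2 * sin(2 * pi * 1 * t15) + sin(2 * pi * 5 * t15)
  pg <- Mod(fft(x2 - mean(x2)))^2 / (length(x2) * fs)
  freq <- (seq_along(x2) - 1) * fs / length(x2)
  oracle_bp <- function(lo, hi) 2 * sum(pg[freq > lo & freq <= hi &
                                             freq <= fs / 2]) * (fs / length(x2))
  expect_lt(abs(band_power(x2, fs, 0.5, 3) - oracle_bp(0.5, 3)) /
              oracle_bp(0.5, 3), 0.05)
  expect_lt(abs(band_power(x2, fs, 4, 7) - oracle_bp(4, 7)) /
              oracle_bp(4, 7), 0.05)
  expect_lt(abs(oracle_bp(0.5, 3) - 2), 0.01)   # A^2/2 with A = 2
  expect_lt(abs(oracle_bp(4, 7) - 0.5), 0.01)
})

test_that("disjoint band powers add up to the signal variance", {
  set.seed(7)
  x <- 2 * sin(2 * pi * 1.3 * t15) + sin(2 * pi * 6.1 * t15) +
    rnorm(length(t15), 0, 0.3)
  edges <- c(0, 2, 4, 8, 16, 32, 50)
  total <- sum(vapply(seq_len(length(edges) - 1), function(i)
    band_power(x, fs, edges[i], edges[i + 1]), numeric(1)))
  expect_lt(abs(total - var(x)) / var(x), 0.02)
})

test_that("spectral summaries locate pure and mixed tones", {
  x <- sin(2 * pi * 5 * t15)
  ss <- spectral_summaries(x, fs)
  expect_equal(ss$F50, 5, tolerance = 0.05)
  expect_equal(ss$CFREQ, 5, tolerance = 0.01)
  expect_equal(ss$frec_peak, 5, tolerance = 0.05)
  expect_lt(ss$FRQD, 0.5)
  # equal-power tones at 2 and 6 Hz: centroid at the midpoint
  x2 <- sin(2 * pi * 2 * t15) + sin(2 * pi * 6 * t15)
  expect_equal(spectral_summaries(x2, fs)$CFREQ, 4, tolerance = 0.05)
  # white noise: flat spectrum, median frequency near fs/4
  set.seed(1)
  xn <- rnorm(30 * fs)
  expect_equal(spectral_summaries(xn, fs)$F50, fs / 4, tolerance = 2)
  # all-zero signal: undefined, emitted as missing
  z <- spectral_summaries(rep(0, 1500), fs)
  expect_true(all(is.na(unlist(z))))
})

test_that("freeze index separates locomotor and freezing content", {
  lb_only <- sin(2 * pi * 1 * t15)
  fb_only <- sin(2 * pi * 5 * t15)
  mix <- sin(2 * pi * 1 * t15) + sin(2 * pi * 5 * t15)
  expect_lt(freeze_metrics(lb_only, fs)$FreezeInd, 0.05)
  expect_gt(freeze_metrics(fb_only, fs)$FreezeInd, 10)
  expect_equal(freeze_metrics(mix, fs)$FreezeInd, 1, tolerance = 0.1)
  # monotone in freezing-band amplitude
  fi <- vapply(c(0.5, 1, 2), function(a)
    freeze_metrics(sin(2 * pi * 1 * t15) + a * sin(2 * pi * 5 * t15),
                   fs)$FreezeInd, numeric(1))
  expect_true(all(diff(fi) > 0))
})

test_that("features respond correctly to offset and amplitude scaling", {
  set.seed(3)
  x <- sin(2 * pi * 2 * t15) + rnorm(length(t15), 0, 0.1)
  base_bp <- band_power(x, fs, 1, 3)
  base_ss <- spectral_summaries(x, fs)
  # constant offset: removed by detrending
  expect_equal(band_power(x + 5, fs, 1, 3), base_bp, tolerance = 1e-10)
  # amplitude scaling: power quadratic, frequency summaries invariant
  expect_equal(band_power(3 * x, fs, 1, 3) / base_bp, 9, tolerance = 1e-6)
  ss3 <- spectral_summaries(3 * x, fs)
  expect_equal(ss3$F50, base_ss$F50)
  expect_equal(ss3$CFREQ, base_ss$CFREQ, tolerance = 1e-10)
  mm <- moment_features(x, fs)
  mm3 <- moment_features(3 * x, fs)
  expect_equal(mm3$rms / mm$rms, 3, tolerance = 1e-10)
})

test_that("step detection recovers periodic cadence", {
  # impulse train every 0.5 s: stride = alternate steps = 1.0 s
  imp <- rep(0, length(t15))
  imp[seq(1, length(imp), by = 50)] <- 1
  steps <- detect_steps(imp, fs)
  iv <- diff(steps)
  expect_equal(median(iv), 0.5, tolerance = 0.02)
  st <- stride_features(steps)
  expect_equal(st$MSI, 1.0, tolerance = 0.05)
  expect_lt(st$strideCov, 0.05)
  # 2 Hz sinusoidal cadence
  s2 <- sin(2 * pi * 2 * t15)
  st2 <- stride_features(detect_steps(s2, fs))
  expect_equal(st2$MSI, 1.0, tolerance = 0.05)
  # flat signal: no steps, stride features missing
  expect_length(detect_steps(rep(0.5, 1500), fs), 0)
  expect_true(is.na(stride_features(numeric(0))$MSI))
})

test_that("moment features match closed forms and moment oracles", {
  x <- sin(2 * pi * 1 * seq(0, 10 - 1 / fs, by = 1 / fs))
  mm <- moment_features(x, fs)
  expect_equal(mm$rms, sqrt(0.5), tolerance = 1e-3)
  expect_equal(mm$zcr, 2, tolerance = 0.05)
  set.seed(11)
  g <- rnorm(1e5)
  mg <- moment_features(g, fs)
  expect_lt(abs(mg$skew), 0.05)
  expect_lt(abs(mg$kur), 0.05)   # excess kurtosis
  mc <- moment_features(rep(2, 100), fs)
  expect_equal(mc$iqr, 0)
  expect_true(is.na(mc$skew) && is.na(mc$kur))
})

test_that("derived motion signals and extractors produce full feature rows", {
  set.seed(9)
  cfg <- sim_config(seed = 9)
  g <- dbstability:::synth_gait(cfg$task_params$gait, fs, 0.3, 1.7, 0.05)
  rec <- window_record(motion_record(g, "gait", id = "G1"))
  rows <- extract_gait_features(rec$payload, fs, "G1")
  expect_true(all(c("gait.FreezeInd.a", "gait.MSI", "gait.rms.vel",
                    "gait.kur.a", "gait.zcr.y") %in% rows$feature))
  expect_false(any(duplicated(rows$feature)))
  # cadence recovered through step detection
  msi <- rows$value[rows$feature == "gait.MSI"]
  expect_equal(msi, 2 / 1.7, tolerance = 0.15)
  b <- dbstability:::synth_balance(cfg$task_params$balance, fs,
                                   0.05, 0.04, 5.5, 0.02)
  recb <- window_record(motion_record(b, "balance", id = "B1"))
  rowsb <- extract_balance_features(recb$payload, fs, "B1")
  expect_true(all(c("bal.a.trem", "bal.x.post", "bal.a.RHL",
                    "bal.a.CFREQ", "bal.rms.x") %in% rowsb$feature))
  # tremor band power dominated by the injected 5.5 Hz component
  expect_gt(rowsb$value[rowsb$feature == "bal.x.trem"],
            rowsb$value[rowsb$feature == "bal.x.VHF"])
})
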