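make_optical <- function(hbo, hbr = -0.25 * hbo, rate = 10,
                         wavelengths = c(760, 850), dpf = 6, dist = 30) {
  eps <- extinction_coefficients(wavelengths)
  L <- dist / 10
  od <- rbind(
    (eps[1, "HbO"] * hbo + eps[1, "HbR"] * hbr) * 1e-6 * L * dpf,
    (eps[2, "HbO"] * hbo + eps[2, "HbR"] * hbr) * 1e-6 * L * dpf
  )
  optical_recording(od, rate = rate, wavelengths = wavelengths,
                    pair = c(1, 1), distance_mm = c(dist, dist))
}

test_that("Beer-Lambert conversion inverts the forward mixing", {
  t <- seq(0, 60, by = 0.1)
  hbo <- 0.2 * sin(2 * pi * 1.1 * t)
  opt <- make_optical(hbo)
  hemo <- convert_beer_lambert(opt)
  expect_lt(max(abs(hemo$oxy[1, ] - hbo)) / max(abs(hbo)), 1e-9)
  # zero optical density -> zero concentration
  z <- convert_beer_lambert(make_optical(rep(0, 100)))
  expect_equal(max(abs(z$oxy)), 0)
  # linearity: scaling OD scales concentration
  opt2 <- opt; opt2$samples <- 3 * opt$samples
  hemo2 <- convert_beer_lambert(opt2)
  expect_equal(hemo2$oxy, 3 * hemo$oxy, tolerance = 1e-12)
  # singular extinction matrix rejected
  expect_error(
    convert_beer_lambert(opt, extinction = matrix(1, 2, 2,
      dimnames = list(NULL, c("HbO", "HbR")))), "singular")
})

test_that("cardiac band-pass keeps 1 Hz and attenuates 0.1 Hz by >= 20 dB", {
  t <- seq(0, 120, by = 0.1)
  x <- sin(2 * pi * 1 * t) + sin(2 * pi * 0.1 * t)
  hemo <- structure(list(oxy = rbind(x, x), rate = 10, t0 = 0),
                    class = "hemoglobin_series")
  out <- extract_cardiac_waveform(hemo)
  n <- length(out$x)
  sp <- Mod(stats::fft(out$x))
  f <- (seq_len(n) - 1) * 10 / n
  amp_1hz <- max(sp[abs(f - 1) < 0.02])
  amp_01hz <- max(sp[abs(f - 0.1) < 0.02 & f > 0])
  spin <- Mod(stats::fft(x))
  in_1hz <- max(spin[abs(f - 1) < 0.02])
  in_01hz <- max(spin[abs(f - 0.1) < 0.02 & f > 0])
  expect_gt(amp_1hz / in_1hz, 0.7)               # passband preserved
  expect_lt(amp_01hz / in_01hz, 10^(-20 / 20))   # >= 20 dB down
  expect_lt(abs(mean(out$x)), 1e-8)
  # constant input -> ~zero output
  hemo0 <- structure(list(oxy = matrix(5, 2, 300), rate = 10, t0 = 0),
                     class = "hemoglobin_series")
  expect_lt(max(abs(extract_cardiac_waveform(hemo0)$x)), 1e-8)
  # channel-permutation invariance of the average
  hemo2 <- hemo; hemo2$oxy <- hemo$oxy[c(2, 1), ]
  expect_equal(extract_cardiac_waveform(hemo2)$x, out$x)
  expect_error(extract_cardiac_waveform(
    structure(list(oxy = matrix(1, 2, 50), rate = 10, t0 = 0),
              class = "hemoglobin_series")), "10 s")
})

test_that("zero-crossing beat periods recover pure tones", {
  t <- seq(0, 60, by = 0.1)
  b1 <- detect_beat_periods(sin(2 * pi * 1.0 * t), rate = 10)
  expect_true(all(abs(b1$periods - 1.0) < 0.02))
  hr1 <- heart_rate_series(b1, rate = 10)
  expect_true(all(abs(hr1$hr - 60) < 1.5))
  b2 <- detect_beat_periods(sin(2 * pi * 1.2 * t), rate = 10)
  expect_true(all(abs(b2$periods - 0.8333) < 0.02))
  expect_true(all(abs(60 / b2$periods - 72) < 2))
  # times strictly increasing, periods positive
  expect_true(all(diff(b1$times) > 0))
  expect_true(all(b1$periods > 0))
  # too few crossings -> empty flagged series
  b0 <- detect_beat_periods(rep(0.5, 100), rate = 10)
  expect_length(b0$periods, 0)
  expect_true(isTRUE(attr(b0, "flagged")))
})

test_that("beat tracking follows a linear chirp within 2 percent", {
  rate <- 50
  t <- seq(0, 60, by = 1 / rate)
  f0 <- 0.8; f1 <- 1.5
  k <- (f1 - f0) / 60
  x <- sin(2 * pi * (f0 * t + k * t^2 / 2))
  beats <- detect_beat_periods(x, rate = rate)
  inst_f <- 1 / beats$periods
  true_f <- f0 + k * beats$times       # analytic instantaneous frequency
  rel <- abs(inst_f - true_f) / true_f
  expect_lt(max(rel[beats$times > 2 & beats$times < 58]), 0.02)
})

test_that("heart-rate interpolation is linear with constant extrapolation", {
  beats <- structure(list(times = c(10, 20), periods = c(1.0, 0.5)),
                     class = "beat_series")
  hr <- heart_rate_series(beats, rate = 10, duration = 30)
  expect_equal(hr$hr[hr$t == 15], 90)
  expect_equal(hr$hr[hr$t == 5], 60)    # constant extrapolation left
  expect_equal(hr$hr[hr$t == 25], 120)  # constant extrapolation right
  flat <- structure(list(times = c(1, 2, 3), periods = c(1, 1, 1)),
                    class = "beat_series")
  expect_true(all(heart_rate_series(flat, rate = 10, duration = 4)$hr == 60))
  expect_error(heart_rate_series(
    structure(list(times = 1, periods = 1), class = "beat_series"), rate = 10),
    "two beats")
})

test_that("band powers match a direct-DFT oracle and separate HF from LF", {
  rate <- 10
  t <- seq(0, 60 - 1 / rate, by = 1 / rate)
  hr_hf <- 70 + sin(2 * pi * 0.3 * t)
  bp <- compute_band_powers(hr_hf, rate)
  expect_gt(bp$HF / max(bp$LF, 1e-12), 100)
  t2 <- seq(0, 120 - 1 / rate, by = 1 / rate)
  hr_lf <- 70 + sin(2 * pi * 0.05 * t2)
  bp2 <- compute_band_powers(hr_lf, rate)
  expect_gt(bp2$LF / max(bp2$HF, 1e-12), 100)
  bp0 <- compute_band_powers(rep(70, 600), rate)
  expect_lt(bp0$LF + bp0$HF, 1e-12)
  # oracle equivalence on random segments
  withr::with_seed(8, {
    for (i in 1:5) {
      x <- 70 + cumsum(rnorm(240, 0, 0.3))
      bp <- compute_band_powers(x, rate)
      expect_equal(bp$LF, oracle_band_power(x, rate, 0.01, 0.15), tolerance = 1e-10)
      expect_equal(bp$HF, oracle_band_power(x, rate, 0.15, 0.8), tolerance = 1e-10)
    }
  })
  expect_error(compute_band_powers(rep(70, 50), rate), "too short")
})

test_that("the HRV index is bounded, monotone in HF, and exact on edge cases", {
  expect_equal(compute_hrv(list(LF = 0, HF = 5)), 1)
  expect_equal(compute_hrv(list(LF = 5, HF = 0)), 0)
  expect_equal(compute_hrv(list(LF = 3, HF = 3)), 0.5)
  expect_true(is.na(compute_hrv(list(LF = 0, HF = 0))))
  hf <- seq(0.1, 5, length.out = 50)
  vals <- vapply(hf, function(h) compute_hrv(list(LF = 1.7, HF = h)), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("windowed HRV series has the stated shape and detects RSA loss", {
  rate <- 10
  t <- seq(0, 300 - 1 / rate, by = 1 / rate)
  rsa <- ifelse(t < 150, 3, 0)
  hr <- 70 + rsa * sin(2 * pi * 0.25 * t) + 1.0 * sin(2 * pi * 0.08 * t)
  hs <- compute_hrv_series(hr, rate, window_s = 30, step_s = 1)
  expect_length(hs$t, floor((300 - 30) / 1) + 1)
  first <- hs$hrv[hs$t < 120]
  second <- hs$hrv[hs$t > 180]
  expect_gt(mean(first), mean(second))
  expect_gt(mean(first), 0.9)   # pure-HF-dominated half
  expect_true(all(hs$hrv >= 0 & hs$hrv <= 1, na.rm = TRUE))
  expect_error(compute_hrv_series(hr[1:100], rate, window_s = 30), "window")
})

test_that("episode-mean HR is recovered within 2 bpm and HRV tracks RSA depth", {
  cfg <- simulation_config(n_subjects = 3, seed = 61,
                           layout = default_session_layout(task_s = 120, rest_s = 60))
  co <- simulate_cohort(cfg, include_eeg = FALSE)
  for (b in co) {
    chain <- fnirs_cardiac_chain(b$optical)
    lay <- b$layout
    err <- vapply(seq_len(nrow(lay)), function(e) {
      sel <- chain$hr$t >= lay$start[e] & chain$hr$t < lay$end[e]
      mean(chain$hr$hr[sel]) - mean(b$truth$true_hr[sel])
    }, numeric(1))
    expect_lt(sqrt(mean(err^2)), 2)
  }
})

test_that("episode-mean HR and HRV are anti-correlated across task episodes", {
  cfg <- simulation_config(n_subjects = 12, seed = 77)
  co <- simulate_cohort(cfg, include_eeg = FALSE, include_fnirs = FALSE)
  rows <- do.call(rbind, lapply(co, function(b) {
    ex <- extract_subject_features(b, use_truth = TRUE)
    ex$features[grepl("^Task", ex$features$label), c("hr_mean", "hrv_mean")]
  }))
  expect_lt(cor(rows$hr_mean, rows$hrv_mean), 0)
})
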