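## ---------------------------------------------------------------------------
## Cardiac extraction from fNIRS optics: modified Beer-Lambert conversion,
## 0.5-2 Hz band-pass, zero-crossing beat periods, instantaneous heart rate
## on the acquisition grid, and the spectral HRV index HF / (HF + LF).
## ---------------------------------------------------------------------------

#' Construct an optical recording
#'
#' Container for raw multi-channel, dual-wavelength fNIRS optical-density
#' series. Channels come in wavelength pairs sharing an optode pair.
#'
#' @param samples channels x time matrix of optical-density values (a.u.).
#' @param rate sampling rate (Hz).
#' @param wavelengths wavelength (nm) of each channel.
#' @param pair optode-pair index of each channel.
#' @param distance_mm source-detector separation (mm) per channel.
#' @param t0 start time (s).
#' @return an `optical_recording`.
#' @export
optical_recording <- function(samples, rate, wavelengths, pair,
                              distance_mm, t0 = 0) {
  samples <- as.matrix(samples)
  if (rate <= 0) stopf("rate must be positive")
  if (length(wavelengths) != nrow(samples) || length(pair) != nrow(samples))
    stopf("wavelengths and pair must have one entry per channel")
  for (p in unique(pair))
    if (length(unique(wavelengths[pair == p])) < 2)
      stopf("each optode pair needs two distinct wavelengths")
  structure(list(samples = samples, rate = rate, wavelengths = wavelengths,
                 pair = pair, distance_mm = distance_mm, t0 = t0),
            class = "optical_recording")
}

#' @export
print.optical_recording <- function(x, ...) {
  cat(sprintf("<optical_recording> %d channels (%d pairs) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), length(unique(x$pair)), ncol(x$samples),
              x$rate, ncol(x$samples) / x$rate))
  invisible(x)
}

#' Convert optical density to hemoglobin concentration changes
#'
#' Modified Beer-Lambert law: for each optode pair the 2 x 2 extinction
#' system is solved per sample, giving oxy- (returned) and deoxyhemoglobin
#' (retained) concentration changes in micromolar. This inverts the
#' simulator's forward mixing exactly when noise is off.
#'
#' @param optical an [optical_recording()].
#' @param extinction 2 x 2 extinction matrix (rows = the two wavelengths,
#'   columns `HbO`, `HbR`); defaults to the tabled coefficients for the
#'   recording's wavelengths.
#' @param dpf differential pathlength factor.
#' @return a `hemoglobin_series`: list with `oxy` and `deoxy`
#'   (pairs x time, micromolar) and `rate`.
#' @export
convert_beer_lambert <- function(optical, extinction = NULL, dpf = 6) {
  wls <- sort(unique(optical$wavelengths))
  if (length(wls) != 2)
    stopf("two distinct wavelengths are required (got %d)", length(wls))
  E <- extinction %||% extinction_coefficients(wls)
  if (abs(det(E)) < 1e-12) stopf("extinction matrix is singular")
  Einv <- solve(E)
  pairs <- sort(unique(optical$pair))
  n <- ncol(optical$samples)
  oxy <- matrix(0, length(pairs), n)
  deoxy <- matrix(0, length(pairs), n)
  for (i in seq_along(pairs)) {
    idx <- which(optical$pair == pairs[i])
    idx <- idx[order(optical$wavelengths[idx])]
    L_cm <- optical$distance_mm[idx] / 10
    if (any(L_cm <= 0)) stopf("source-detector distance must be positive")
    od <- optical$samples[idx, , drop = FALSE] / (L_cm * dpf)
    conc <- Einv %*% od * 1e6      # micromolar
    oxy[i, ] <- conc[1, ]
    deoxy[i, ] <- conc[2, ]
  }
  structure(list(oxy = oxy, deoxy = deoxy, rate = optical$rate,
                 t0 = optical$t0),
            class = "hemoglobin_series")
}

#' Extract the channel-averaged cardiac waveform
#'
#' Zero-phase band-pass (fourth-order Butterworth applied forward and
#' backward) of each oxyhemoglobin channel in the cardiac band, then
#' average across channels. The result is zero-mean and carries the
#' cardiac pulsation.
#'
#' @param hemo a `hemoglobin_series` from [convert_beer_lambert()].
#' @param band pass band (Hz), default 0.5-2.
#' @param order Butterworth prototype order.
#' @return list with `x` (the waveform), `rate`, `t0`.
#' @export
extract_cardiac_waveform <- function(hemo, band = c(0.5, 2), order = 4) {
  n <- ncol(hemo$oxy)
  if (n / hemo$rate < 10) stopf("record shorter than 10 s")
  ny <- hemo$rate / 2
  if (band[2] >= ny) stopf("upper band edge must be below the Nyquist frequency")
  bf <- signal::butter(order, band / ny, type = "pass")
  filt <- t(apply(hemo$oxy, 1, function(ch) signal::filtfilt(bf, ch - mean(ch))))
  x <- colMeans(filt)
  list(x = x - mean(x), rate = hemo$rate, t0 = hemo$t0)
}

#' Detect beat periods from zero crossings
#'
#' Sign changes of the zero-mean cardiac waveform are located with linear
#' interpolation between the bracketing samples. The interval between every
#' other zero crossing (i.e. between same-direction crossings) is one beat
#' period, timestamped at the midpoint of the two crossings. Periods
#' outside the plausibility gate are discarded.
#'
#' @param cardiac list with `x` and `rate` (see
#'   [extract_cardiac_waveform()]), or a numeric vector.
#' @param rate sampling rate (Hz), required when `cardiac` is a vector.
#' @param period_range plausible beat-period gate (s); mirrors the 0.5-2 Hz
#'   design band.
#' @return a `beat_series`: list with `times` (midpoints, s) and
#'   `periods` (s); empty (with attribute `flagged`) when fewer than three
#'   zero crossings are found.
#' @export
detect_beat_periods <- function(cardiac, rate = NULL,
                                period_range = c(0.3, 2.0)) {
  if (is.list(cardiac)) { x <- cardiac$x; rate <- cardiac$rate; t0 <- cardiac$t0 %||% 0 }
  else { x <- cardiac; t0 <- 0 }
  if (is.null(rate)) stopf("rate required")
  n <- length(x)
  i <- which(x[-n] * x[-1] < 0 | (x[-n] == 0 & x[-1] != 0))
  if (length(i) < 3) {
    out <- list(times = numeric(0), periods = numeric(0))
    attr(out, "flagged") <- TRUE
    class(out) <- "beat_series"
    return(out)
  }
  frac <- ifelse(x[i] == 0, 0, x[i] / (x[i] - x[i + 1]))
  tc <- t0 + (i - 1 + frac) / rate
  periods <- tc[-(1:2)] - tc[seq_len(length(tc) - 2)]   # every other crossing
  mids <- (tc[-(1:2)] + tc[seq_len(length(tc) - 2)]) / 2
  keep <- periods >= period_range[1] & periods <= period_range[2]
  out <- list(times = mids[keep], periods = periods[keep])
  class(out) <- "beat_series"
  out
}

#' Instantaneous heart rate on a regular grid
#'
#' Heart rate (60 / period, bpm) at the beat midpoints, linearly
#' interpolated onto the regular acquisition grid, with constant
#' extrapolation at the edges.
#'
#' @param beats a `beat_series`.
#' @param rate grid rate (Hz; the fNIRS acquisition rate).
#' @param duration grid length (s); defaults to the beat span.
#' @param t0 grid start time (s).
#' @return a `heart_rate_series`: list with `t`, `hr` (bpm), `rate`.
#' @export
heart_rate_series <- function(beats, rate, duration = NULL, t0 = 0) {
  if (length(beats$times) < 2) stopf("need at least two beats")
  hr <- 60 / beats$periods
  duration <- duration %||% (max(beats$times) - t0)
  tg <- t0 + (seq_len(round(duration * rate)) - 1) / rate
  out <- approx(beats$times, hr, xout = tg, rule = 2)$y
  structure(list(t = tg, hr = out, rate = rate), class = "heart_rate_series")
}

#' Spectral band powers of a heart-rate segment
#'
#' Hann-tapered periodogram of the mean-removed segment, integrated over
#' the low-frequency (default 0.01-0.15 Hz) and high-frequency (default
#' 0.15-0.8 Hz) bands. Only resolvable bins (multiples of 1/T) contribute,
#' so the LF band is under-resolved for windows shorter than 100 s.
#'
#' @param hr numeric heart-rate segment (bpm) or a `heart_rate_series`.
#' @param rate sampling rate (Hz), required for a plain vector.
#' @param lf,hf band edges (Hz). The 0.15 Hz boundary bin belongs to HF.
#' @return list with `LF` and `HF` powers (bpm squared).
#' @export
compute_band_powers <- function(hr, rate = NULL, lf = c(0.01, 0.15),
                                hf = c(0.15, 0.8)) {
  if (is.list(hr)) { rate <- hr$rate; hr <- hr$hr }
  if (is.null(rate)) stopf("rate required")
  n <- length(hr)
  if (n / rate < 10) stopf("segment too short to resolve the HF band (need >= 10 s)")
  pg <- periodogram_hann(hr, rate)
  list(LF = band_power(pg, lf[1], lf[2]), HF = band_power(pg, hf[1], hf[2]))
}

#' The HRV index HF / (HF + LF)
#'
#' The high-frequency share of heart-rate spectral power: a normalized
#' index in \[0, 1\] of how strongly the heart rate is modulated by
#' respiration. `NA` when both band powers are zero.
#'
#' @param bp list with `LF` and `HF` (see [compute_band_powers()]).
#' @return numeric in \[0, 1\], or `NA`.
#' @export
compute_hrv <- function(bp) {
  tot <- bp$LF + bp$HF
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  bp$HF / tot
}

#' Sliding-window HRV series
#'
#' Applies [compute_band_powers()] + [compute_hrv()] in a sliding window
#' over a heart-rate series; timestamps are window centres.
#'
#' @param hr a `heart_rate_series` or numeric vector.
#' @param rate sampling rate (Hz) for a plain vector.
#' @param window_s window length (s), default 30.
#' @param step_s window step (s), default 1.
#' @return an `hrv_series`: list with `t` (window centres) and `hrv`.
#' @export
compute_hrv_series <- function(hr, rate = NULL, window_s = 30, step_s = 1) {
  if (is.list(hr)) { t0 <- hr$t[1]; rate <- hr$rate; hr <- hr$hr } else t0 <- 0
  if (is.null(rate)) stopf("rate required")
  n <- length(hr)
  wn <- round(window_s * rate)
  st <- max(1, round(step_s * rate))
  if (wn > n) stopf("window longer than the record")
  starts <- seq(1, n - wn + 1, by = st)
  hrv <- vapply(starts, function(s) {
    compute_hrv(compute_band_powers(hr[s:(s + wn - 1)], rate))
  }, numeric(1))
  structure(list(t = t0 + (starts - 1 + (wn - 1) / 2) / rate, hrv = hrv),
            class = "hrv_series")
}

#' Full fNIRS cardiac chain
#'
#' Convenience wrapper: Beer-Lambert conversion, cardiac band-pass,
#' beat detection, heart-rate interpolation and the windowed HRV series.
#'
#' @param optical an [optical_recording()].
#' @param band cardiac band (Hz).
#' @param hrv_window_s,hrv_step_s HRV sliding-window parameters (s).
#' @return list with `hr` (a `heart_rate_series`), `hrv` (an
#'   `hrv_series`), and `beats`.
#' @export
fnirs_cardiac_chain <- function(optical, band = c(0.5, 2),
                                hrv_window_s = 30, hrv_step_s = 1) {
  hemo <- convert_beer_lambert(optical)
  card <- extract_cardiac_waveform(hemo, band = band)
  beats <- detect_beat_periods(card)
  hr <- heart_rate_series(beats, rate = optical$rate,
                          duration = ncol(optical$samples) / optical$rate,
                          t0 = optical$t0)
  hrv <- compute_hrv_series(hr, window_s = hrv_window_s, step_s = hrv_step_s)
  list(hr = hr, hrv = hrv, beats = beats)
}
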