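## ---------------------------------------------------------------------------
## EEG blink pathway: artifact cleaning, zero-phase FIR band-pass and
## downsampling, ICA decomposition, blink-component identification
## (frontal dominance + source kurtosis), peak detection, blink rate.
## ---------------------------------------------------------------------------

#' Construct an EEG recording
#'
#' @param samples channels x time matrix of potentials (microvolt).
#' @param rate sampling rate (Hz).
#' @param channel_names channel labels (10-20 names for real montages).
#' @param t0 start time (s).
#' @param segments data.frame with `start`, `end` (s): the runs of original
#'   time represented by the (possibly excised) sample columns. Defaults to
#'   one contiguous run.
#' @param removed_intervals data.frame with `start`, `end` (s) of excised
#'   fragments (empty by default).
#' @param bad_channels character vector of rejected channel names.
#' @return an `eeg_recording`.
#' @export
eeg_recording <- function(samples, rate, channel_names = NULL, t0 = 0,
                          segments = NULL, removed_intervals = NULL,
                          bad_channels = character(0)) {
  samples <- as.matrix(samples)
  if (rate <= 0) stopf("rate must be positive")
  channel_names <- channel_names %||% paste0("ch", seq_len(nrow(samples)))
  if (length(channel_names) != nrow(samples))
    stopf("channel_names must have one entry per channel")
  segments <- segments %||%
    data.frame(start = t0, end = t0 + ncol(samples) / rate)
  removed_intervals <- removed_intervals %||%
    data.frame(start = numeric(0), end = numeric(0))
  structure(list(samples = samples, rate = rate,
                 channel_names = channel_names, t0 = t0,
                 segments = segments, removed_intervals = removed_intervals,
                 bad_channels = bad_channels),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz; %d bad channel(s), %d excised fragment(s)\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              length(x$bad_channels), nrow(x$removed_intervals)))
  invisible(x)
}

#' Original-time stamps of the retained samples
#'
#' Maps sample columns back to original session time through the kept
#' segments, so event times remain valid after fragment excision and
#' downsampling.
#'
#' @param x an `eeg_recording` or `component_set`.
#' @return numeric vector of times (s), one per sample column.
#' @export
sample_times <- function(x) {
  unlist(lapply(seq_len(nrow(x$segments)), function(i) {
    s <- x$segments$start[i]; e <- x$segments$end[i]
    n <- round((e - s) * x$rate)
    s + (seq_len(n) - 1) / x$rate
  }), use.names = FALSE)
}

#' Baseline-correct an EEG recording per episode
#'
#' Subtracts, per channel and episode epoch, the epoch mean (the whole
#' epoch serves as its own baseline).
#'
#' @param eeg an [eeg_recording()].
#' @param layout a [session_layout()]; with `NULL` the whole recording is
#'   one epoch.
#' @return the corrected `eeg_recording`.
#' @export
baseline_correct_epochs <- function(eeg, layout = NULL) {
  tt <- sample_times(eeg)
  if (is.null(layout)) {
    eeg$samples <- eeg$samples - rowMeans(eeg$samples)
    return(eeg)
  }
  for (i in seq_len(nrow(layout))) {
    sel <- tt >= layout$start[i] & tt < layout$end[i]
    if (any(sel))
      eeg$samples[, sel] <- eeg$samples[, sel, drop = FALSE] -
        rowMeans(eeg$samples[, sel, drop = FALSE])
  }
  eeg
}

#' Clean an EEG recording
#'
#' Two artifact rules applied to the (epoched, baseline-corrected) data:
#' consecutive windows of `window_ms` in which any channel exceeds
#' `amp_thresh_uV` in magnitude are excised (and logged as removed
#' intervals); channels whose sample excess kurtosis exceeds `kurt_thresh`
#' afterwards are rejected.
#'
#' @param eeg an [eeg_recording()].
#' @param amp_thresh_uV amplitude threshold (microvolt), default 200.
#' @param window_ms excision window length (ms), default 1000.
#' @param kurt_thresh excess-kurtosis threshold for channel rejection,
#'   default 5.
#' @return the cleaned `eeg_recording`; attribute `excised_fraction` gives
#'   the fraction of samples removed (a warning is raised above 50
#'   percent).
#' @export
clean_eeg <- function(eeg, amp_thresh_uV = 200, window_ms = 1000,
                      kurt_thresh = 5) {
  n <- ncol(eeg$samples)
  ws <- max(1, round(window_ms / 1000 * eeg$rate))
  nwin <- ceiling(n / ws)
  tt <- sample_times(eeg)
  bad_win <- logical(nwin)
  for (w in seq_len(nwin)) {
    idx <- ((w - 1) * ws + 1):min(w * ws, n)
    bad_win[w] <- any(abs(eeg$samples[, idx]) > amp_thresh_uV)
  }
  keep <- rep(!bad_win, each = ws)[seq_len(n)]
  removed <- eeg$removed_intervals
  if (any(!keep)) {
    r <- rle(!keep)
    ends <- cumsum(r$lengths); starts <- c(1, head(ends, -1) + 1)
    for (k in which(r$values)) {
      removed <- rbind(removed, data.frame(
        start = tt[starts[k]],
        end = tt[ends[k]] + 1 / eeg$rate))
    }
  }
  samples <- eeg$samples[, keep, drop = FALSE]
  tt <- tt[keep]
  # channel rejection by sample kurtosis
  kurt <- apply(samples, 1, excess_kurtosis)
  bad_ch <- kurt > kurt_thresh
  if (all(bad_ch)) stopf("all channels rejected by the kurtosis rule")
  out <- eeg_recording(
    samples = samples[!bad_ch, , drop = FALSE], rate = eeg$rate,
    channel_names = eeg$channel_names[!bad_ch], t0 = eeg$t0,
    segments = runs_to_segments(tt, eeg$rate),
    removed_intervals = removed,
    bad_channels = c(eeg$bad_channels, eeg$channel_names[bad_ch])
  )
  frac <- 1 - ncol(samples) / n
  attr(out, "excised_fraction") <- frac
  if (frac > 0.5) warnf("more than 50%% of samples excised (%.0f%%)", 100 * frac)
  out
}

## collapse a sorted time vector (uniform rate, possibly with gaps) into
## contiguous segments
runs_to_segments <- function(tt, rate) {
  if (!length(tt)) return(data.frame(start = numeric(0), end = numeric(0)))
  gap <- which(diff(tt) > 1.5 / rate)
  starts <- c(1, gap + 1); ends <- c(gap, length(tt))
  data.frame(start = tt[starts], end = tt[ends] + 1 / rate)
}

## Hamming windowed-sinc low-pass kernel, DC gain 1, odd length L
sinc_lowpass <- function(fc, rate, L) {
  M <- (L - 1) / 2
  m <- (0:(L - 1)) - M
  h <- ifelse(m == 0, 2 * fc / rate, sin(2 * pi * fc * m / rate) / (pi * m))
  h <- h * (0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1)))
  h / sum(h)
}

## zero-phase FIR filtering via FFT convolution (linear-phase kernel,
## group delay compensated)
fft_filter <- function(x, h) {
  n <- length(x); L <- length(h); M <- (L - 1) / 2
  nfft <- nextn(n + L - 1, c(2, 3, 5))
  y <- Re(fft(fft(c(x, numeric(nfft - n))) *
              fft(c(h, numeric(nfft - L))), inverse = TRUE)) / nfft
  y[(M + 1):(M + n)]
}

#' Band-pass filter and downsample an EEG recording
#'
#' Zero-phase Hamming windowed-sinc FIR band-pass (default 0.16-40 Hz),
#' then decimation to `out_rate`. The 40 Hz cut-off is far below the
#' output Nyquist frequency, so the band-pass itself anti-aliases.
#'
#' @param eeg an [eeg_recording()].
#' @param band pass band (Hz).
#' @param out_rate output rate (Hz); the input rate must be an integer
#'   multiple.
#' @param transition_hz FIR transition width (Hz); sets the kernel length
#'   as `3.3 / transition * rate` (Hamming design rule). Defaults to the
#'   lower band edge.
#' @return the filtered, downsampled `eeg_recording`.
#' @export
filter_downsample_eeg <- function(eeg, band = c(0.16, 40), out_rate = 200,
                                  transition_hz = band[1]) {
  if (out_rate > eeg$rate) stopf("out_rate exceeds the input rate")
  if (eeg$rate < 2 * band[2]) stopf("input rate below twice the upper band edge")
  fac <- eeg$rate / out_rate
  if (abs(fac - round(fac)) > 1e-9)
    stopf("input rate must be an integer multiple of out_rate")
  fac <- round(fac)
  L <- ceiling(3.3 / transition_hz * eeg$rate)
  if (L %% 2 == 0) L <- L + 1
  h <- sinc_lowpass(band[2], eeg$rate, L) - sinc_lowpass(band[1], eeg$rate, L)
  n <- ncol(eeg$samples)
  dec <- seq(1, n, by = fac)
  out <- matrix(0, nrow(eeg$samples), length(dec))
  for (ch in seq_len(nrow(eeg$samples)))
    out[ch, ] <- fft_filter(eeg$samples[ch, ], h)[dec]
  tt <- sample_times(eeg)[dec]
  eeg_recording(samples = out, rate = out_rate,
                channel_names = eeg$channel_names, t0 = eeg$t0,
                segments = runs_to_segments(tt, out_rate),
                removed_intervals = eeg$removed_intervals,
                bad_channels = eeg$bad_channels)
}

#' ICA decomposition of an EEG recording
#'
#' Decomposes the (cleaned, filtered, downsampled) channel data into
#' independent components behind a stable contract: `sources = unmixing
#' %*% centered data` and `topographies %*% sources` reconstructs the
#' centered data (exactly at full rank). The backend is pluggable: FastICA
#' (default, fast and reliable for isolating the high-kurtosis blink
#' source) or extended Infomax.
#'
#' @param eeg an [eeg_recording()].
#' @param nc number of components (default: number of channels).
#' @param method `"fast"` (FastICA) or `"imax"` (extended Infomax).
#' @param seed integer seed for the backend's random initialisation.
#' @param est_subsample integer; estimate the unmixing on every k-th
#'   sample (sources are still computed on all samples). 1 uses all.
#' @param maxit,tol backend iteration controls.
#' @return a `component_set`: list with `unmixing` (components x
#'   channels), `sources` (components x time), `topographies` (channels x
#'   components), plus `rate`, `segments`, `channel_names`.
#' @export
decompose_ica <- function(eeg, nc = NULL, method = c("fast", "imax"),
                          seed = 1L, est_subsample = 1L,
                          maxit = 100, tol = 1e-5) {
  method <- match.arg(method)
  X <- t(eeg$samples)                       # time x channels
  n <- nrow(X); ch <- ncol(X)
  nc <- nc %||% ch
  if (nc > ch) stopf("nc cannot exceed the channel count")
  cm <- colMeans(X)
  Xc <- sweep(X, 2, cm)
  if (qr(crossprod(Xc))$rank < nc)
    stopf("rank-deficient data: reduce nc or drop duplicate channels")
  Xe <- if (est_subsample > 1) Xc[seq(1, n, by = est_subsample), , drop = FALSE] else Xc
  fit <- with_seed_if(seed, switch(method,
    fast = ica::icafast(Xe, nc = nc, maxit = maxit, tol = tol),
    imax = ica::icaimax(Xe, nc = nc, fun = "ext", maxit = maxit, tol = tol)
  ))
  M <- fit$M                                # channels x components
  U <- solve(crossprod(M), t(M))            # components x channels (LS inverse)
  S <- Xc %*% t(U)                          # time x components
  structure(list(unmixing = U, sources = t(S), topographies = M,
                 rate = eeg$rate, segments = eeg$segments,
                 channel_names = eeg$channel_names,
                 removed_intervals = eeg$removed_intervals),
            class = "component_set")
}

#' Identify blink-related independent components
#'
#' Simplified automatic surrogate for template-based artifact classifiers:
#' a component is flagged when its topography is frontally dominant (mean
#' absolute weight over frontal channels divided by the mean over the rest
#' exceeds `ratio_thresh`) and its source is temporally spiky (excess
#' kurtosis above `kurt_thresh`). May return an empty set.
#'
#' @param cs a `component_set`.
#' @param frontal_channels channel names counted as frontal.
#' @param ratio_thresh frontal-dominance threshold, default 2.
#' @param kurt_thresh source excess-kurtosis threshold, default 3.
#' @return integer vector of flagged component indices, with a `scores`
#'   attribute (data.frame of per-component frontal ratio and kurtosis).
#' @export
identify_blink_components <- function(cs,
                                      frontal_channels = c("Fp1", "Fp2", "F7",
                                                           "F3", "Fz", "F4", "F8"),
                                      ratio_thresh = 2, kurt_thresh = 3) {
  fr <- cs$channel_names %in% frontal_channels
  if (!any(fr) || all(fr))
    stopf("frontal_channels must select a proper subset of channels")
  nc <- ncol(cs$topographies)
  ratio <- vapply(seq_len(nc), function(j) {
    a <- abs(cs$topographies[, j])
    mean(a[fr]) / max(mean(a[!fr]), 1e-12)
  }, numeric(1))
  kurt <- apply(cs$sources, 1, excess_kurtosis)
  scores <- data.frame(component = seq_len(nc), frontal_ratio = ratio,
                       kurtosis = kurt)
  flagged <- which(ratio > ratio_thresh & kurt > kurt_thresh)
  attr(flagged, "scores") <- scores
  flagged
}

#' Detect blink events from flagged components
#'
#' The flagged component with the spikiest source is sign-aligned (so
#' blinks point upward), then local maxima above an adaptive threshold
#' (median + `k_mad` times the MAD) and at least `min_separation_s` apart
#' are taken as blink events. Event times are original session times.
#'
#' @param cs a `component_set`.
#' @param flagged component indices from [identify_blink_components()].
#' @param min_separation_s minimum event separation (s), default 0.2.
#' @param k_mad adaptive-threshold multiplier, default 4.
#' @return a `blink_events` list with `times` (s) and `component`; `NULL`
#'   with an empty flagged set.
#' @export
detect_blink_events <- function(cs, flagged, min_separation_s = 0.2,
                                k_mad = 4) {
  if (!length(flagged)) return(NULL)
  kurt <- apply(cs$sources[flagged, , drop = FALSE], 1, excess_kurtosis)
  kurt[!is.finite(kurt)] <- -Inf
  comp <- flagged[if (all(kurt == -Inf)) 1L else which.max(kurt)]
  s <- cs$sources[comp, ]
  if (sd(s) == 0) {
    out <- list(times = numeric(0), component = comp)
    class(out) <- "blink_events"
    return(out)
  }
  if (e1071::skewness(s, type = 1) < 0) s <- -s
  thr <- median(s) + k_mad * mad(s)
  above <- s > thr
  if (!any(above)) {
    out <- list(times = numeric(0), component = comp)
    class(out) <- "blink_events"
    return(out)
  }
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- c(1, head(ends, -1) + 1)
  peaks <- vapply(which(r$values), function(k) {
    idx <- starts[k]:ends[k]
    idx[which.max(s[idx])]
  }, integer(1))
  # enforce minimum separation, keeping the larger peak
  min_gap <- min_separation_s * cs$rate
  keep <- integer(0)
  for (p in peaks) {
    if (length(keep) && p - keep[length(keep)] < min_gap) {
      if (s[p] > s[keep[length(keep)]]) keep[length(keep)] <- p
    } else keep <- c(keep, p)
  }
  tt <- sample_times(cs)
  out <- list(times = tt[keep], component = comp)
  class(out) <- "blink_events"
  out
}

#' Blink rate over an episode
#'
#' Event count divided by the effective episode duration (episode length
#' minus any excised fragments overlapping it), in blinks per minute.
#'
#' @param events a `blink_events` (or `NULL`, giving `NA`).
#' @param episode numeric `c(start, end)` in seconds.
#' @param removed_intervals data.frame of excised `start`/`end` intervals
#'   (optional).
#' @return blinks per minute, or `NA` when undefined.
#' @export
blink_rate <- function(events, episode, removed_intervals = NULL) {
  if (is.null(events)) return(NA_real_)
  eff <- episode[2] - episode[1]
  if (!is.null(removed_intervals) && nrow(removed_intervals)) {
    ov <- pmin(removed_intervals$end, episode[2]) -
      pmax(removed_intervals$start, episode[1])
    eff <- eff - sum(pmax(ov, 0))
  }
  if (eff <= 0) return(NA_real_)
  cnt <- sum(events$times >= episode[1] & events$times < episode[2])
  cnt / (eff / 60)
}

#' Full EEG blink chain
#'
#' Convenience wrapper: per-episode baseline correction, artifact
#' cleaning, zero-phase FIR band-pass + downsampling, ICA, blink-component
#' identification and peak detection.
#'
#' @param eeg an [eeg_recording()].
#' @param layout optional [session_layout()] for epoch baseline
#'   correction.
#' @param out_rate downsampled rate (Hz).
#' @param nc,method,seed,est_subsample ICA controls, see
#'   [decompose_ica()].
#' @param ... passed to [identify_blink_components()].
#' @return list with `events` (a `blink_events` or `NULL`), `components`,
#'   `flagged`, and the cleaned recording `eeg`.
#' @export
eeg_blinks_chain <- function(eeg, layout = NULL, out_rate = 200,
                             nc = NULL, method = "fast", seed = 1L,
                             est_subsample = 1L, ...) {
  eeg <- baseline_correct_epochs(eeg, layout)
  eeg <- clean_eeg(eeg)
  eeg <- filter_downsample_eeg(eeg, out_rate = out_rate)
  cs <- decompose_ica(eeg, nc = nc, method = method, seed = seed,
                      est_subsample = est_subsample)
  flagged <- identify_blink_components(cs, ...)
  events <- detect_blink_events(cs, flagged)
  list(events = events, components = cs, flagged = flagged, eeg = eeg)
}
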