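## ---------------------------------------------------------------------------
## Synthetic multi-subject sessions with full ground truth.
##
## The generator emulates the statistical structure the downstream analysis
## assumes: a cardiac oscillation carried by fNIRS optics whose instantaneous
## rate is modulated by respiration (RSA) and by a latent per-episode load;
## Mayer-wave and drift confounds; EEG background plus frontal blink
## transients at a load-dependent rate; dual-task behaviour and subjective
## scores as noisy monotone or U-shaped functions of load.
## ---------------------------------------------------------------------------

#' Default session layout
#'
#' Seven episodes: a two-minute baseline (secondary task alone), then the
#' three primary tasks (first task, second task, first task repeated), each
#' preceded by a two-minute rest. Task durations default to 300 s, well
#' under the 900 s (15 min) time-on-task cap.
#'
#' @param task_s task episode duration in seconds.
#' @param rest_s rest/baseline episode duration in seconds.
#' @return a `session_layout` data.frame with columns `episode`, `label`,
#'   `start`, `end` (seconds).
#' @export
default_session_layout <- function(task_s = 300, rest_s = 120) {
  session_layout(
    labels = c("Baseline", "Rest", "Task1", "Rest", "Task2", "Rest", "Task1R"),
    durations = c(rest_s, rest_s, task_s, rest_s, task_s, rest_s, task_s)
  )
}

#' Construct a session layout
#'
#' @param labels episode labels; allowed values are `Baseline`, `Rest`,
#'   `Task1`, `Task2`, `Task1R`.
#' @param durations episode durations in seconds (same length as `labels`).
#' @return a `session_layout` data.frame (contiguous, ordered episodes).
#' @export
session_layout <- function(labels, durations) {
  allowed <- c("Baseline", "Rest", "Task1", "Task2", "Task1R")
  if (!all(labels %in% allowed))
    stopf("unknown episode label(s): %s",
          paste(setdiff(labels, allowed), collapse = ", "))
  if (length(labels) != length(durations) || any(durations <= 0))
    stopf("durations must be positive and match labels")
  if (any(durations[grepl("^Task", labels)] > 900))
    stopf("task durations must not exceed 900 s")
  if (!any(grepl("^Task", labels)) || !any(labels %in% c("Rest", "Baseline")))
    stopf("layout needs at least one task and one rest/baseline episode")
  end <- cumsum(durations)
  out <- data.frame(
    episode = seq_along(labels), label = labels,
    start = c(0, head(end, -1)), end = end
  )
  class(out) <- c("session_layout", "data.frame")
  out
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic cohort generator. Defaults are the
#' study conditions the package is validated under: 10 Hz dual-wavelength
#' fNIRS over 8 optode pairs, 19-channel EEG at 2000 Hz, a resting blink
#' rate of 14 per minute, respiration at 0.25 Hz (inside the 0.15-0.8 Hz
#' high-frequency band), and load effects that raise heart rate and lower
#' both RSA depth and blink rate.
#'
#' @param n_subjects number of subjects.
#' @param seed integer seed; the cohort is bit-reproducible given the seed.
#' @param layout a [session_layout()].
#' @param hr_base_mean,hr_base_sd across-subject distribution of resting
#'   heart rate (bpm), truncated to `hr_base_range`.
#' @param hr_base_range truncation bounds for the resting heart rate (bpm).
#' @param rsa_depth_rest resting RSA depth (dimensionless fraction of the
#'   base rate; 0.06 means a +/-6 percent respiratory swing).
#' @param resp_freq respiration frequency (Hz); must lie in (0.15, 0.8).
#' @param hr_tau_s time constant (s) of the exponential approach of heart
#'   rate to its episode level (heart rate ramps; RSA depth switches
#'   instantly at episode boundaries).
#' @param hr_drift_sd per-sqrt-second standard deviation of the slow
#'   random-walk drift added to the true heart rate (bpm).
#' @param hr_lf_amplitude,hr_lf_freq amplitude (bpm) and frequency (Hz) of
#'   the low-frequency (baroreflex/Mayer-band) heart-rate oscillation.
#'   Real heart rate always carries such a component; it supplies the
#'   low-frequency power against which the HF-share HRV index is
#'   normalised.
#' @param cardiac_amplitude_uM amplitude of the cardiac oxyhemoglobin
#'   oscillation (micromolar).
#' @param mayer_amplitude_uM,mayer_freq Mayer-wave confound amplitude
#'   (micromolar) and frequency (Hz).
#' @param drift_sd per-sample standard deviation of the optical-density
#'   random-walk drift (a.u.).
#' @param noise_sd white measurement noise in optical density (a.u.).
#' @param fnirs_rate fNIRS sampling rate (Hz).
#' @param n_fnirs_pairs number of optode pairs; each pair yields two
#'   wavelength channels.
#' @param wavelengths the two wavelengths (nm).
#' @param dpf differential pathlength factor used in the forward model.
#' @param distance_mm source-detector separation (mm).
#' @param eeg_rate EEG sampling rate (Hz).
#' @param n_eeg_channels number of EEG channels (up to 19; the standard
#'   10-20 names are used).
#' @param eeg_background_sd standard deviation of the 1/f EEG background
#'   (microvolt).
#' @param blink_amplitude_uV peak blink-transient amplitude at the most
#'   frontal channels (microvolt).
#' @param blink_rate_rest resting blink rate (per minute).
#' @param blink_refractory_s minimum inter-blink interval (s).
#' @param load_effects list with elements `hr` (bpm per unit load), `rsa`
#'   (RSA-depth change per unit load; negative), `br` (blinks/min per unit
#'   load; negative). These set the within-subject episode contrasts:
#'   under load, heart rate rises while RSA depth and blink rate fall.
#' @param trait_effects list with elements `hr` (bpm per SD), `rsa`
#'   (RSA-depth change per SD), `br` (blinks/min per SD) and `rt`
#'   (log-latency change per SD): the effect of a per-subject tonic
#'   arousal/engagement trait (standard normal). Tonically aroused
#'   subjects carry a higher heart rate, a shallower RSA, a higher
#'   spontaneous blink rate and faster secondary-task responses; this
#'   between-subject dimension is what makes pooled heart rate correlate
#'   negatively - and HRV positively - with reaction time while the
#'   within-subject load effects keep their own signs.
#' @param rsa_depth_floor lower bound for RSA depth (the near-zero floor
#'   that produces the saturation of the HRV index under load).
#' @param target_links list describing the target-generating links; see
#'   Details.
#' @param beep_interval_range secondary-task inter-onset interval range (s).
#' @param beep_duration_range beep duration range (ms).
#'
#' @details `target_links` holds, per target family, the link and noise
#' scale used by [simulate_behaviour()]: `nasa` (linear in load, additive
#' noise on the 0-100 scale), `rt` (log-linear latency shift per unit load
#' plus a miss probability increasing in load) and `completion` (quadratic
#' in arousal about an optimum, emulating an inverted-U performance law).
#'
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_subjects = 31,
                              seed = 1L,
                              layout = default_session_layout(),
                              hr_base_mean = 70, hr_base_sd = 8,
                              hr_base_range = c(45, 100),
                              rsa_depth_rest = 0.06,
                              resp_freq = 0.25,
                              hr_tau_s = 30,
                              hr_drift_sd = 0.15,
                              hr_lf_amplitude = 1.5, hr_lf_freq = 0.1,
                              cardiac_amplitude_uM = 0.15,
                              mayer_amplitude_uM = 0.08, mayer_freq = 0.1,
                              drift_sd = 2e-5,
                              noise_sd = 5e-4,
                              fnirs_rate = 10, n_fnirs_pairs = 8,
                              wavelengths = c(760, 850),
                              dpf = 6, distance_mm = 30,
                              eeg_rate = 2000, n_eeg_channels = 19,
                              eeg_background_sd = 15,
                              blink_amplitude_uV = 120,
                              blink_rate_rest = 14,
                              blink_refractory_s = 0.5,
                              load_effects = list(hr = 10, rsa = -0.065, br = -7),
                              trait_effects = list(hr = 4, rsa = -0.015,
                                                   br = 3, rt = -0.2),
                              rsa_depth_floor = 0.005,
                              target_links = list(
                                nasa = list(link = "linear", base = 15, slope = 55, noise = 8),
                                rt = list(link = "linear", base_s = 0.32, log_slope = 0.3,
                                          sdlog = 0.22, miss_intercept = -3.2, miss_slope = 2.8),
                                completion = list(link = "quadratic", base_s = 220,
                                                  curvature = 900, optimum = 0.5,
                                                  trait_weight = 0.3, noise = 20)
                              ),
                              beep_interval_range = c(3, 10),
                              beep_duration_range = c(500, 1000)) {
  cfg <- as.list(environment())
  if (cfg$n_subjects < 1) stopf("n_subjects must be >= 1")
  if (!inherits(cfg$layout, "session_layout")) stopf("layout must be a session_layout")
  if (cfg$resp_freq <= 0.15 || cfg$resp_freq >= 0.8)
    stopf("resp_freq must lie inside the high-frequency band (0.15, 0.8) Hz")
  for (f in c("fnirs_rate", "eeg_rate", "hr_base_mean", "blink_refractory_s"))
    if (cfg[[f]] <= 0) stopf("%s must be positive", f)
  if (cfg$blink_rate_rest < 0) stopf("blink_rate_rest must be >= 0")
  if (length(cfg$wavelengths) != 2) stopf("exactly two wavelengths are required")
  if (cfg$n_eeg_channels < 2 || cfg$n_eeg_channels > 19)
    stopf("n_eeg_channels must be in [2, 19]")
  class(cfg) <- "simulation_config"
  cfg
}

## standard 10-20 names, frontal first, and the rank-one blink topography
eeg_channel_names <- function(n) {
  nm <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7", "C3", "Cz",
          "C4", "T8", "P7", "P3", "Pz", "P4", "P8", "O1", "O2")
  nm[seq_len(n)]
}

blink_topography <- function(channel_names) {
  w <- c(Fp1 = 1, Fp2 = 1, F7 = 0.5, F3 = 0.55, Fz = 0.6, F4 = 0.55,
         F8 = 0.5, T7 = 0.15, C3 = 0.2, Cz = 0.25, C4 = 0.2, T8 = 0.15,
         P7 = 0.06, P3 = 0.08, Pz = 0.08, P4 = 0.08, P8 = 0.06,
         O1 = 0.03, O2 = 0.03)
  unname(w[channel_names])
}

#' Extinction coefficients for oxy- and deoxyhemoglobin
#'
#' Molar extinction coefficients (1/cm per M) at the wavelengths used by
#' the forward model and its inverse. The same table is used by the
#' simulator's forward mixing and by [convert_beer_lambert()], so the
#' round trip is exact up to measurement noise.
#'
#' @param wavelengths wavelengths (nm); 690, 760, 830 and 850 are tabled.
#' @return a 2 x 2 matrix (rows = wavelengths, columns = `HbO`, `HbR`).
#' @export
extinction_coefficients <- function(wavelengths = c(760, 850)) {
  tab <- rbind(
    "690" = c(HbO = 276.0,  HbR = 2051.96),
    "760" = c(HbO = 1486.59, HbR = 3843.71),
    "830" = c(HbO = 2321.40, HbR = 1791.96),
    "850" = c(HbO = 2526.39, HbR = 1798.64)
  )
  key <- as.character(wavelengths)
  if (!all(key %in% rownames(tab)))
    stopf("no extinction coefficients tabled for wavelength(s): %s",
          paste(setdiff(key, rownames(tab)), collapse = ", "))
  out <- tab[key, , drop = FALSE]
  rownames(out) <- key
  out
}

#' True instantaneous heart rate trajectory
#'
#' Base rate plus a respiratory (RSA) oscillation and an optional slow
#' random-walk drift: `hr(t) = base * (1 + depth * sin(2 pi f t)) + drift`.
#'
#' @param base_hr base heart rate (bpm), in \[30, 200\].
#' @param rsa_depth RSA depth (dimensionless, >= 0).
#' @param resp_freq respiration frequency (Hz).
#' @param duration trajectory duration (s).
#' @param rate sampling rate (Hz).
#' @param drift_sd per-sqrt-second drift standard deviation (bpm); 0 turns
#'   the drift off.
#' @param phase0 initial respiratory phase (radians).
#' @return numeric vector of instantaneous heart rate (bpm).
#' @export
simulate_hr_truth <- function(base_hr, rsa_depth, resp_freq, duration,
                              rate = 10, drift_sd = 0, phase0 = 0) {
  if (base_hr < 30 || base_hr > 200) stopf("base_hr must be in [30, 200] bpm")
  if (rsa_depth < 0) stopf("rsa_depth must be >= 0")
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  hr <- base_hr * (1 + rsa_depth * sin(2 * pi * resp_freq * t + phase0))
  if (drift_sd > 0)
    hr <- hr + cumsum(rnorm(n, 0, drift_sd / sqrt(rate)))
  if (any(hr <= 0)) stopf("parameters produce non-positive heart rate")
  hr
}

## whole-session HR / RSA-depth trajectories given per-episode loads.
## HR relaxes exponentially (time constant hr_tau_s) toward the episode
## level; RSA depth switches instantly. Respiratory phase is continuous.
session_truth <- function(base_hr, loads, cfg,
                          depth_rest = cfg$rsa_depth_rest) {
  lay <- cfg$layout
  rate <- cfg$fnirs_rate
  n <- round(max(lay$end) * rate)
  t <- (seq_len(n) - 1) / rate
  ep <- findInterval(t, lay$start)
  level <- base_hr + cfg$load_effects$hr * loads[ep]
  depth <- pmax(depth_rest + cfg$load_effects$rsa * loads[ep],
                cfg$rsa_depth_floor)
  # exponential relaxation of the HR level
  a <- exp(-1 / (rate * cfg$hr_tau_s))
  sm <- numeric(n)
  sm[1] <- level[1]
  for (i in 2:n) sm[i] <- a * sm[i - 1] + (1 - a) * level[i]
  hr <- sm * (1 + depth * sin(2 * pi * cfg$resp_freq * t)) +
    cfg$hr_lf_amplitude * sin(2 * pi * cfg$hr_lf_freq * t + runif(1, 0, 2 * pi)) +
    cumsum(rnorm(n, 0, cfg$hr_drift_sd / sqrt(rate)))
  hr <- clamp(hr, 30, 200)
  list(t = t, hr = hr, depth_by_episode = pmax(
    depth_rest + cfg$load_effects$rsa * loads, cfg$rsa_depth_floor))
}

#' Synthesize a dual-wavelength fNIRS optical recording
#'
#' Each optode pair carries a cardiac oxyhemoglobin oscillation whose
#' instantaneous phase is the integral of the true heart rate, a Mayer-wave
#' sinusoid near 0.1 Hz, and a random-walk drift; deoxyhemoglobin is a
#' scaled counter-phase copy. The two wavelength channels per pair are
#' produced by forward modified Beer-Lambert mixing with the tabled
#' extinction coefficients, plus white optical-density noise.
#'
#' @param true_hr instantaneous heart rate (bpm) sampled at
#'   `config$fnirs_rate`.
#' @param config a [simulation_config()].
#' @return an [optical_recording()].
#' @export
synthesize_fnirs <- function(true_hr, config) {
  cfg <- config
  n <- length(true_hr)
  rate <- cfg$fnirs_rate
  t <- (seq_len(n) - 1) / rate
  phase <- 2 * pi * cumsum(true_hr / 60) / rate
  npair <- cfg$n_fnirs_pairs
  eps <- extinction_coefficients(cfg$wavelengths)
  L_cm <- cfg$distance_mm / 10
  nch <- 2 * npair
  samples <- matrix(0, nch, n)
  for (j in seq_len(npair)) {
    amp <- cfg$cardiac_amplitude_uM * runif(1, 0.7, 1.3)
    hbo <- amp * (sin(phase) + 0.25 * sin(2 * phase + 0.8)) +
      cfg$mayer_amplitude_uM * sin(2 * pi * cfg$mayer_freq * t + runif(1, 0, 2 * pi))
    hbr <- -0.25 * hbo
    for (k in 1:2) {
      od <- (eps[k, "HbO"] * hbo + eps[k, "HbR"] * hbr) * 1e-6 * L_cm * cfg$dpf
      if (cfg$drift_sd > 0) od <- od + cumsum(rnorm(n, 0, cfg$drift_sd))
      if (cfg$noise_sd > 0) od <- od + rnorm(n, 0, cfg$noise_sd)
      samples[2 * (j - 1) + k, ] <- od
    }
  }
  optical_recording(
    samples = samples, rate = rate,
    wavelengths = rep(cfg$wavelengths, npair),
    pair = rep(seq_len(npair), each = 2),
    distance_mm = rep(cfg$distance_mm, nch)
  )
}

#' Simulate blink times
#'
#' Homogeneous Poisson-like process with a refractory period: intervals are
#' `refractory + Exp(mean = 60/rate - refractory)`, so the expected count
#' over a long window is `rate * duration / 60`.
#'
#' @param rate blink rate (per minute); 0 gives no blinks.
#' @param duration window length (s).
#' @param refractory minimum inter-blink interval (s).
#' @param t0 start time (s) added to all blink times.
#' @return strictly increasing blink times (s).
#' @export
simulate_blink_times <- function(rate, duration, refractory = 0.5, t0 = 0) {
  if (rate < 0) stopf("rate must be >= 0")
  if (rate == 0) return(numeric(0))
  mu <- 60 / rate
  if (mu <= refractory)
    stopf("blink rate %.1f/min incompatible with refractory period %.2f s", rate, refractory)
  # generous over-draw, then cut at the window end
  ndraw <- max(10, ceiling(2 * duration / mu + 10))
  gaps <- refractory + rexp(ndraw, 1 / (mu - refractory))
  times <- cumsum(gaps)
  while (sum(times) < duration && times[length(times)] < duration) {
    gaps <- refractory + rexp(ndraw, 1 / (mu - refractory))
    times <- c(times, times[length(times)] + cumsum(gaps))
  }
  t0 + times[times < duration]
}

#' Synthesize a multi-channel EEG recording with blink transients
#'
#' Per-channel 1/f background noise plus a stereotyped ~300 ms biphasic
#' blink transient added at each blink time with a frontally weighted,
#' rank-one spatial pattern, so that independent component analysis can
#' isolate the blink source.
#'
#' @param blink_times blink onset times (s).
#' @param config a [simulation_config()].
#' @param duration recording length (s).
#' @return an [eeg_recording()].
#' @export
synthesize_eeg <- function(blink_times, config, duration) {
  cfg <- config
  rate <- cfg$eeg_rate
  n <- round(duration * rate)
  nch <- cfg$n_eeg_channels
  nm <- eeg_channel_names(nch)
  # 1/f background: shape white noise in the frequency domain
  samples <- matrix(0, nch, n)
  f <- c(1, seq_len(n - 1)) * (rate / n)
  f <- pmin(f, rate - f + rate / n)      # mirror for negative frequencies
  shape <- 1 / sqrt(f + 0.5)
  for (ch in seq_len(nch)) {
    x <- Re(fft(fft(rnorm(n)) * shape, inverse = TRUE)) / n
    samples[ch, ] <- x / sd(x) * cfg$eeg_background_sd
  }
  if (length(blink_times)) {
    tpl_t <- seq(0, 0.3, by = 1 / rate)
    tpl <- exp(-(tpl_t - 0.12)^2 / (2 * 0.04^2)) -
      0.35 * exp(-(tpl_t - 0.22)^2 / (2 * 0.06^2))
    tpl <- tpl / max(tpl) * cfg$blink_amplitude_uV
    w <- blink_topography(nm)
    src <- numeric(n)
    idx0 <- round(blink_times * rate) + 1
    for (i0 in idx0) {
      ii <- i0:min(i0 + length(tpl) - 1, n)
      src[ii] <- src[ii] + tpl[seq_along(ii)]
    }
    samples <- samples + w %o% src
  }
  eeg_recording(samples = samples, rate = rate, channel_names = nm)
}

#' Simulate dual-task behaviour and workload targets
#'
#' Secondary-task beeps with uniformly random inter-onset intervals; per
#' beep, a load-shifted lognormal response latency or a miss with
#' probability increasing in load. A response is a non-response if it
#' arrives after the next stimulus onset. Per task episode: six NASA-TLX
#' dimension scores (0-100 in steps of 5) increasing in load, a completion
#' time that is quadratic in arousal about an optimum (inverted-U
#' performance law), and Poisson error counts.
#'
#' @param true_load per-episode latent load (aligned with `layout` rows).
#' @param layout a [session_layout()].
#' @param config a [simulation_config()].
#' @param trait per-subject tonic arousal trait (standard-normal scale);
#'   shifts response latency by `trait_effects$rt` per SD and contributes
#'   to the arousal variable behind the completion-time optimum.
#' @return list with `log` (the secondary-task log: one row per beep with
#'   `episode`, `label`, `onset`, `duration_ms`, `response_time`) and
#'   `targets` (one row per task episode) and `true_targets` (noiseless
#'   values underlying `targets`).
#' @export
simulate_behaviour <- function(true_load, layout, config, trait = 0) {
  cfg <- config
  tl <- cfg$target_links
  logs <- list(); tg <- list(); tt <- list()
  for (i in seq_len(nrow(layout))) {
    ep <- layout[i, ]
    load <- true_load[i]
    onsets <- numeric(0); cur <- ep$start
    repeat {
      cur <- cur + runif(1, cfg$beep_interval_range[1], cfg$beep_interval_range[2])
      if (cur >= ep$end) break
      onsets <- c(onsets, cur)
    }
    if (length(onsets)) {
      miss <- runif(length(onsets)) < plogis(tl$rt$miss_intercept + tl$rt$miss_slope * load)
      lat <- rlnorm(length(onsets),
                    log(tl$rt$base_s) + tl$rt$log_slope * load +
                      cfg$trait_effects$rt * trait,
                    tl$rt$sdlog)
      resp <- ifelse(miss, NA_real_, onsets + lat)
      logs[[i]] <- data.frame(
        episode = ep$episode, label = ep$label, onset = onsets,
        duration_ms = runif(length(onsets), cfg$beep_duration_range[1],
                            cfg$beep_duration_range[2]),
        response_time = resp
      )
    }
    if (grepl("^Task", ep$label)) {
      dims <- c("Mental", "Physical", "Temporal", "Performance", "Effort", "Frustration")
      true_score <- clamp(tl$nasa$base + tl$nasa$slope * load, 0, 100)
      scores <- clamp(round((true_score + rnorm(6, 0, tl$nasa$noise)) / 5) * 5, 0, 100)
      arousal <- load + tl$completion$trait_weight * trait
      ct_true <- tl$completion$base_s +
        tl$completion$curvature * (arousal - tl$completion$optimum)^2
      ct <- clamp(ct_true + rnorm(1, 0, tl$completion$noise), 30, 900)
      err <- c(rpois(1, 0.4 + 3.5 * load), rpois(1, 0.2 + 1.5 * load),
               rpois(1, 0.1 + 1.0 * load))
      row <- data.frame(episode = ep$episode, label = ep$label,
                        nasa_tlx_avg = mean(scores),
                        completion_time = ct,
                        errors_10 = err[1], errors_20 = err[2], errors_30 = err[3])
      row[paste0("nasa_", tolower(dims))] <- as.list(scores)
      tg[[i]] <- row
      tt[[i]] <- data.frame(episode = ep$episode, label = ep$label,
                            true_load = load, true_arousal = arousal,
                            true_nasa = true_score,
                            true_completion_time = ct_true)
    }
  }
  list(log = do.call(rbind, logs), targets = do.call(rbind, tg),
       true_targets = do.call(rbind, tt))
}

## per-episode latent loads for one subject
episode_loads <- function(layout, aptitude) {
  diff_map <- c(Task1 = 0.4, Task2 = 0.8, Task1R = 0.0)
  vapply(seq_len(nrow(layout)), function(i) {
    lab <- layout$label[i]
    if (lab == "Baseline") return(0.15)
    if (lab == "Rest") return(0.05)
    plogis(diff_map[[lab]] - 0.7 * aptitude + rnorm(1, 0, 0.35))
  }, numeric(1))
}

#' Simulate a cohort of synthetic sessions
#'
#' Generates `config$n_subjects` independent subject bundles. Each subject
#' has a latent aptitude (standard normal) and a truncated-normal resting
#' heart rate; per-episode latent load is a logistic function of task
#' difficulty minus aptitude plus noise, so load rises with task demand and
#' falls with aptitude. Load raises heart rate, lowers RSA depth (floored
#' near zero) and lowers blink rate, and drives the behavioural and
#' subjective targets.
#'
#' @param config a [simulation_config()].
#' @param include_eeg generate the EEG recording for each subject. A full
#'   session at 2000 Hz occupies ~200 MB per subject; disable (or reduce
#'   `eeg_rate`) for large in-memory cohorts, in which case ground-truth
#'   blink times still permit blink-rate features.
#' @param include_fnirs generate the optical recording; disable when only
#'   ground-truth trajectories are needed (large Monte Carlo sweeps).
#' @return list of subject bundles, each a list with `subject_id`,
#'   `optical`, `eeg` (or `NULL`), `layout`, `task_log`, `targets`, and
#'   `truth` (ground truth: `true_hr`, `rsa_depth_by_episode`,
#'   `true_blink_times`, `true_load`, `base_hr`, `aptitude`,
#'   `blink_rate_by_episode`, `true_targets`).
#' @export
simulate_cohort <- function(config, include_eeg = TRUE, include_fnirs = TRUE) {
  cfg <- config
  with_seed_if(cfg$seed, {
    lapply(seq_len(cfg$n_subjects), function(s) {
      aptitude <- rnorm(1)
      trait <- rnorm(1)
      base_hr <- rnorm_trunc(1, cfg$hr_base_mean, cfg$hr_base_sd,
                             cfg$hr_base_range[1], cfg$hr_base_range[2])
      loads <- episode_loads(cfg$layout, aptitude)
      truth <- session_truth(
        clamp(base_hr + cfg$trait_effects$hr * trait, 40, 180), loads, cfg,
        depth_rest = max(cfg$rsa_depth_rest + cfg$trait_effects$rsa * trait,
                         cfg$rsa_depth_floor))
      optical <- if (include_fnirs) synthesize_fnirs(truth$hr, cfg) else NULL
      br_ep <- pmax(cfg$blink_rate_rest + cfg$trait_effects$br * trait +
                      cfg$load_effects$br * loads, 1)
      blink_times <- unlist(lapply(seq_len(nrow(cfg$layout)), function(i) {
        ep <- cfg$layout[i, ]
        simulate_blink_times(br_ep[i], ep$end - ep$start,
                             cfg$blink_refractory_s, t0 = ep$start)
      }))
      eeg <- if (include_eeg)
        synthesize_eeg(blink_times, cfg, max(cfg$layout$end)) else NULL
      beh <- simulate_behaviour(loads, cfg$layout, cfg, trait = trait)
      list(
        subject_id = sprintf("S%02d", s),
        optical = optical, eeg = eeg, layout = cfg$layout,
        task_log = beh$log, targets = beh$targets,
        truth = list(
          t = truth$t, true_hr = truth$hr,
          rsa_depth_by_episode = truth$depth_by_episode,
          true_blink_times = blink_times,
          blink_rate_by_episode = br_ep,
          true_load = loads, base_hr = base_hr, aptitude = aptitude,
          trait = trait, true_targets = beh$true_targets
        )
      )
    })
  })
}
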