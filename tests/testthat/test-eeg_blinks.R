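# compact synthetic EEG for unit tests: modest rate keeps the suite quick;
# the acceptance suite exercises larger records
small_cfg <- function(...) simulation_config(eeg_rate = 500, ...)

test_that("clean EEG passes artifact-free data through untouched", {
  withr::with_seed(41, {
    eeg <- synthesize_eeg(numeric(0), small_cfg(), 30)
  })
  out <- clean_eeg(eeg)
  expect_equal(nrow(out$removed_intervals), 0)
  expect_length(out$bad_channels, 0)
  expect_equal(dim(out$samples), dim(eeg$samples))
})

test_that("an amplitude spike excises exactly its window on all channels", {
  withr::with_seed(42, {
    eeg <- synthesize_eeg(numeric(0), small_cfg(), 30)
  })
  # 500 uV spike at t = 10.2 s on one channel
  eeg$samples[4, round(10.2 * eeg$rate)] <- 500
  out <- clean_eeg(eeg)
  expect_equal(nrow(out$removed_intervals), 1)
  # the 1 s window containing t = 10.2 (windows are consecutive from 0)
  expect_equal(out$removed_intervals$start[1], 10, tolerance = 1e-6)
  expect_equal(out$removed_intervals$end[1], 11, tolerance = 1e-6)
  expect_equal(ncol(out$samples), ncol(eeg$samples) - eeg$rate)
  # timestamps skip the excised second
  tt <- sample_times(out)
  expect_false(any(tt >= 10 & tt < 11))
})

test_that("a heavy-tailed channel - and only it - is rejected by kurtosis", {
  withr::with_seed(43, {
    eeg <- synthesize_eeg(numeric(0), small_cfg(), 30)
    spiky <- rnorm(ncol(eeg$samples)) * 3
    spiky[sample(length(spiky), 40)] <- rnorm(40, 0, 60)  # sparse heavy tails
    eeg$samples[7, ] <- spiky
    # oracle: moment-based sample excess kurtosis
    m <- spiky - mean(spiky)
    k_oracle <- mean(m^4) / mean(m^2)^2 - 3
    expect_gt(k_oracle, 5)
    out <- clean_eeg(eeg)
    expect_equal(out$bad_channels, eeg$channel_names[7])
    expect_equal(nrow(out$samples), nrow(eeg$samples) - 1)
  })
})

test_that("FIR band-pass attenuates 50 Hz and DC, and decimates correctly", {
  rate <- 1000
  t <- seq(0, 80 - 1 / rate, by = 1 / rate)
  x <- 3 + sin(2 * pi * 10 * t) + sin(2 * pi * 50 * t)
  eeg <- eeg_recording(rbind(x, x), rate = rate)
  out <- filter_downsample_eeg(eeg, band = c(0.16, 40), out_rate = 200)
  expect_equal(ncol(out$samples), length(t) / 5)
  expect_equal(out$rate, 200)
  y <- out$samples[1, ]
  n <- length(y)
  f <- (seq_len(n) - 1) * 200 / n
  sp <- Mod(stats::fft(y))
  amp10 <- max(sp[abs(f - 10) < 0.2])
  amp50 <- max(sp[abs(f - 50) < 0.2])
  expect_gt(amp10 / amp50, 10^(20 / 20))      # >= 20 dB relative attenuation
  expect_lt(abs(mean(y)), 0.1)                # DC (amplitude 3) removed
  expect_error(filter_downsample_eeg(eeg, out_rate = 2000), "exceeds")
})

test_that("ICA reconstructs the data and recovers a rank-one blink pattern", {
  withr::with_seed(44, {
    bt <- simulate_blink_times(15, 60)
    eeg <- synthesize_eeg(bt, small_cfg(), 60)
  })
  eeg <- filter_downsample_eeg(eeg, out_rate = 100)
  cs <- decompose_ica(eeg, seed = 9)
  Xc <- eeg$samples - rowMeans(eeg$samples)
  rec <- cs$topographies %*% cs$sources
  expect_lt(norm(rec - Xc, "F") / norm(Xc, "F"), 1e-6)
  expect_equal(dim(cs$unmixing), c(nrow(eeg$samples), nrow(eeg$samples)))
  # some topography matches the true blink spatial pattern
  w <- physioload:::blink_topography(eeg$channel_names)
  cors <- abs(cor(cs$topographies, w))
  expect_gt(max(cors), 0.95)
  # permuting the channel order leaves the blink pattern recoverable, with
  # its topography rows permuted accordingly
  perm <- rev(seq_len(nrow(eeg$samples)))
  eeg2 <- eeg; eeg2$samples <- eeg$samples[perm, ]
  eeg2$channel_names <- eeg$channel_names[perm]
  cs2 <- decompose_ica(eeg2, seed = 9)
  expect_gt(max(abs(cor(cs2$topographies, w[perm]))), 0.95)
  rec2 <- cs2$topographies %*% cs2$sources
  Xc2 <- eeg2$samples - rowMeans(eeg2$samples)
  expect_lt(norm(rec2 - Xc2, "F") / norm(Xc2, "F"), 1e-6)
})

test_that("blink-component identification flags the right component", {
  # hand-built component set: one frontal spiky source, one flat posterior
  nch <- 6
  nms <- c("Fp1", "Fp2", "F3", "C3", "P3", "O1")
  n <- 2000
  s1 <- rnorm(n, 0, 0.3); s1[seq(100, n, by = 200)] <- 8
  s2 <- sin(2 * pi * (1:n) / 180)
  topo <- cbind(c(1, 0.9, 0.5, 0.1, 0.05, 0.02),
                c(0.05, 0.02, 0.1, 0.4, 0.9, 1))
  cs <- structure(list(
    unmixing = matrix(0, 2, nch), sources = rbind(s1, s2),
    topographies = topo, rate = 100, channel_names = nms,
    segments = data.frame(start = 0, end = n / 100),
    removed_intervals = data.frame(start = numeric(0), end = numeric(0))
  ), class = "component_set")
  flagged <- identify_blink_components(cs, frontal_channels = c("Fp1", "Fp2", "F3"))
  expect_equal(as.integer(flagged), 1L)
  sc <- attr(flagged, "scores")
  expect_equal(nrow(sc), 2)
  expect_gt(sc$kurtosis[1], 3)
  expect_lt(sc$kurtosis[2], 3)
})

test_that("blink-free sessions mostly yield an empty flagged set", {
  hits <- withr::with_seed(45, {
    vapply(1:25, function(i) {
      eeg <- synthesize_eeg(numeric(0), small_cfg(), 20)
      eeg <- filter_downsample_eeg(eeg, out_rate = 100)
      cs <- decompose_ica(eeg, seed = i)
      length(identify_blink_components(cs)) > 0
    }, logical(1))
  })
  expect_lte(mean(hits), 0.1)
})

test_that("peak detection finds injected peaks and merges close ones", {
  rate <- 100
  n <- 60 * rate
  src <- rnorm(n, 0, 0.2)
  true_idx <- seq(300, n - 300, length.out = 10)
  tpl <- sin(seq(0, pi, length.out = 21))^2 * 6
  for (i in round(true_idx)) src[i:(i + 20)] <- src[i:(i + 20)] + tpl
  cs <- structure(list(
    sources = matrix(src, 1), topographies = matrix(1, 1, 1),
    unmixing = matrix(1, 1, 1), rate = rate, channel_names = "Fp1",
    segments = data.frame(start = 0, end = 60),
    removed_intervals = data.frame(start = numeric(0), end = numeric(0))
  ), class = "component_set")
  ev <- detect_blink_events(cs, 1L)
  expect_length(ev$times, 10)
  # peak of the injected template sits 10 samples after its start index
  true_t <- (round(true_idx) - 1 + 10) / rate
  expect_true(all(abs(ev$times - true_t) <= 0.025))
  # flat source -> no events
  cs0 <- cs; cs0$sources <- matrix(rep(0.1, n), 1)
  expect_length(detect_blink_events(cs0, 1L)$times, 0)
  # two peaks 50 ms apart merge into one event
  src2 <- rnorm(n, 0, 0.1)
  src2[1000] <- 10; src2[1005] <- 9
  cs2 <- cs; cs2$sources <- matrix(src2, 1)
  ev2 <- detect_blink_events(cs2, 1L)
  expect_length(ev2$times, 1)
  # empty flagged set is the undefined marker
  expect_null(detect_blink_events(cs, integer(0)))
})

test_that("blink rate uses the effective episode duration", {
  ev <- structure(list(times = seq(2, 58, length.out = 14), component = 1L),
                  class = "blink_events")
  expect_equal(blink_rate(ev, c(0, 60)), 14)
  expect_equal(blink_rate(structure(list(times = numeric(0), component = 1L),
                                    class = "blink_events"), c(0, 60)), 0)
  ev10 <- structure(list(times = seq(1, 50, length.out = 10), component = 1L),
                    class = "blink_events")
  rem <- data.frame(start = 60, end = 120)
  expect_equal(blink_rate(ev10, c(0, 120), rem), 10)
  expect_true(is.na(blink_rate(ev10, c(0, 60), data.frame(start = 0, end = 60))))
  expect_true(is.na(blink_rate(NULL, c(0, 60))))
})

test_that("the full chain recovers the realized blink rate end to end", {
  withr::with_seed(46, {
    bt <- simulate_blink_times(14, 300)
    eeg <- synthesize_eeg(bt, small_cfg(), 300)
  })
  out <- eeg_blinks_chain(eeg, seed = 2, out_rate = 100, nc = 10,
                          est_subsample = 3)
  est <- blink_rate(out$events, c(0, 300), out$eeg$removed_intervals)
  truth <- length(bt) / 5
  expect_lt(abs(est - truth) / truth, 0.1)
  # no event inside an excised fragment
  if (nrow(out$eeg$removed_intervals)) {
    for (i in seq_len(nrow(out$eeg$removed_intervals)))
      expect_false(any(out$events$times >= out$eeg$removed_intervals$start[i] &
                       out$events$times < out$eeg$removed_intervals$end[i]))
  }
})

test_that("halving the simulated blink rate lowers the estimate", {
  rates <- withr::with_seed(47, {
    t(vapply(1:6, function(i) {
      bt_hi <- simulate_blink_times(16, 120)
      bt_lo <- simulate_blink_times(8, 120)
      cfg <- small_cfg()
      e_hi <- synthesize_eeg(bt_hi, cfg, 120)
      e_lo <- synthesize_eeg(bt_lo, cfg, 120)
      c(hi = blink_rate(eeg_blinks_chain(e_hi, seed = i, out_rate = 100,
                                         nc = 8, est_subsample = 3)$events, c(0, 120)),
        lo = blink_rate(eeg_blinks_chain(e_lo, seed = i, out_rate = 100,
                                         nc = 8, est_subsample = 3)$events, c(0, 120)))
    }, numeric(2)))
  })
  expect_true(all(rates[, "hi"] > rates[, "lo"]))
})
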