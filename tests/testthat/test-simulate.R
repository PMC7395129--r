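test_that("session layout is validated and the default has seven episodes", {
  lay <- default_session_layout()
  expect_equal(nrow(lay), 7)
  expect_equal(lay$start[1], 0)
  expect_true(all(diff(lay$start) > 0))
  expect_equal(lay$end[-7], lay$start[-1])   # contiguous
  expect_error(session_layout("Task1", 1000), "900 s")
  expect_error(session_layout(c("Rest", "Rest"), c(60, 60)), "task")
  expect_error(session_layout("Nope", 60), "unknown")
})

test_that("config rejects out-of-band respiration and bad counts", {
  expect_error(simulation_config(resp_freq = 0.1), "high-frequency band")
  expect_error(simulation_config(resp_freq = 0.9), "high-frequency band")
  expect_error(simulation_config(n_subjects = 0), "n_subjects")
  expect_s3_class(simulation_config(), "simulation_config")
})

test_that("hr truth has the stated amplitude and spectral peak", {
  hr <- simulate_hr_truth(70, 0, 0.25, 60, rate = 10)
  expect_equal(hr, rep(70, 600))
  hr <- simulate_hr_truth(70, 0.05, 0.25, 600, rate = 10)
  expect_equal(max(hr), 73.5, tolerance = 1e-3)
  expect_equal(min(hr), 66.5, tolerance = 1e-3)
  expect_equal(oracle_peak_freq(hr, 10), 0.25, tolerance = 0.01)
  expect_error(simulate_hr_truth(20, 0, 0.25, 10), "30, 200")
})

test_that("cohort simulation is deterministic given the seed", {
  cfg <- simulation_config(n_subjects = 1, seed = 99,
                           layout = default_session_layout(task_s = 60, rest_s = 30),
                           eeg_rate = 200, n_eeg_channels = 4)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(length(a), 1)
  expect_equal(nrow(a[[1]]$layout), 7)
})

test_that("a default cohort yields one bundle with 7 episodes per subject", {
  cfg <- simulation_config(n_subjects = 3, seed = 5,
                           layout = default_session_layout(task_s = 60, rest_s = 30))
  co <- simulate_cohort(cfg, include_eeg = FALSE)
  expect_length(co, 3)
  for (b in co) {
    expect_equal(nrow(b$layout), 7)
    expect_equal(nrow(b$optical$samples), 2 * cfg$n_fnirs_pairs)
    expect_equal(ncol(b$optical$samples), 300 * cfg$fnirs_rate)
    expect_true(all(b$truth$true_hr >= 30 & b$truth$true_hr <= 200))
    expect_true(all(diff(b$truth$true_blink_times) > 0))
  }
})

test_that("zero load effects leave episode-mean true HR exchangeable", {
  # with all couplings off, task-vs-rest differences in the episode-mean
  # true heart rate are pure sampling noise: their distribution over
  # replicates is centred at zero
  cfg <- simulation_config(
    n_subjects = 1, layout = default_session_layout(task_s = 60, rest_s = 60),
    load_effects = list(hr = 0, rsa = 0, br = 0),
    trait_effects = list(hr = 0, rsa = 0, br = 0, rt = 0))
  diffs <- vapply(1:60, function(i) {
    cfg$seed <- 7000 + i
    b <- simulate_cohort(cfg, include_eeg = FALSE, include_fnirs = FALSE)[[1]]
    lay <- b$layout
    epm <- vapply(seq_len(nrow(lay)), function(e) {
      sel <- b$truth$t >= lay$start[e] & b$truth$t < lay$end[e]
      mean(b$truth$true_hr[sel])
    }, numeric(1))
    mean(epm[grepl("^Task", lay$label)]) - mean(epm[lay$label == "Rest"])
  }, numeric(1))
  expect_gt(t.test(diffs)$p.value, 0.01)
})

test_that("blink times respect rate, refractory period and Poisson mean", {
  expect_length(simulate_blink_times(0, 300), 0)
  withr::with_seed(11, {
    counts <- replicate(200, length(simulate_blink_times(14, 300)))
    # mean count ~ 70, within 3 sigma of the Poisson-like expectation
    expect_lt(abs(mean(counts) - 70), 3 * sqrt(70) / sqrt(200))
    bt <- simulate_blink_times(25, 600)
    expect_true(all(diff(bt) >= 0.5))
  })
})

test_that("blink transients are frontally weighted and absent without blinks", {
  cfg <- simulation_config(eeg_rate = 250, n_eeg_channels = 19)
  withr::with_seed(3, {
    eeg0 <- synthesize_eeg(numeric(0), cfg, 20)
    eeg1 <- synthesize_eeg(c(2, 5, 8, 11, 14, 17), cfg, 20)
  })
  v0 <- apply(eeg0$samples, 1, var)
  v1 <- apply(eeg1$samples, 1, var)
  frontal <- eeg1$channel_names %in% c("Fp1", "Fp2")
  posterior <- eeg1$channel_names %in% c("O1", "O2")
  expect_gt(mean(v1[frontal]), mean(v1[posterior]))
  # background-only recording has no frontal excess
  expect_lt(mean(v0[frontal]) / mean(v0[posterior]), 2)
})

test_that("behaviour simulation matches its stated construction", {
  cfg <- simulation_config()
  lay <- default_session_layout(task_s = 120, rest_s = 60)
  withr::with_seed(21, {
    beh <- simulate_behaviour(rep(0.5, nrow(lay)), lay, cfg)
  })
  tg <- beh$targets
  nasa_cols <- grep("^nasa_(?!tlx)", names(tg), value = TRUE, perl = TRUE)
  scores <- unlist(tg[nasa_cols])
  expect_true(all(scores %% 5 == 0 & scores >= 0 & scores <= 100))
  # non-response iff no response before the next onset (final beep exempt)
  log <- beh$log
  for (ep in unique(log$episode)) {
    sl <- log[log$episode == ep, ]
    nxt <- c(sl$onset[-1], Inf)
    responded <- !is.na(sl$response_time) & sl$response_time < nxt
    m <- secondary_task_metrics(sl, c(min(sl$onset), max(sl$onset) + 1))
    expect_equal(m$non_response_rate, mean(!responded))
  }
  # inter-onset gaps respect the configured range
  gaps <- unlist(tapply(log$onset, log$episode, diff))
  expect_true(all(gaps >= cfg$beep_interval_range[1] - 1e-9 &
                  gaps <= cfg$beep_interval_range[2] + 1e-9))
})

test_that("null reaction-time link makes episodes exchangeable", {
  cfg <- simulation_config(trait_effects = list(hr = 0, rsa = 0, br = 0, rt = 0))
  cfg$target_links$rt$log_slope <- 0
  cfg$target_links$rt$miss_slope <- 0
  lay <- default_session_layout(task_s = 120, rest_s = 120)
  withr::with_seed(31, {
    # pooled RTs from a high-load and a zero-load episode follow the same
    # law; the KS test should reject at about the nominal rate
    rej <- replicate(100, {
      beh <- simulate_behaviour(c(0, 0, 1, 0, 0, 0, 0), lay, cfg)
      log <- beh$log
      rt1 <- with(log[log$label == "Task1", ], response_time - onset)
      rt2 <- with(log[log$label == "Task2", ], response_time - onset)
      suppressWarnings(ks.test(rt1[!is.na(rt1)], rt2[!is.na(rt2)])$p.value) < 0.05
    })
    expect_lt(mean(rej), 0.15)
  })
})

test_that("monotone couplings hold across a simulated cohort", {
  cfg <- simulation_config(n_subjects = 31, seed = 404)
  co <- simulate_cohort(cfg, include_eeg = FALSE, include_fnirs = FALSE)
  rows <- do.call(rbind, lapply(co, function(b) {
    lay <- b$layout
    task <- grepl("^Task", lay$label)
    epm <- vapply(which(task), function(e) {
      sel <- b$truth$t >= lay$start[e] & b$truth$t < lay$end[e]
      mean(b$truth$true_hr[sel])
    }, numeric(1))
    data.frame(load = b$truth$true_load[task], hr = epm,
               depth = b$truth$rsa_depth_by_episode[task],
               br = b$truth$blink_rate_by_episode[task])
  }))
  expect_gt(cor(rows$load, rows$hr), 0)
  expect_lt(cor(rows$load, rows$depth), 0)
  expect_lt(cor(rows$load, rows$br), 0)
})

test_that("generated cardiac component peaks inside the 0.5-2 Hz band", {
  cfg <- simulation_config(n_subjects = 1, seed = 12,
                           layout = default_session_layout(task_s = 60, rest_s = 30))
  b <- simulate_cohort(cfg, include_eeg = FALSE)[[1]]
  hemo <- convert_beer_lambert(b$optical)
  card <- extract_cardiac_waveform(hemo)
  pk <- oracle_peak_freq(card$x, card$rate)
  expect_gt(pk, 0.5)
  expect_lt(pk, 2)
})
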