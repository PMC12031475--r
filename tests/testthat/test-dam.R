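# Helper: build a calibration profile by hand for detector-only tests.
fake_profile <- function(threshold, window = 10L) {
  structure(list(rest_mean_amplitude = 0, max_mean_amplitude = threshold * 2,
                 threshold_fraction = 0.5, trigger_threshold = threshold,
                 gain = 1, window = window),
            class = "calibration_profile")
}

# Helper: a deterministic stream whose amplitude is controlled directly —
# alternating +/- per-sample levels give |diff| ~ 2 * level.
alternating_stream <- function(levels, fs = 100) {
  emg_recording(fs, levels * rep_len(c(1, -1), length(levels)))
}

test_that("amplitude step is the absolute consecutive difference", {
  expect_equal(amplitude_step(5, 7), 2)
  expect_equal(amplitude_step(7, 4), 3)
  expect_equal(amplitude_step(3.2, 3.2), 0)
  expect_equal(amplitude_step(c(0, 10), c(5, 5)), c(5, 5))
})

test_that("rolling amplitude averages the last `window` values with prefix warm-up", {
  expect_equal(rolling_amplitude(rep(4, 50), 10), rep(4, 50))
  expect_equal(rolling_amplitude(c(0, 2, 4), 2), c(0, 1, 3))
  expect_error(rolling_amplitude(numeric(0)))
  # steady-state variance of the rolling mean ~ input variance / window
  set.seed(1)
  x <- abs(rnorm(300 * 200))
  r <- rolling_amplitude(x, 300)[-(1:300)]
  ratio <- var(r) / var(x) * 300
  expect_gt(ratio, 0.75)
  expect_lt(ratio, 1.25)
})

test_that("threshold interpolates 60% of the rest-to-max range", {
  expect_equal(compute_threshold(0, 1, 0.60), 0.60)
  expect_equal(compute_threshold(10, 110, 0.60), 70)
  expect_error(compute_threshold(5, 5, 0.60),
               class = "semgrip_calibration_failure")
  expect_error(compute_threshold(5, 4, 0.60),
               class = "semgrip_calibration_failure")
  expect_error(compute_threshold(0, 1, 0), class = "semgrip_config_error")
})

test_that("calibration separates rest from a maximal squeeze and is linear in gain", {
  cfg <- sim_config(duration_s = 14, event_onsets_s = 10, burst_duration_s = 3,
                    burst_gain = 5, seed = 3)
  stream <- simulate_session(cfg)$recording
  p1 <- run_calibration(stream, gain = 1)
  expect_s3_class(p1, "calibration_profile")
  expect_gt(p1$max_mean_amplitude, p1$rest_mean_amplitude)
  expect_gte(p1$trigger_threshold, p1$rest_mean_amplitude)
  expect_lte(p1$trigger_threshold, p1$max_mean_amplitude)
  p2 <- run_calibration(stream, gain = 2)
  expect_equal(p2$rest_mean_amplitude, 2 * p1$rest_mean_amplitude)
  expect_equal(p2$max_mean_amplitude, 2 * p1$max_mean_amplitude)
  expect_equal(p2$trigger_threshold, 2 * p1$trigger_threshold)
  # a flat stream cannot calibrate
  expect_error(run_calibration(emg_recording(500, rep(0, 14 * 500))),
               class = "semgrip_calibration_failure")
  # too-short stream
  expect_error(run_calibration(emg_recording(500, rnorm(500))))
})

test_that("state timeline lasts 5/5/3 seconds at any sampling rate", {
  for (fs in c(500, 250)) {
    cfg <- sim_config(duration_s = 14, sampling_rate_hz = fs,
                      event_onsets_s = 10, burst_duration_s = 3,
                      band_high_hz = 0.4 * fs, target_mdf_hz = 0.2 * fs,
                      band_low_hz = 10, burst_gain = 5, seed = 3)
    p <- run_calibration(simulate_session(cfg)$recording)
    durs <- table(p$state_timeline$state) / fs
    expect_equal(as.numeric(durs[c("S1", "S2", "S3")]), c(5, 5, 3))
    expect_equal(as.numeric(durs["S4"]), 1)
  }
})

test_that("triggers fire on rising threshold crossings with a refractory period", {
  # quiet stream: no events
  quiet <- alternating_stream(rep(1, 500))
  expect_equal(nrow(detect_triggers(quiet, fake_profile(10))$events), 0L)
  # one clean burst far above threshold: exactly one event inside the burst
  lv1 <- rep(1, 500); lv1[201:300] <- 10          # burst at 2.0-3.0 s
  d1 <- detect_triggers(alternating_stream(lv1), fake_profile(10, 5L))
  expect_equal(nrow(d1$events), 1L)
  expect_gte(d1$events$time_s, 2)
  expect_lte(d1$events$time_s, 3.1)
  # two bursts separated by less than the refractory period collapse to one
  lv2 <- rep(1, 1000); lv2[301:310] <- 10; lv2[321:330] <- 10  # 0.1 s apart
  d2 <- detect_triggers(alternating_stream(lv2), fake_profile(10, 5L),
                        refractory_s = 0.3)
  expect_equal(nrow(d2$events), 1L)
  # well-separated bursts both detected, and the activity trace is per sample
  lv3 <- rep(1, 1000); lv3[301:350] <- 10; lv3[701:750] <- 10  # 4 s apart
  d3 <- detect_triggers(alternating_stream(lv3), fake_profile(10, 5L),
                        refractory_s = 0.3)
  expect_equal(nrow(d3$events), 2L)
  expect_length(d3$activity, 1000L)
})

test_that("detection is invariant to a DC offset of the raw stream", {
  cfg <- sim_config(duration_s = 30, event_onsets_s = c(5, 15, 25),
                    burst_gain = 5, seed = 8)
  s <- simulate_session(cfg)
  cal <- simulate_session(sim_config(duration_s = 14, event_onsets_s = 10,
                                     burst_duration_s = 3, burst_gain = 5,
                                     seed = 9))
  p <- run_calibration(cal$recording)
  d0 <- detect_triggers(s$recording, p)
  shifted <- emg_recording(500, s$recording$samples + 1000)
  d1 <- detect_triggers(shifted, p)
  expect_identical(d0$events, d1$events)
  expect_identical(d0$activity, d1$activity)
})

test_that("lowering the threshold fraction never loses events", {
  cfg <- sim_config(duration_s = 60, mean_inter_event_s = 5, burst_gain = 5,
                    seed = 21)
  s <- simulate_session(cfg)
  cal <- simulate_session(sim_config(duration_s = 14, event_onsets_s = 10,
                                     burst_duration_s = 3, burst_gain = 5,
                                     seed = 22))
  counts <- vapply(c(0.9, 0.7, 0.5, 0.3), function(fr) {
    p <- run_calibration(cal$recording, threshold_fraction = fr)
    nrow(detect_triggers(s$recording, p)$events)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("simulated squeezes are detected nearly perfectly end to end", {
  cal <- simulate_session(sim_config(duration_s = 14, event_onsets_s = 10,
                                     burst_duration_s = 3, burst_gain = 5,
                                     seed = 31))
  p <- run_calibration(cal$recording)
  s <- simulate_session(sim_config(duration_s = 150, mean_inter_event_s = 6,
                                   burst_gain = 5, seed = 32))
  expect_gte(nrow(s$truth), 20)
  d <- detect_triggers(s$recording, p)
  m <- match_events(s$truth$onset_s + 0.35, d$events$time_s, tolerance_s = 0.2)
  expect_gte(m$f1, 0.95)
})
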