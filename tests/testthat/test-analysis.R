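fs <- 500

test_that("bandpass keeps the sEMG band and rejects out-of-band content", {
  t <- (0:4999) / fs
  inband <- sin(2 * pi * 50 * t)
  expect_equal(sd(bandpass(inband, fs)) / sd(inband), 1, tolerance = 0.02)
  low <- sin(2 * pi * 5 * t)
  atten_db <- 20 * log10(sd(bandpass(low, fs)) / sd(low))
  expect_lt(atten_db, -20)
  expect_lt(max(abs(bandpass(rep(1, 1000), fs))), 1e-3)
  expect_error(bandpass(inband, fs = 30))
})

test_that("normalization maps to [-1,1], rectification to [0,1], scale-free", {
  nr <- normalize_rectify(c(-2, 1, 2))
  expect_equal(nr$normalized, c(-1, 0.5, 1))
  expect_equal(nr$rectified, c(1, 0.5, 1))
  expect_equal(normalize_rectify(nr$normalized)$normalized, nr$normalized)
  x <- rnorm(100)
  expect_equal(normalize_rectify(x * 7)$rectified,
               normalize_rectify(x)$rectified)
  expect_error(normalize_rectify(rep(0, 10)))
})

test_that("peak picking finds one peak per contraction", {
  expect_identical(find_activity_peaks(rep(0, 1000), fs), integer(0))
  for (sd in 1:3) {
    on <- seq(2, by = 3, length.out = 20)
    s <- simulate_session(sim_config(duration_s = 65, event_onsets_s = on,
                                     burst_gain = 5, seed = sd))
    nr <- normalize_rectify(bandpass(s$recording$samples, fs))
    pk <- find_activity_peaks(nr$rectified, fs)
    expect_gte(length(pk), 18)
    expect_lte(length(pk), 22)
  }
  # of two excursions closer than the separation, the taller survives
  env <- c(rep(0, 100), rep(0.5, 50), rep(0, 30), rep(0.3, 50), rep(0, 100))
  pk <- find_activity_peaks(env, fs, min_separation_s = 0.5, smooth_s = 0.01)
  expect_length(pk, 1L)
  expect_true(env[pk] == 0.5)
})

test_that("median frequency matches analytic and brute-force expectations", {
  t <- (0:999) / fs
  expect_equal(median_frequency(sin(2 * pi * 50 * t), fs), 50, tolerance = 1)
  two <- sin(2 * pi * 60 * t) + sin(2 * pi * 120 * t)
  mdf2 <- median_frequency(two, fs)
  expect_gt(mdf2, 85); expect_lt(mdf2, 95)
  # amplitude scaling changes nothing
  x <- bandpass(simulate_session(sim_config(duration_s = 10, seed = 4)
                                 )$recording$samples, fs)
  expect_equal(median_frequency(x, fs), median_frequency(x * 100, fs))
  # agreement with the plain-periodogram cumulative-sum oracle
  for (sd in 1:3) {
    s <- simulate_session(sim_config(duration_s = 8, target_mdf_hz = 90,
                                     seed = sd))
    xf <- bandpass(s$recording$samples, fs)
    expect_equal(median_frequency(xf, fs), mdf_periodogram(xf, fs),
                 tolerance = 5)
  }
  expect_error(median_frequency(rep(0, 1000), fs))
  expect_error(median_frequency(rnorm(100), fs))     # < 1 s
})

test_that("segment metrics compute per-game MPA/MDF and the fatigue change", {
  s <- simulate_session(sim_config(duration_s = 180, mean_inter_event_s = 6,
                                   burst_gain = 5, seed = 10))
  gb <- data.frame(game_id = paste("Game", 1:3),
                   start_s = c(0, 60, 120), end_s = c(60, 120, 180))
  sm <- segment_metrics(s$recording, gb)
  expect_equal(sm$metrics$segment_id, paste("Game", 1:3))
  expect_true(all(sm$metrics$mpa >= 0 & sm$metrics$mpa <= 1))
  expect_true(all(sm$metrics$mdf_hz >= 20 & sm$metrics$mdf_hz <= 250))
  expect_equal(sm$fatigue$pct_change_mdf,
               100 * (sm$metrics$mdf_hz[3] - sm$metrics$mdf_hz[1]) /
                 sm$metrics$mdf_hz[1])
  expect_equal(nrow(sm$per_minute_mdf), 3L)
  # identical game segments give (near) zero percent change
  block <- simulate_session(sim_config(duration_s = 60,
                                       event_onsets_s = c(10, 30, 50),
                                       burst_gain = 5, seed = 11))
  tripled <- emg_recording(fs, rep(block$recording$samples, 3))
  sm0 <- segment_metrics(tripled, gb)
  expect_equal(sm0$fatigue$pct_change_mdf, 0, tolerance = 0.5)
  # amplitude scaling leaves both metrics unchanged
  scaled <- emg_recording(fs, s$recording$samples * 13)
  sm_k <- segment_metrics(scaled, gb)
  expect_equal(sm_k$metrics$mpa, sm$metrics$mpa)
  expect_equal(sm_k$metrics$mdf_hz, sm$metrics$mdf_hz)
  # overlapping segments rejected
  bad <- data.frame(game_id = 1:3, start_s = c(0, 50, 120),
                    end_s = c(60, 120, 180))
  expect_error(segment_metrics(s$recording, bad))
})

test_that("a configured MDF drift yields a declining per-minute series", {
  cors <- vapply(1:3, function(sd) {
    s <- simulate_session(sim_config(duration_s = 300, mean_inter_event_s = 8,
                                     burst_gain = 3, target_mdf_hz = 80,
                                     mdf_drift_pct_per_min = -4, seed = sd))
    m <- mdf_over_time(bandpass(s$recording$samples, fs), fs, block_s = 60)
    cor(m$t_mid_s, m$mdf_hz, method = "spearman")
  }, numeric(1))
  expect_lt(mean(cors), -0.8)
})
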