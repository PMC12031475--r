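test_that("configuration invariants are enforced", {
  expect_error(sim_config(duration_s = 10, event_onsets_s = c(2, 2.5)),
               class = "semgrip_scheduling_error")
  expect_error(sim_config(duration_s = 10, target_mdf_hz = 300),
               class = "semgrip_config_error")
  expect_error(sim_config(duration_s = 10, target_mdf_hz = 10),
               class = "semgrip_config_error")
  expect_error(sim_config(duration_s = 1.0001),
               class = "semgrip_config_error")
  expect_error(sim_config(duration_s = 10, burst_gain = 0.5),
               class = "semgrip_config_error")
  expect_error(sim_config(duration_s = 10, event_onsets_s = 9.5),
               class = "semgrip_config_error")
})

test_that("session generation is deterministic and follows the schedule", {
  cfg <- sim_config(duration_s = 10, event_onsets_s = c(2, 5, 8),
                    burst_duration_s = 1, seed = 42)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$recording$samples, s2$recording$samples)
  expect_identical(s1$truth, s2$truth)
  expect_equal(nrow(s1$truth), 3L)
  expect_equal(s1$truth$onset_s, c(2, 5, 8))
  expect_length(s1$recording$samples, 10 * 500)
  # a different seed changes the samples
  s3 <- simulate_session(sim_config(duration_s = 10,
                                    event_onsets_s = c(2, 5, 8), seed = 43))
  expect_false(identical(s1$recording$samples, s3$recording$samples))
})

test_that("burst envelope raises amplitude inside bursts only when gain > 1", {
  onsets <- seq(2, by = 4, length.out = 10)
  seg_rms <- function(s) {
    t <- recording_times(s$recording)
    burst_rms <- vapply(seq_along(onsets), function(i) {
      sel <- t >= onsets[i] + 0.1 & t <= onsets[i] + 0.9
      sqrt(mean(s$recording$samples[sel]^2))
    }, numeric(1))
    rest_rms <- vapply(seq_along(onsets), function(i) {
      sel <- t >= onsets[i] + 1.5 & t <= onsets[i] + 2.3
      sqrt(mean(s$recording$samples[sel]^2))
    }, numeric(1))
    list(burst = burst_rms, rest = rest_rms)
  }
  s_hot <- simulate_session(sim_config(duration_s = 44, event_onsets_s = onsets,
                                       burst_gain = 5, seed = 1))
  r <- seg_rms(s_hot)
  expect_true(all(r$burst > r$rest))
  # mean rectified amplitude higher inside bursts
  expect_gt(mean(r$burst), 3 * mean(r$rest))
  # degenerate gain: burst and rest RMS statistically indistinguishable
  s_flat <- simulate_session(sim_config(duration_s = 44, event_onsets_s = onsets,
                                        burst_gain = 1, seed = 1))
  r0 <- seg_rms(s_flat)
  expect_gt(t.test(r0$burst, r0$rest)$p.value, 0.05)
})

test_that("estimated median frequency recovers the configured target", {
  for (sd in 1:3) {
    s <- simulate_session(sim_config(duration_s = 60, target_mdf_hz = 100,
                                     seed = sd))
    mdf <- median_frequency(bandpass(s$recording$samples, 500), 500)
    expect_gt(mdf, 90)
    expect_lt(mdf, 110)
  }
})

test_that("cohort generation is deterministic and respects config ranges", {
  base <- sim_config(duration_s = 30, mean_inter_event_s = 6)
  c1 <- simulate_cohort(2, list(target_mdf_hz = c(50, 60)), seed = 9,
                        base = base)
  c2 <- simulate_cohort(2, list(target_mdf_hz = c(50, 60)), seed = 9,
                        base = base)
  expect_identical(lapply(c1, `[[`, "recording"),
                   lapply(c2, `[[`, "recording"))
  expect_true(all(vapply(c1, function(s)
    s$config$target_mdf_hz >= 50 && s$config$target_mdf_hz <= 60,
    logical(1))))
  # disjoint MDF ranges separate in the estimates
  lo <- simulate_cohort(1, list(target_mdf_hz = c(50, 60)), seed = 5,
                        base = base)[[1]]
  hi <- simulate_cohort(1, list(target_mdf_hz = c(90, 100)), seed = 5,
                        base = base)[[1]]
  mdf_of <- function(s) median_frequency(bandpass(s$recording$samples, 500), 500)
  expect_lt(mdf_of(lo), mdf_of(hi))
  expect_error(simulate_cohort(2, list(target_mdf_hz = c(60, 50)), seed = 1),
               class = "semgrip_config_error")
})

test_that("DC offset and quantisation behave like an ADC front-end", {
  cfg0 <- sim_config(duration_s = 5, event_onsets_s = 2, seed = 3)
  cfg1 <- sim_config(duration_s = 5, event_onsets_s = 2, seed = 3,
                     dc_offset = 512)
  s0 <- simulate_session(cfg0)
  s1 <- simulate_session(cfg1)
  expect_equal(s1$recording$samples - 512, s0$recording$samples)
  cfgq <- sim_config(duration_s = 5, event_onsets_s = 2, seed = 3,
                     adc_lsb = 0.01)
  sq <- simulate_session(cfgq)
  expect_true(all(abs(sq$recording$samples / 0.01 -
                        round(sq$recording$samples / 0.01)) < 1e-9))
})
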