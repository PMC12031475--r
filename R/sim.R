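#' Simulation configuration for a synthetic sEMG session
#'
#' Describes one synthetic surface-EMG recording session: a band-limited
#' stochastic "interference pattern" signal whose power spectrum is shaped so
#' that its median frequency (MDF) sits at a chosen target, amplitude-modulated
#' by a rest/contraction-burst envelope with known burst onsets. An optional
#' linear MDF drift over the session emulates the spectral compression seen in
#' fatiguing muscle.
#'
#' The spectral template is a unimodal Gaussian bump centred on the current
#' target MDF, truncated to the `[band_low_hz, band_high_hz]` band, with its
#' width chosen as one third of the distance to the nearest band edge so the
#' template stays effectively symmetric inside the band and its median equals
#' the target. Each 1 s block of the session is synthesised independently in
#' the frequency domain (random Gaussian spectral coefficients scaled by the
#' template), giving a piecewise-constant MDF that tracks the linear drift.
#'
#' Bursts use trapezoidal envelopes with 50 ms linear rise/fall ramps so that
#' onset times are well defined and no broadband step artifacts are injected.
#'
#' @param duration_s session length in seconds; `duration_s * sampling_rate_hz`
#'   must be a whole number of samples.
#' @param sampling_rate_hz sampling rate (default 500, the acquisition
#'   module's streaming rate).
#' @param event_onsets_s optional sorted vector of burst onset times (s). If
#'   `NULL`, bursts are scheduled randomly using `mean_inter_event_s`.
#' @param mean_inter_event_s mean inter-onset interval for random scheduling
#'   (ignored when `event_onsets_s` is given).
#' @param burst_duration_s duration of each contraction burst (s).
#' @param rest_rms RMS amplitude of the resting signal, arbitrary ADC-like
#'   units.
#' @param burst_gain ratio of burst RMS to rest RMS; must be >= 1
#'   (`1` produces a flat envelope, useful as a degenerate control).
#' @param band_low_hz,band_high_hz spectral band of the synthetic signal
#'   (defaults 20 and 250 Hz, the usable sEMG band).
#' @param target_mdf_hz target median frequency at session start; must lie
#'   strictly inside the band. Default 60 Hz, typical of forearm flexor sEMG.
#' @param mdf_drift_pct_per_min linear MDF drift in percent of the initial
#'   target per minute; negative values emulate fatigue.
#' @param dc_offset constant added to every sample (an ADC mid-rail offset).
#' @param adc_lsb optional quantisation step; samples are rounded to this grid
#'   to mimic an ADC. `NULL` disables quantisation.
#' @param seed integer seed; identical configurations with identical seeds
#'   produce identical sessions.
#'
#' @return an object of class `sim_config`.
#' @seealso [simulate_session()], [simulate_cohort()]
#' @export
sim_config <- function(duration_s,
                       sampling_rate_hz = 500,
                       event_onsets_s = NULL,
                       mean_inter_event_s = NULL,
                       burst_duration_s = 1,
                       rest_rms = 1,
                       burst_gain = 5,
                       band_low_hz = 20,
                       band_high_hz = 250,
                       target_mdf_hz = 60,
                       mdf_drift_pct_per_min = 0,
                       dc_offset = 0,
                       adc_lsb = NULL,
                       seed = 1L) {
  assert_number(duration_s, "duration_s", positive = TRUE)
  assert_number(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  assert_number(burst_duration_s, "burst_duration_s", positive = TRUE)
  assert_number(rest_rms, "rest_rms", positive = TRUE)
  assert_number(burst_gain, "burst_gain")
  assert_number(target_mdf_hz, "target_mdf_hz", positive = TRUE)
  assert_number(mdf_drift_pct_per_min, "mdf_drift_pct_per_min")
  assert_number(dc_offset, "dc_offset")
  if (burst_gain < 1) {
    stopf("`burst_gain` must be >= 1", class = "semgrip_config_error")
  }
  n <- duration_s * sampling_rate_hz
  if (abs(n - round(n)) > 1e-8) {
    stopf("duration_s * sampling_rate_hz must be a whole number of samples",
          class = "semgrip_config_error")
  }
  nyq <- sampling_rate_hz / 2
  if (!(band_low_hz < target_mdf_hz && target_mdf_hz < band_high_hz &&
        band_high_hz <= nyq)) {
    stopf(paste("need band_low_hz < target_mdf_hz < band_high_hz <=",
                "sampling_rate_hz/2 (got %g < %g < %g <= %g)"),
          band_low_hz, target_mdf_hz, band_high_hz, nyq,
          class = "semgrip_config_error")
  }
  if (!is.null(event_onsets_s)) {
    if (is.unsorted(event_onsets_s, strictly = TRUE)) {
      stopf("event_onsets_s must be strictly increasing",
            class = "semgrip_config_error")
    }
    if (any(event_onsets_s < 0) ||
        any(event_onsets_s + burst_duration_s > duration_s)) {
      stopf("all burst intervals must lie inside [0, duration_s]",
            class = "semgrip_config_error")
    }
    if (length(event_onsets_s) > 1 &&
        any(diff(event_onsets_s) < burst_duration_s)) {
      stopf("burst intervals overlap: onsets closer than burst_duration_s",
            class = "semgrip_scheduling_error")
    }
  } else if (!is.null(mean_inter_event_s)) {
    assert_number(mean_inter_event_s, "mean_inter_event_s", positive = TRUE)
    if (mean_inter_event_s <= burst_duration_s) {
      stopf("mean_inter_event_s must exceed burst_duration_s",
            class = "semgrip_scheduling_error")
    }
  }
  structure(
    list(duration_s = duration_s,
         sampling_rate_hz = sampling_rate_hz,
         event_onsets_s = event_onsets_s,
         mean_inter_event_s = mean_inter_event_s,
         burst_duration_s = burst_duration_s,
         rest_rms = rest_rms,
         burst_gain = burst_gain,
         band_low_hz = band_low_hz,
         band_high_hz = band_high_hz,
         target_mdf_hz = target_mdf_hz,
         mdf_drift_pct_per_min = mdf_drift_pct_per_min,
         dc_offset = dc_offset,
         adc_lsb = adc_lsb,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Construct a uniformly sampled EMG recording
#'
#' @param sampling_rate_hz sampling rate in Hz.
#' @param samples numeric vector of raw samples (arbitrary ADC-like units).
#' @param start_time_s time of the first sample relative to session start.
#' @return an object of class `emg_recording`.
#' @export
emg_recording <- function(sampling_rate_hz, samples, start_time_s = 0) {
  assert_number(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stopf("a recording needs at least 2 samples")
  structure(list(sampling_rate_hz = sampling_rate_hz,
                 samples = samples,
                 start_time_s = start_time_s),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d samples @ %g Hz (%.1f s), start %g s\n",
              length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz, x$start_time_s))
  invisible(x)
}

#' Sample times of a recording
#'
#' @param rec an [emg_recording()].
#' @return numeric vector of per-sample times in seconds.
#' @export
recording_times <- function(rec) {
  rec$start_time_s + (seq_along(rec$samples) - 1) / rec$sampling_rate_hz
}

# Gaussian spectral template truncated to the band; width = 1/3 of the
# distance to the nearest band edge so the in-band shape stays symmetric and
# its median equals `mdf`.
spectral_template <- function(freq, mdf, low, high) {
  sigma <- max(min(mdf - low, high - mdf) / 3, 1)
  s <- exp(-(freq - mdf)^2 / (2 * sigma^2))
  s[freq < low | freq > high] <- 0
  s
}

# One block of unit-RMS noise with power spectrum shaped by the template.
# Synthesised in the frequency domain: Hermitian-symmetric Gaussian
# coefficients scaled by sqrt(S(f)).
shaped_noise_block <- function(n, fs, mdf, low, high) {
  freq <- (0:(n %/% 2)) * fs / n
  amp <- sqrt(spectral_template(freq, mdf, low, high))
  k <- length(freq)
  z <- complex(real = rnorm(k), imaginary = rnorm(k)) * amp
  z[1] <- 0                              # no DC
  if (n %% 2 == 0) z[k] <- complex(real = rnorm(1), imaginary = 0) * amp[k]
  full <- c(z, Conj(z[seq(if (n %% 2 == 0) k - 1 else k, 2)]))
  x <- Re(fft(full, inverse = TRUE)) / n
  r <- sqrt(mean(x^2))
  if (r == 0) x else x / r
}

# Trapezoidal rest/burst envelope on the sample grid.
burst_envelope <- function(n, fs, onsets, dur, rest_rms, gain, ramp_s = 0.05) {
  t <- (seq_len(n) - 1) / fs
  g <- numeric(n)
  ramp <- min(ramp_s, dur / 2)
  for (on in onsets) {
    off <- on + dur
    rise <- t >= on & t < on + ramp
    hold <- t >= on + ramp & t <= off - ramp
    fall <- t > off - ramp & t <= off
    g[rise] <- pmax(g[rise], (t[rise] - on) / ramp)
    g[hold] <- 1
    g[fall] <- pmax(g[fall], (off - t[fall]) / ramp)
  }
  rest_rms * (1 + (gain - 1) * g)
}

schedule_random_onsets <- function(duration_s, mean_gap, burst_dur) {
  min_gap <- burst_dur + 0.5
  onsets <- numeric(0)
  t <- 1                                  # lead-in before the first burst
  repeat {
    gap <- max(min_gap, runif(1, 0.5, 1.5) * mean_gap)
    t_next <- if (length(onsets) == 0) t else onsets[length(onsets)] + gap
    if (t_next + burst_dur > duration_s - 0.5) break
    onsets <- c(onsets, t_next)
  }
  onsets
}

#' Generate one synthetic sEMG session with ground truth
#'
#' Synthesises the session described by a [sim_config()]: spectrum-shaped
#' noise (piecewise-constant MDF per 1 s block, following the configured
#' linear drift) multiplied by a trapezoidal rest/burst envelope, plus the
#' optional DC offset and ADC quantisation. The same configuration and seed
#' always produce identical samples.
#'
#' @param config a [sim_config()].
#' @return a list with components `recording` (an [emg_recording()]) and
#'   `truth` (data frame with columns `onset_s`, `duration_s`, one row per
#'   contraction burst).
#' @examples
#' s <- simulate_session(sim_config(duration_s = 10, event_onsets_s = c(2, 5, 8)))
#' nrow(s$truth)  # 3 scheduled bursts
#' @export
simulate_session <- function(config) {
  if (!inherits(config, "sim_config")) {
    stopf("`config` must be a sim_config", class = "semgrip_config_error")
  }
  fs <- config$sampling_rate_hz
  n <- as.integer(round(config$duration_s * fs))
  with_seed(config$seed, {
    onsets <- config$event_onsets_s
    if (is.null(onsets)) {
      onsets <- if (is.null(config$mean_inter_event_s)) numeric(0) else {
        schedule_random_onsets(config$duration_s, config$mean_inter_event_s,
                               config$burst_duration_s)
      }
    }
    block_n <- as.integer(round(fs))     # 1 s synthesis blocks
    n_blocks <- ceiling(n / block_n)
    noise <- numeric(n_blocks * block_n)
    for (b in seq_len(n_blocks)) {
      t_mid_min <- (b - 0.5) * (block_n / fs) / 60
      mdf_b <- config$target_mdf_hz *
        (1 + config$mdf_drift_pct_per_min * t_mid_min / 100)
      mdf_b <- min(max(mdf_b, config$band_low_hz + 1),
                   config$band_high_hz - 1)
      idx <- ((b - 1) * block_n + 1):(b * block_n)
      noise[idx] <- shaped_noise_block(block_n, fs, mdf_b,
                                       config$band_low_hz,
                                       config$band_high_hz)
    }
    noise <- noise[seq_len(n)]
    env <- burst_envelope(n, fs, onsets, config$burst_duration_s,
                          config$rest_rms, config$burst_gain)
    x <- noise * env + config$dc_offset
    if (!is.null(config$adc_lsb)) {
      x <- round(x / config$adc_lsb) * config$adc_lsb
    }
    list(
      recording = emg_recording(fs, x, 0),
      truth = data.frame(onset_s = onsets,
                         duration_s = rep(config$burst_duration_s,
                                          length(onsets)))
    )
  })
}

#' Generate a cohort of synthetic subjects
#'
#' Draws one session per subject, with per-subject configuration parameters
#' sampled uniformly inside the supplied ranges and per-subject seeds derived
#' deterministically from the master seed, emulating between-subject
#' variability in a study cohort.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param config_ranges named list of `c(min, max)` ranges for numeric
#'   [sim_config()] fields (e.g. `target_mdf_hz`, `rest_rms`, `burst_gain`);
#'   fields not listed use the values in `base`.
#' @param seed master seed; all per-subject randomness derives from it.
#' @param base a [sim_config()] providing fixed fields for every subject.
#' @return list of per-subject session lists, each as from
#'   [simulate_session()], with the drawn config attached as `$config`.
#' @export
simulate_cohort <- function(n_subjects, config_ranges = list(), seed = 1L,
                            base = sim_config(duration_s = 60,
                                              mean_inter_event_s = 6)) {
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    stopf("n_subjects must be >= 1", class = "semgrip_config_error")
  }
  for (nm in names(config_ranges)) {
    r <- config_ranges[[nm]]
    if (length(r) != 2L || !is.numeric(r) || r[1] > r[2]) {
      stopf("config range `%s` must be c(min, max) with min <= max", nm,
            class = "semgrip_config_error")
    }
  }
  lapply(seq_len(n_subjects), function(i) {
    subj_seed <- derive_seed(seed, i)
    draws <- with_seed(subj_seed, {
      lapply(config_ranges, function(r) runif(1, r[1], r[2]))
    })
    args <- unclass(base)
    args[names(draws)] <- draws
    args$seed <- derive_seed(subj_seed, 1L)
    cfg <- do.call(sim_config, args)
    out <- simulate_session(cfg)
    out$config <- cfg
    out
  })
}
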