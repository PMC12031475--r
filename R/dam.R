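#' Sample-wise sEMG amplitude
#'
#' The acquisition module's amplitude statistic: the absolute difference
#' between the latest raw sample and the previous one. Being a difference, it
#' is invariant to any DC offset in the raw stream.
#'
#' @param prev_sample,curr_sample consecutive raw samples (vectorised).
#' @return non-negative amplitude(s).
#' @export
amplitude_step <- function(prev_sample, curr_sample) {
  abs(curr_sample - prev_sample)
}

# Full amplitude series of a raw stream; element 1 is 0 (no predecessor).
amplitude_series <- function(samples) {
  c(0, abs(diff(samples)))
}

#' Rolling average of amplitude measurements
#'
#' Mean of the last `window` amplitude values at each position. During
#' warm-up (the first `window - 1` positions) the mean is taken over the
#' available prefix rather than zero-padding, avoiding a spurious
#' low-amplitude start.
#'
#' @param amplitudes numeric vector of amplitude measurements.
#' @param window window length in samples (default 300, i.e. 0.6 s at
#'   500 Hz).
#' @return numeric vector the same length as `amplitudes`.
#' @export
rolling_amplitude <- function(amplitudes, window = 300L) {
  if (length(amplitudes) == 0L) stopf("empty amplitude series")
  window <- as.integer(window)
  if (window < 1L) stopf("window must be >= 1")
  n <- length(amplitudes)
  cs <- cumsum(amplitudes)
  out <- numeric(n)
  warm <- seq_len(min(window, n))
  out[warm] <- cs[warm] / warm
  if (n > window) {
    i <- (window + 1L):n
    out[i] <- (cs[i] - cs[i - window]) / window
  }
  out
}

#' Trigger threshold from calibration anchors
#'
#' Interpolates the trigger threshold between the rest and maximal-contraction
#' mean amplitudes: `rest + fraction * (max - rest)`. The default fraction of
#' 0.60 places the threshold at 60% of the way from full relaxation to maximal
#' contraction — a moderate effort a user can exert repeatedly.
#'
#' @param rest_mean mean rolling amplitude at rest.
#' @param max_mean mean rolling amplitude at maximal contraction.
#' @param fraction interpolation fraction in (0, 1].
#' @return the trigger threshold.
#' @export
compute_threshold <- function(rest_mean, max_mean, fraction = 0.60) {
  assert_number(rest_mean, "rest_mean", nonneg = TRUE)
  assert_number(max_mean, "max_mean", nonneg = TRUE)
  assert_number(fraction, "fraction")
  if (fraction <= 0 || fraction > 1) {
    stopf("fraction must be in (0, 1]", class = "semgrip_config_error")
  }
  if (max_mean <= rest_mean) {
    stopf(paste0("maximal contraction amplitude (%g) does not exceed rest ",
                 "amplitude (%g); increase the sensor gain and recalibrate"),
          max_mean, rest_mean, class = "semgrip_calibration_failure")
  }
  rest_mean + fraction * (max_mean - rest_mean)
}

# Calibration state timetable: S1 standby 5 s (red), S2 relax 5 s (yellow),
# S3 maximal squeeze 3 s (blue), then S4 calibrated (green, unbounded).
device_states <- function() {
  data.frame(
    code = c("S1", "S2", "S3", "S4"),
    state = c("standby", "relax grip", "maximal grip squeeze", "calibrated"),
    led_color = c("red", "yellow", "blue", "green"),
    duration_s = c(5, 5, 3, NA),
    stringsAsFactors = FALSE
  )
}

#' Run the four-state calibration sequence on a raw stream
#'
#' Replays the device's calibration procedure: 5 s standby (S1, discarded),
#' 5 s relaxed grip (S2) from which the rest mean amplitude is taken, 3 s of
#' maximal squeeze (S3) giving the maximal mean amplitude, after which the
#' device is calibrated (S4). Amplitudes are the rolling average (window 300)
#' of the sample-wise absolute differences, computed on the gain-scaled
#' stream.
#'
#' Calibration fails — signalling that the analog gain must be raised and the
#' procedure retried — when the maximal mean does not exceed the rest mean by
#' at least `separation_factor`.
#'
#' @param stream an [emg_recording()] covering at least the 13 s calibration
#'   sequence.
#' @param gain multiplicative gain applied to the raw samples before
#'   amplitude extraction (the sensor's potentiometer gain).
#' @param threshold_fraction passed to [compute_threshold()].
#' @param separation_factor minimum ratio `max_mean / rest_mean` for a valid
#'   calibration (default 1.5).
#' @param window rolling-average window in samples.
#' @return an object of class `calibration_profile` with fields
#'   `rest_mean_amplitude`, `max_mean_amplitude`, `threshold_fraction`,
#'   `trigger_threshold`, `gain`, `window`, and a `state_timeline` data frame
#'   (`time_s`, `state`, `led_color`) recording the device state at each
#'   sample.
#' @export
run_calibration <- function(stream, gain = 1,
                            threshold_fraction = 0.60,
                            separation_factor = 1.5,
                            window = 300L) {
  if (!inherits(stream, "emg_recording")) stopf("`stream` must be an emg_recording")
  assert_number(gain, "gain", positive = TRUE)
  fs <- stream$sampling_rate_hz
  states <- device_states()
  need_s <- sum(states$duration_s, na.rm = TRUE)       # 13 s
  n <- length(stream$samples)
  if (n < need_s * fs) {
    stopf("calibration stream too short: need >= %g s at %g Hz", need_s, fs)
  }
  amps <- amplitude_series(stream$samples * gain)
  roll <- rolling_amplitude(amps, window)
  t <- recording_times(stream) - stream$start_time_s    # 0-based stream time
  s1 <- t < 5
  s2 <- t >= 5 & t < 10
  s3 <- t >= 10 & t < 13
  state <- rep("S4", n)
  state[s1] <- "S1"; state[s2] <- "S2"; state[s3] <- "S3"
  rest_mean <- mean(roll[s2])
  max_mean <- mean(roll[s3])
  if (!is.finite(rest_mean) || !is.finite(max_mean) ||
      max_mean < separation_factor * rest_mean || max_mean <= 0) {
    stopf(paste0("calibration failed: maximal-squeeze amplitude (%g) is not ",
                 ">= %g x rest amplitude (%g); adjust the sensor gain and retry"),
          max_mean, separation_factor, rest_mean,
          class = "semgrip_calibration_failure")
  }
  threshold <- compute_threshold(rest_mean, max_mean, threshold_fraction)
  structure(
    list(rest_mean_amplitude = rest_mean,
         max_mean_amplitude = max_mean,
         threshold_fraction = threshold_fraction,
         trigger_threshold = threshold,
         gain = gain,
         window = as.integer(window),
         state_timeline = data.frame(
           time_s = t + stream$start_time_s,
           state = state,
           led_color = states$led_color[match(state, states$code)],
           stringsAsFactors = FALSE)),
    class = "calibration_profile"
  )
}

#' @export
print.calibration_profile <- function(x, ...) {
  cat("<calibration_profile>\n")
  cat(sprintf("  rest mean amplitude: %.4g\n", x$rest_mean_amplitude))
  cat(sprintf("  max  mean amplitude: %.4g\n", x$max_mean_amplitude))
  cat(sprintf("  trigger threshold:   %.4g (fraction %.2f, gain %g)\n",
              x$trigger_threshold, x$threshold_fraction, x$gain))
  invisible(x)
}

#' Detect grip triggers in a raw stream
#'
#' Emits a trigger event at each rising crossing of the rolling amplitude
#' above the calibrated threshold, then suppresses further events for the
#' refractory period so one sustained squeeze produces one click. The same
#' 300-sample rolling-amplitude statistic used for calibration is used here,
#' so thresholds and detections share units.
#'
#' @param stream an [emg_recording()].
#' @param profile a `calibration_profile` from [run_calibration()].
#' @param refractory_s minimum separation between triggers (default 0.3 s).
#' @param gain gain applied to the stream; defaults to the gain the profile
#'   was calibrated at.
#' @return a list with `events` (data frame, column `time_s`, one row per
#'   trigger) and `activity` (logical vector per sample: rolling amplitude at
#'   or above threshold — the device's green/red activity indicator).
#' @export
detect_triggers <- function(stream, profile, refractory_s = 0.3,
                            gain = profile$gain) {
  if (!inherits(profile, "calibration_profile")) {
    stopf("`profile` must be a calibration_profile")
  }
  fs <- stream$sampling_rate_hz
  roll <- rolling_amplitude(amplitude_series(stream$samples * gain),
                            profile$window)
  above <- roll >= profile$trigger_threshold
  rising <- which(above & !c(FALSE, above[-length(above)]))
  t <- recording_times(stream)
  times <- numeric(0)
  last <- -Inf
  for (i in rising) {
    if (t[i] - last >= refractory_s) {
      times <- c(times, t[i])
      last <- t[i]
    }
  }
  list(events = data.frame(time_s = times), activity = above)
}
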