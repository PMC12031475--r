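#' Full session configuration for the feasibility protocol
#'
#' Bundles the parameters of every stage of the protocol: the simulated
#' subject (spectral content, burst strength, event cadence, fatigue drift),
#' the acquisition module (threshold fraction, refractory period, gain), the
#' game, the offline analysis, and the protocol layout — three 5-minute games
#' with 3-minute rests, about 21 minutes in total of which 15 minutes are
#' gameplay.
#'
#' @param rest_rms,burst_gain,burst_duration_s,mean_inter_event_s,target_mdf_hz,mdf_drift_pct_per_min
#'   simulated-subject parameters, see [sim_config()]. The default cadence of
#'   one squeeze every ~6 s gives roughly 50 squeezes per game.
#' @param threshold_fraction,refractory_s,gain,separation_factor acquisition
#'   parameters, see [run_calibration()] and [detect_triggers()].
#' @param game a [game_config()].
#' @param band,min_height,min_separation_s analysis parameters, see
#'   [segment_metrics()].
#' @param n_games,game_duration_s,rest_s protocol layout (defaults 3 games of
#'   300 s with 180 s rests).
#' @param latency_allowance_s expected detector lag added to ground-truth
#'   onsets before tolerance matching: the 300-sample rolling average needs a
#'   fraction of its 0.6 s span to climb above threshold after a burst
#'   starts.
#' @param tolerance_s event-matching tolerance (default 0.2 s).
#' @param seed master seed; every stage's randomness derives from it.
#' @return an object of class `session_config`.
#' @export
session_config <- function(rest_rms = 1,
                           burst_gain = 5,
                           burst_duration_s = 1,
                           mean_inter_event_s = 6,
                           target_mdf_hz = 60,
                           mdf_drift_pct_per_min = 0,
                           threshold_fraction = 0.60,
                           refractory_s = 0.3,
                           gain = 1,
                           separation_factor = 1.5,
                           game = game_config(),
                           band = c(20, 250),
                           min_height = 0.1,
                           min_separation_s = 0.5,
                           n_games = 3L,
                           game_duration_s = 300,
                           rest_s = 180,
                           latency_allowance_s = 0.35,
                           tolerance_s = 0.2,
                           seed = 1L) {
  structure(as.list(environment()), class = "session_config")
}

#' Run the whole feasibility protocol on one simulated subject
#'
#' Deterministic end-to-end pipeline: simulate a 13 s calibration stream
#' (relaxed grip, then a maximal 3 s squeeze) and calibrate the trigger
#' threshold, doubling the gain and retrying if calibration cannot separate
#' rest from contraction; simulate the gameplay recording (`n_games`
#' contiguous game segments — rest periods are not recorded and do not
#' advance the fatigue clock) with randomly scheduled squeezes as ground
#' truth; detect triggers; replay each game's triggers through the headless
#' game; run the offline analysis per game segment; and match detected
#' triggers against ground truth (onsets shifted by the detector latency
#' allowance) with the 0.2 s tolerance.
#'
#' @param config a [session_config()].
#' @param out_dir optional directory; when given, every intermediate CSV
#'   (EMG stream with trigger flags, ground truth, triggers, per-game logs,
#'   metrics, per-minute MDF, match summary) is written there.
#' @return an object of class `protocol_result`: list with `profile`,
#'   `truth`, `triggers`, `game_logs`, `metrics` (a `signal_metrics`),
#'   `match` (a `match_summary`) and the `config`.
#' @export
run_protocol <- function(config = session_config(), out_dir = NULL) {
  if (!inherits(config, "session_config")) {
    stopf("`config` must be a session_config", class = "semgrip_config_error")
  }
  seed <- config$seed
  spectral <- list(rest_rms = config$rest_rms,
                   burst_gain = config$burst_gain,
                   band_low_hz = config$band[1],
                   band_high_hz = config$band[2],
                   target_mdf_hz = config$target_mdf_hz)

  # --- calibration: 5 s standby + 5 s rest + 3 s maximal squeeze ----------
  cal_cfg <- do.call(sim_config, c(list(
    duration_s = 14, event_onsets_s = 10, burst_duration_s = 3,
    mdf_drift_pct_per_min = 0, seed = derive_seed(seed, 101L)), spectral))
  cal <- simulate_session(cal_cfg)
  profile <- NULL
  g <- config$gain
  for (attempt in 1:6) {
    profile <- tryCatch(
      run_calibration(cal$recording, gain = g,
                      threshold_fraction = config$threshold_fraction,
                      separation_factor = config$separation_factor),
      semgrip_calibration_failure = function(e) NULL)
    if (!is.null(profile)) break
    g <- g * 2                           # sensor gain adjustment, then retry
  }
  if (is.null(profile)) {
    stopf("calibration failed at every gain; no muscle activity detectable",
          class = "semgrip_calibration_failure")
  }

  # --- gameplay recording: contiguous game segments -----------------------
  play_s <- config$n_games * config$game_duration_s
  play_cfg <- do.call(sim_config, c(list(
    duration_s = play_s,
    mean_inter_event_s = config$mean_inter_event_s,
    burst_duration_s = config$burst_duration_s,
    mdf_drift_pct_per_min = config$mdf_drift_pct_per_min,
    seed = derive_seed(seed, 202L)), spectral))
  sess <- simulate_session(play_cfg)

  det <- detect_triggers(sess$recording, profile,
                         refractory_s = config$refractory_s)

  # --- replay triggers through the game, one log per game -----------------
  game_logs <- lapply(seq_len(config$n_games), function(gi) {
    t0 <- (gi - 1) * config$game_duration_s
    trig <- det$events$time_s
    trig <- trig[trig >= t0 & trig < t0 + config$game_duration_s] - t0
    run_game_session(trig, duration_s = config$game_duration_s,
                     config = config$game, seed = derive_seed(seed, 300L + gi))
  })

  # --- offline analysis per game segment ----------------------------------
  bounds <- data.frame(
    game_id = paste("Game", seq_len(config$n_games)),
    start_s = (seq_len(config$n_games) - 1) * config$game_duration_s,
    end_s = seq_len(config$n_games) * config$game_duration_s)
  metrics <- segment_metrics(sess$recording, bounds,
                             band = config$band,
                             min_height = config$min_height,
                             min_separation_s = config$min_separation_s)

  # --- detection reliability ----------------------------------------------
  match <- match_events(sess$truth$onset_s + config$latency_allowance_s,
                        det$events$time_s,
                        tolerance_s = config$tolerance_s)

  res <- structure(list(profile = profile,
                        truth = sess$truth,
                        triggers = det$events,
                        game_logs = game_logs,
                        metrics = metrics,
                        match = match,
                        config = config),
                   class = "protocol_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_emg_csv(sess$recording, file.path(out_dir, "emg.csv"),
                  trigger = as.integer(det$activity))
    write_truth_csv(sess$truth, file.path(out_dir, "ground_truth.csv"))
    write_triggers_csv(det$events, file.path(out_dir, "triggers.csv"))
    for (gi in seq_along(game_logs)) {
      write_game_log(game_logs[[gi]], file.path(out_dir, sprintf("game%d", gi)))
    }
    write.csv(metrics$metrics, file.path(out_dir, "metrics.csv"),
              row.names = FALSE)
    write.csv(metrics$per_minute_mdf,
              file.path(out_dir, "per_minute_mdf.csv"), row.names = FALSE)
    write.csv(data.frame(tp = match$tp, fp = match$fp, fn = match$fn,
                         f1 = match$f1),
              file.path(out_dir, "match_summary.csv"), row.names = FALSE)
  }
  res
}

#' @export
print.protocol_result <- function(x, ...) {
  cat("<protocol_result>\n")
  cat(sprintf("  calibration: threshold %.4g (gain %g)\n",
              x$profile$trigger_threshold, x$profile$gain))
  cat(sprintf("  %d ground-truth squeezes, %d detected triggers\n",
              nrow(x$truth), nrow(x$triggers)))
  cat(sprintf("  detection: TP=%d FP=%d FN=%d F1=%.4f\n",
              x$match$tp, x$match$fp, x$match$fn, x$match$f1))
  cat(sprintf("  MDF per game: %s Hz\n",
              paste(sprintf("%.1f", x$metrics$metrics$mdf_hz), collapse = ", ")))
  cat(sprintf("  MDF percent change (Game %d vs Game 1): %+.2f%%\n",
              x$config$n_games, x$metrics$fatigue$pct_change_mdf))
  invisible(x)
}
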