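#' Band-limit a raw sEMG signal
#'
#' Zero-phase Butterworth bandpass isolating the usable sEMG band
#' (20-250 Hz by default). The filter is a 4th-order design applied
#' forward-backward ([signal::filtfilt()]) so peak timing is preserved. At a
#' 500 Hz sampling rate the nominal 250 Hz upper edge coincides with Nyquist
#' and is unrealisable; the edge is clamped to 99% of Nyquist.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param low,high band edges in Hz (defaults 20 and 250).
#' @param order filter order of the underlying design (default 4).
#' @return filtered signal, same length as `x`.
#' @export
bandpass <- function(x, fs, low = 20, high = 250, order = 4) {
  assert_number(fs, "fs", positive = TRUE)
  high <- min(high, 0.99 * fs / 2)
  if (low >= high) {
    stopf("sampling rate too low for band [%g, %g] Hz", low, high)
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  # odd-reflection padding suppresses the start/end transients of filtfilt
  n <- length(x)
  np <- min(n - 1L, as.integer(round(fs)))
  head_pad <- 2 * x[1] - x[(np + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - np)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  as.numeric(y[(np + 1L):(np + n)])
}

#' Normalize to [-1, 1] and rectify
#'
#' Scales a signal by its maximum absolute value so it spans `[-1, 1]`, then
#' rectifies (absolute value). Scaling the input by any positive constant
#' leaves both outputs unchanged.
#'
#' @param filtered numeric signal (typically the bandpassed sEMG).
#' @return list with `normalized` (in `[-1, 1]`) and `rectified`
#'   (in `[0, 1]`).
#' @export
normalize_rectify <- function(filtered) {
  m <- max(abs(filtered))
  if (!is.finite(m) || m == 0) {
    stopf("cannot normalize an all-zero signal")
  }
  normalized <- filtered / m
  list(normalized = normalized, rectified = abs(normalized))
}

#' Locate grip-exertion peaks in a rectified envelope
#'
#' Smooths the rectified signal with a short moving average (the envelope),
#' takes one candidate peak per contiguous envelope excursion above
#' `min_height` (a noise-like rectified interference signal has hundreds of
#' raw local maxima per contraction; one excursion corresponds to one grip
#' exertion), then enforces the minimum separation, keeping the taller of any
#' two candidates closer than `min_separation_s`. Each reported index is the
#' largest rectified sample around its envelope maximum, so peaks lie on the
#' rectified signal itself.
#'
#' @param rectified rectified normalized signal (from [normalize_rectify()]).
#' @param fs sampling rate (Hz).
#' @param min_height minimum envelope height, in normalized units
#'   (default 0.1).
#' @param min_separation_s minimum separation between peaks (default 0.5 s).
#' @param smooth_s moving-average length for the envelope (default 0.3 s).
#' @return integer vector of peak sample indices (possibly empty), sorted.
#' @export
find_activity_peaks <- function(rectified, fs, min_height = 0.1,
                                min_separation_s = 0.5, smooth_s = 0.3) {
  assert_number(min_height, "min_height", positive = TRUE)
  assert_number(min_separation_s, "min_separation_s", positive = TRUE)
  n <- length(rectified)
  w <- max(1L, as.integer(round(smooth_s * fs)))
  env <- as.numeric(stats::filter(rectified, rep(1 / w, w), sides = 2))
  env[is.na(env)] <- 0
  above <- env >= min_height
  if (!any(above)) return(integer(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- mapply(function(s, e) s + which.max(env[s:e]) - 1L,
                 starts[r$values], ends[r$values])
  # taller-wins suppression of candidates closer than the minimum separation
  min_gap <- min_separation_s * fs
  keep <- integer(0)
  for (i in cand[order(env[cand], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(keep - i) >= min_gap)) keep <- c(keep, i)
  }
  half <- w %/% 2
  refined <- vapply(sort(keep), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    as.integer(lo + which.max(rectified[lo:hi]) - 1L)
  }, integer(1))
  sort(unique(refined))
}

# Welch power spectral density: Hamming-windowed segments, 50% overlap.
# Returns freq (Hz) and average periodogram power per bin.
welch_psd <- function(x, fs, win_s = 1) {
  n <- length(x)
  seg <- min(n, max(8L, as.integer(round(win_s * fs))))
  step <- max(1L, seg %/% 2L)
  starts <- seq(1L, n - seg + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(seg - 1)) / (seg - 1))
  acc <- numeric(seg %/% 2 + 1)
  for (s in starts) {
    xs <- x[s:(s + seg - 1L)] * w
    sp <- abs(fft(xs))^2
    acc <- acc + sp[seq_len(seg %/% 2 + 1)]
  }
  list(freq = (0:(seg %/% 2)) * fs / seg, power = acc / length(starts))
}

#' Median frequency of an sEMG segment
#'
#' Frequency at which the cumulative power of the Welch spectrum (1 s
#' Hamming windows, 50% overlap) reaches half of the total in-band power.
#' Between spectral bins the crossing is located by linear interpolation;
#' when the cumulative power plateaus at the half-power level (as for two
#' equal-power tones), the midpoint of the plateau is returned. Computed on
#' the bandpassed, pre-normalization signal; the result is invariant to
#' amplitude scaling.
#'
#' @param x numeric signal segment (at least 1 s of samples).
#' @param fs sampling rate (Hz).
#' @param band integration band in Hz (default `c(20, 250)`, clipped to
#'   Nyquist). Power outside the band is ignored.
#' @param win_s Welch window length in seconds (default 1).
#' @return median frequency in Hz.
#' @export
median_frequency <- function(x, fs, band = c(20, 250), win_s = 1) {
  if (length(x) < fs) stopf("segment shorter than 1 s")
  psd <- welch_psd(x, fs, win_s)
  keep <- psd$freq >= band[1] & psd$freq <= min(band[2], fs / 2)
  f <- psd$freq[keep]
  p <- psd$power[keep]
  tot <- sum(p)
  if (tot <= 0 || !is.finite(tot)) {
    stopf("zero-power segment: median frequency undefined")
  }
  cum <- cumsum(p)
  half <- tot / 2
  tol <- 1e-4 * tot
  i_lo <- max(c(0L, which(cum < half - tol)))
  i_up <- min(c(length(f) + 1L, which(cum > half + tol)))
  if (i_lo == 0L) return(f[1])
  if (i_up > length(f)) return(f[length(f)])
  if (i_up == i_lo + 1L) {
    # single-bin crossing: linear interpolation on cumulative power
    f[i_lo] + (half - cum[i_lo]) / (cum[i_up] - cum[i_lo]) *
      (f[i_up] - f[i_lo])
  } else {
    # cumulative power plateaus at half: midpoint convention
    (f[i_lo] + f[i_up]) / 2
  }
}

#' Per-minute median-frequency series
#'
#' MDF over consecutive fixed-length blocks, the input for a fatigue
#' scatterplot of MDF against gameplay time.
#'
#' @param x bandpassed signal.
#' @param fs sampling rate (Hz).
#' @param block_s block length in seconds (default 60).
#' @inheritParams median_frequency
#' @return data frame with `t_mid_s` (block midpoint) and `mdf_hz`.
#' @export
mdf_over_time <- function(x, fs, block_s = 60, band = c(20, 250)) {
  n_block <- as.integer(round(block_s * fs))
  n <- length(x) %/% n_block
  if (n < 1) stopf("signal shorter than one block")
  res <- vapply(seq_len(n), function(b) {
    seg <- x[((b - 1) * n_block + 1):(b * n_block)]
    median_frequency(seg, fs, band)
  }, numeric(1))
  data.frame(t_mid_s = (seq_len(n) - 0.5) * block_s, mdf_hz = res)
}

#' Segment a recording by game and compute fatigue metrics
#'
#' Runs the offline pipeline on a full-session recording: bandpass the raw
#' signal, normalize once over the whole recording (so amplitude differences
#' between games are preserved), rectify, then per game segment compute the
#' mean peak amplitude (MPA, mean height of detected rectified peaks) and the
#' median frequency (MDF, from the bandpassed pre-normalization signal).
#' The fatigue statistic is the percent change in MDF between the last and
#' first games, `100 * (mdf_3 - mdf_1) / mdf_1`.
#'
#' @param recording an [emg_recording()] covering all three games.
#' @param game_boundaries data frame with columns `game_id`, `start_s`,
#'   `end_s`: three non-overlapping segments inside the recording.
#' @param band bandpass edges in Hz.
#' @param min_height,min_separation_s peak-picking parameters, see
#'   [find_activity_peaks()].
#' @return a list of class `signal_metrics`: `metrics` (data frame
#'   `segment_id`, `mpa`, `mdf_hz`), `fatigue` (list with `pct_change_mdf`),
#'   and `per_minute_mdf` (data frame `t_mid_s`, `mdf_hz` over the gameplay
#'   segments).
#' @export
segment_metrics <- function(recording, game_boundaries,
                            band = c(20, 250),
                            min_height = 0.1, min_separation_s = 0.5) {
  gb <- game_boundaries
  need <- c("game_id", "start_s", "end_s")
  if (!all(need %in% names(gb))) {
    stopf("game_boundaries needs columns game_id, start_s, end_s",
          class = "semgrip_format_error")
  }
  gb <- gb[order(gb$start_s), , drop = FALSE]
  if (nrow(gb) != 3L) stopf("expected exactly three game segments")
  if (any(gb$end_s <= gb$start_s)) stopf("segments must have end_s > start_s")
  if (any(head(gb$end_s, -1) > tail(gb$start_s, -1))) {
    stopf("game segments overlap")
  }
  fs <- recording$sampling_rate_hz
  t <- recording_times(recording)
  filtered <- bandpass(recording$samples, fs, band[1], band[2])
  nr <- normalize_rectify(filtered)
  rows <- lapply(seq_len(nrow(gb)), function(i) {
    sel <- t >= gb$start_s[i] & t < gb$end_s[i]
    seg_rect <- nr$rectified[sel]
    seg_filt <- filtered[sel]
    pk <- find_activity_peaks(seg_rect, fs, min_height, min_separation_s)
    data.frame(segment_id = as.character(gb$game_id[i]),
               mpa = if (length(pk)) mean(seg_rect[pk]) else NA_real_,
               mdf_hz = median_frequency(seg_filt, fs, band),
               stringsAsFactors = FALSE)
  })
  metrics <- do.call(rbind, rows)
  pct <- 100 * (metrics$mdf_hz[3] - metrics$mdf_hz[1]) / metrics$mdf_hz[1]
  per_min <- do.call(rbind, lapply(seq_len(nrow(gb)), function(i) {
    sel <- t >= gb$start_s[i] & t < gb$end_s[i]
    m <- mdf_over_time(filtered[sel], fs, block_s = 60, band = band)
    m$t_mid_s <- m$t_mid_s + gb$start_s[i]
    m
  }))
  structure(list(metrics = metrics,
                 fatigue = list(pct_change_mdf = pct),
                 per_minute_mdf = per_min),
            class = "signal_metrics")
}

#' @export
print.signal_metrics <- function(x, ...) {
  cat("<signal_metrics>\n")
  print(x$metrics, row.names = FALSE)
  cat(sprintf("  MDF percent change (last vs first game): %+.2f%%\n",
              x$fatigue$pct_change_mdf))
  invisible(x)
}
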