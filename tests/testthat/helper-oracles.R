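# Independent oracles used across test files.

# Brute-force maximum one-to-one matching (max TP) between truth and detected
# times under a +/- tolerance, by exhaustive recursion. Independent of the
# package's greedy matcher; intended for instances with <= 8 events per side.
brute_force_tp <- function(truth, detected, tol) {
  m <- length(detected)
  rec <- function(i, used) {
    if (i > length(truth)) return(0L)
    best <- rec(i + 1L, used)
    for (j in seq_len(m)) {
      if (!used[j] && abs(detected[j] - truth[i]) <= tol) {
        used[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  rec(1L, logical(m))
}

# Median frequency by brute-force cumulative sum over a plain (single-window,
# unwindowed) periodogram, with first-crossing linear interpolation.
mdf_periodogram <- function(x, fs, band = c(20, 250)) {
  n <- length(x)
  p <- (abs(fft(x))^2)[seq_len(n %/% 2 + 1)]
  f <- (0:(n %/% 2)) * fs / n
  keep <- f >= band[1] & f <= min(band[2], fs / 2)
  f <- f[keep]; p <- p[keep]
  cum <- cumsum(p)
  half <- cum[length(cum)] / 2
  i <- which(cum >= half)[1]
  if (i == 1) return(f[1])
  f[i - 1] + (half - cum[i - 1]) / (cum[i] - cum[i - 1]) * (f[i] - f[i - 1])
}

# Random small matching instance: event times uniform on [0, span].
random_match_instance <- function(max_n = 8, span = 5) {
  list(truth = sort(runif(sample.int(max_n, 1), 0, span)),
       detected = sort(runif(sample.int(max_n, 1), 0, span)))
}
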