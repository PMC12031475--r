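#' Match ground-truth events to detections within a time tolerance
#'
#' One-to-one matching of two sorted event lists: each truth event may pair
#' with at most one detection whose time differs by at most `tolerance_s`
#' (closed interval). Truth events are processed in increasing time and each
#' takes the earliest unused detection inside its window; for equal-width
#' windows this greedy rule attains the maximum possible number of pairs
#' (convex bipartite matching), so TP counts never depend on accidental
#' orderings. Unmatched truth events are false negatives, unmatched
#' detections false positives.
#'
#' @param truth_times sorted ground-truth event times (s).
#' @param detected_times sorted detected event times (s).
#' @param tolerance_s matching tolerance (default 0.2 s).
#' @return an object of class `match_summary`: list with counts `tp`, `fp`,
#'   `fn`, the `f1` score, and `pairing` (data frame `truth_s`,
#'   `detected_s`).
#' @export
match_events <- function(truth_times, detected_times, tolerance_s = 0.2) {
  if (is.unsorted(truth_times) || is.unsorted(detected_times)) {
    stopf("event lists must be sorted", class = "semgrip_format_error")
  }
  assert_number(tolerance_s, "tolerance_s", nonneg = TRUE)
  used <- logical(length(detected_times))
  pair_t <- numeric(0); pair_d <- numeric(0)
  for (tt in truth_times) {
    cand <- which(!used &
                    detected_times >= tt - tolerance_s &
                    detected_times <= tt + tolerance_s)
    if (length(cand)) {
      j <- cand[1]                      # earliest unused in-window detection
      used[j] <- TRUE
      pair_t <- c(pair_t, tt)
      pair_d <- c(pair_d, detected_times[j])
    }
  }
  tp <- length(pair_t)
  fn <- length(truth_times) - tp
  fp <- length(detected_times) - tp
  structure(list(tp = tp, fp = fp, fn = fn,
                 f1 = f1_score(tp, fp, fn),
                 pairing = data.frame(truth_s = pair_t,
                                      detected_s = pair_d)),
            class = "match_summary")
}

#' @export
print.match_summary <- function(x, ...) {
  cat(sprintf("<match_summary> TP=%d FP=%d FN=%d  F1=%.4f\n",
              x$tp, x$fp, x$fn, x$f1))
  invisible(x)
}

#' F1 score from confusion counts
#'
#' `2*TP / (2*TP + FP + FN)`: the harmonic mean of precision and recall over
#' matched events. When all three counts are zero (an empty session) the
#' score is defined as 0 with a warning.
#'
#' @param tp,fp,fn non-negative integer counts of true positives, false
#'   positives and false negatives.
#' @return F1 in `[0, 1]`.
#' @examples
#' f1_score(3450, 1323, 47)  # 0.8343
#' @export
f1_score <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stopf("counts must be non-negative")
  denom <- 2 * tp + fp + fn
  if (denom == 0) {
    warning("no events at all: F1 defined as 0")
    return(0)
  }
  2 * tp / denom
}

#' Two-sample comparison of group values
#'
#' Two-sided t-test between two groups, unpaired (Welch by default) or
#' paired. The default alpha of 0.25 is deliberately liberal: in a small
#' exploratory feasibility cohort the aim is to flag candidate trends for
#' follow-up rather than to confirm effects.
#'
#' @param values_a,values_b numeric vectors (>= 2 values each; equal lengths
#'   when `paired`).
#' @param alpha significance level (default 0.25).
#' @param paired paired test instead of two-sample.
#' @param var_equal pooled-variance test instead of Welch (unpaired only).
#' @return an object of class `group_comparison`: list with `t_statistic`,
#'   `p_value`, `alpha`, `significant`, `paired`, and the group values.
#' @export
compare_groups <- function(values_a, values_b, alpha = 0.25,
                           paired = FALSE, var_equal = FALSE) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stopf("need at least 2 values per group")
  }
  if (paired && length(values_a) != length(values_b)) {
    stopf("paired comparison needs equal-length groups")
  }
  tt <- t.test(values_a, values_b, paired = paired, var.equal = var_equal)
  structure(list(group_a_values = values_a,
                 group_b_values = values_b,
                 t_statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 alpha = alpha,
                 significant = tt$p.value < alpha,
                 paired = paired),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> t=%.4g, p=%.4g (alpha=%.2f): %s%s\n",
              x$t_statistic, x$p_value, x$alpha,
              if (x$significant) "significant" else "not significant",
              if (x$paired) " [paired]" else ""))
  invisible(x)
}

#' Aggregate a user-satisfaction questionnaire table
#'
#' Per-question mean and sample standard deviation over respondents for the
#' six 1-5 Likert items (Q1 enjoyment, Q2 engagement, Q3 responsiveness,
#' Q4 comfort, Q5 perceived performance, Q6 ease of use), plus the grand
#' mean, defined as the mean of the six question means. The free-text item
#' is not numeric and is ignored.
#'
#' @param table data frame with columns `Q1`..`Q6`, one row per respondent,
#'   integer scores 1-5.
#' @return list with `per_question` (data frame `question`, `mean`, `sd`)
#'   and `grand_mean`.
#' @export
summarize_useq <- function(table) {
  qs <- paste0("Q", 1:6)
  if (!all(qs %in% names(table))) {
    stopf("questionnaire table needs columns Q1..Q6",
          class = "semgrip_format_error")
  }
  if (nrow(table) < 1) stopf("need at least one respondent")
  vals <- as.matrix(table[qs])
  if (any(!is.finite(vals)) || any(vals < 1 | vals > 5)) {
    stopf("questionnaire scores must be integers in 1..5",
          class = "semgrip_format_error")
  }
  per <- data.frame(
    question = qs,
    mean = colMeans(vals),
    sd = apply(vals, 2, function(v) if (length(v) > 1) sd(v) else 0),
    row.names = NULL
  )
  list(per_question = per, grand_mean = mean(per$mean))
}

#' Mean and sample standard deviation
#'
#' Group descriptives with the n-1 (sample) SD denominator.
#'
#' @param values numeric vector; SD requires n >= 2.
#' @return list with `mean`, `sd` and `n`.
#' @export
descriptive_stats <- function(values) {
  if (length(values) < 2) stopf("sample SD undefined for n < 2")
  list(mean = mean(values), sd = sd(values), n = length(values))
}
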