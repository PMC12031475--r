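# CSV schemas shared by every stage. All files are UTF-8, comma-separated,
# dot-decimal, with a header row; times are seconds from session start.

read_checked_csv <- function(path, required, monotone = NULL) {
  if (!file.exists(path)) {
    stopf("file not found: %s", path, class = "semgrip_format_error")
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stopf("%s: missing required column(s): %s", path,
          paste(missing, collapse = ", "), class = "semgrip_format_error")
  }
  for (col in required) {
    v <- df[[col]]
    if (is.character(v)) {
      # guard against locale-style decimal commas being silently misparsed
      if (any(grepl(",", v, fixed = TRUE))) {
        stopf("%s: column `%s` contains comma decimals; use dot decimals",
              path, col, class = "semgrip_format_error")
      }
      suppressWarnings(vn <- as.numeric(v))
      if (any(is.na(vn) & !is.na(v))) {
        stopf("%s: column `%s` is not numeric", path, col,
              class = "semgrip_format_error")
      }
      df[[col]] <- vn
    }
  }
  for (col in monotone %||% character(0)) {
    if (is.unsorted(df[[col]])) {
      stopf("%s: column `%s` must be non-decreasing", path, col,
            class = "semgrip_format_error")
    }
  }
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write EMG stream CSV
#'
#' Schema: columns `time_s`, `raw`, and on write optionally `trigger` (0/1,
#' the transmitted trigger flag). Sampling must be uniform.
#'
#' @param path CSV file path.
#' @return [read_emg_csv()] returns an [emg_recording()].
#' @export
read_emg_csv <- function(path) {
  df <- read_checked_csv(path, c("time_s", "raw"), monotone = "time_s")
  if (nrow(df) < 2) stopf("EMG stream needs >= 2 samples",
                          class = "semgrip_format_error")
  dt <- diff(df$time_s)
  if (max(dt) - min(dt) > 1e-6) {
    stopf("%s: non-uniform sampling", path, class = "semgrip_format_error")
  }
  emg_recording(1 / mean(dt), df$raw, df$time_s[1])
}

#' @param rec an [emg_recording()].
#' @param trigger optional 0/1 vector (one per sample) written as a
#'   `trigger` column.
#' @rdname read_emg_csv
#' @export
write_emg_csv <- function(rec, path, trigger = NULL) {
  df <- data.frame(time_s = recording_times(rec), raw = rec$samples)
  if (!is.null(trigger)) df$trigger <- as.integer(trigger)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write ground-truth grip-event CSV
#'
#' Schema: columns `onset_s`, `duration_s`, sorted by onset.
#'
#' @param path CSV file path.
#' @export
read_truth_csv <- function(path) {
  read_checked_csv(path, c("onset_s", "duration_s"), monotone = "onset_s")
}

#' @param truth data frame with `onset_s`, `duration_s`.
#' @rdname read_truth_csv
#' @export
write_truth_csv <- function(truth, path) {
  write.csv(truth[c("onset_s", "duration_s")], path, row.names = FALSE)
  invisible(path)
}

#' Read / write trigger-event CSV
#'
#' Schema: single column `time_s`, sorted.
#'
#' @param path CSV file path.
#' @export
read_triggers_csv <- function(path) {
  read_checked_csv(path, "time_s", monotone = "time_s")
}

#' @param events data frame with column `time_s`.
#' @rdname read_triggers_csv
#' @export
write_triggers_csv <- function(events, path) {
  write.csv(events["time_s"], path, row.names = FALSE)
  invisible(path)
}

#' Read / write game-segment boundaries CSV
#'
#' Schema: columns `game_id`, `start_s`, `end_s`.
#'
#' @param path CSV file path.
#' @export
read_segments_csv <- function(path) {
  df <- read_checked_csv(path, c("start_s", "end_s"))
  if (!"game_id" %in% names(df)) {
    stopf("%s: missing required column(s): game_id", path,
          class = "semgrip_format_error")
  }
  df
}

#' Write the three game-log CSVs
#'
#' Writes `clicks.csv` (`time_s`), `difficulty_changes.csv` (`time_s`,
#' `old_level`, `new_level`) and `outcomes.csv` (`time_s`, `kind`) into a
#' directory — the three metrics spreadsheets the game records.
#'
#' @param log a `game_session_log` from [run_game_session()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_game_log <- function(log, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(log$clicks, file.path(dir, "clicks.csv"), row.names = FALSE)
  write.csv(log$difficulty_changes,
            file.path(dir, "difficulty_changes.csv"), row.names = FALSE)
  write.csv(log$outcomes, file.path(dir, "outcomes.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a user-satisfaction questionnaire CSV
#'
#' Schema: one row per respondent, columns `Q1`..`Q6` with 1-5 scores
#' (free-text columns are carried through untouched).
#'
#' @param path CSV file path.
#' @export
read_useq_csv <- function(path) {
  read_checked_csv(path, paste0("Q", 1:6))
}
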