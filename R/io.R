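# Interchange CSV dialects.  Sample tables carry one row per 4 ms sample
# with empty cells for invalid (blink) data; trial tables one row per trial;
# event tables one row per ocular event.  Every writer's output is
# re-readable by the corresponding reader.

sample_cols <- c("participant", "trial", "time_ms", "lx_px", "ly_px",
                 "rx_px", "ry_px", "l_pupil_mm", "r_pupil_mm")

#' Read a gaze sample table
#'
#' Reads the sample-table CSV dialect: header `participant, trial, time_ms,
#' lx_px, ly_px, rx_px, ry_px, l_pupil_mm, r_pupil_mm`; empty cells denote
#' invalid samples and become NA (never 0).  Validates that `time_ms` is
#' strictly increasing within each trial with the constant step implied by
#' the sampling rate (4 ms at 250 Hz).
#'
#' @param path CSV file path.
#' @param sampling_rate expected sampling rate (Hz).
#' @return a sample table data frame.
#' @export
read_samples <- function(path, sampling_rate = 250) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(sample_cols, names(df))
  stop_if(length(missing_cols) > 0,
          paste("parse error: missing columns:",
                paste(missing_cols, collapse = ", ")))
  df <- df[, sample_cols]
  for (col in sample_cols[-(1:2)]) df[[col]] <- as.numeric(df[[col]])
  df$participant <- as.integer(df$participant)
  df$trial <- as.integer(df$trial)
  step <- 1000 / sampling_rate
  for (idx in trial_groups(df)) {
    dt <- diff(df$time_ms[idx])
    if (any(dt <= 0)) {
      bad <- idx[which(dt <= 0)[1] + 1]
      stop("parse error: non-monotone time_ms at line ", bad + 1, call. = FALSE)
    }
    if (any(dt != step)) {
      bad <- idx[which(dt != step)[1] + 1]
      stop("parse error: time_ms step is not ", step, " ms at line ",
           bad + 1, call. = FALSE)
    }
  }
  df
}

#' Write a gaze sample table
#'
#' @param samples a sample table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  write.csv(samples[, sample_cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write trial metadata tables
#'
#' @param path CSV file path.
#' @return `read_trials`: the trial table; `write_trials`: `path`.
#' @export
read_trials <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$catch_flag <- as.logical(df$catch_flag)
  df$passive_response_valid <- as.logical(df$passive_response_valid)
  df
}

#' @rdname read_trials
#' @param trials a trial metadata table.
#' @export
write_trials <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write ocular event tables
#'
#' Events CSV: participant, trial, type, onset_ms, offset_ms,
#' amplitude_deg, peak_vel_deg_s (and any extra columns such as
#' `binocular`).  The same schema is used for detector output and for the
#' simulator's ground truth, so recovery analyses can diff two files.
#'
#' @param path CSV file path.
#' @return `read_events`: the event table; `write_events`: `path`.
#' @export
read_events <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_events
#' @param events an event table.
#' @export
write_events <- function(events, path) {
  write.csv(events, path, row.names = FALSE, na = "")
  invisible(path)
}
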