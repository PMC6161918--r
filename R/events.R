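# Velocity-threshold saccade and microsaccade detection in the style of the
# Engbert-Kliegl algorithm: 5-point moving-average differentiation,
# median-based elliptic velocity threshold (lambda multiplier), minimum
# duration, binocular overlap merging and the 1.5 deg microsaccade boundary.

#' Gaze velocity by 5-point moving-average differentiation
#'
#' Computes per-sample velocity v_n = (x_{n+2} + x_{n+1} - x_{n-1} - x_{n-2})
#' / (6 dt), exact on linear signals.  Velocity is undefined (NA) on the two
#' samples at each end of a segment and on any sample whose 5-point window
#' touches an invalid sample, so samples adjacent to masked gaps carry no
#' velocity.
#'
#' @param x,y gaze position (deg).
#' @param dt sample interval (s).
#' @param valid logical validity per sample (default: finite positions).
#' @return a data frame with columns vx, vy (deg/s; NA where undefined).
#' @export
compute_velocity <- function(x, y, dt, valid = NULL) {
  n <- length(x)
  if (is.null(valid)) valid <- is.finite(x) & is.finite(y)
  else valid <- valid & is.finite(x) & is.finite(y)
  vx <- vy <- rep(NA_real_, n)
  if (n >= 5) {
    i <- 3:(n - 2)
    ok <- valid[i - 2] & valid[i - 1] & valid[i] & valid[i + 1] & valid[i + 2]
    vx[i] <- (x[i + 2] + x[i + 1] - x[i - 1] - x[i - 2]) / (6 * dt)
    vy[i] <- (y[i + 2] + y[i + 1] - y[i - 1] - y[i - 2]) / (6 * dt)
    vx[i][!ok] <- NA_real_
    vy[i][!ok] <- NA_real_
  }
  data.frame(vx = vx, vy = vy)
}

#' Median-based elliptic velocity threshold
#'
#' Estimates the velocity noise level per component with the median-based
#' estimator sigma^2 = median(v^2) - median(v)^2 (robust to the saccades
#' themselves) and returns the detection radii eta = lambda * sigma.  An
#' event is any sample with (vx/eta_x)^2 + (vy/eta_y)^2 > 1 (strictly).
#'
#' @param vel output of [compute_velocity()].
#' @param lambda threshold multiplier.
#' @return named numeric vector c(eta_x, eta_y) in deg/s.
#' @export
velocity_threshold <- function(vel, lambda = 6) {
  vx <- vel$vx[!is.na(vel$vx)]; vy <- vel$vy[!is.na(vel$vy)]
  if (!length(vx)) stop("no valid velocity samples", call. = FALSE)
  sx2 <- median(vx^2) - median(vx)^2
  sy2 <- median(vy^2) - median(vy)^2
  if (!is.finite(sx2) || !is.finite(sy2) || sx2 <= 0 || sy2 <= 0)
    stop("degenerate velocity threshold: zero median-based variance",
         call. = FALSE)
  c(eta_x = lambda * sqrt(sx2), eta_y = lambda * sqrt(sy2))
}

#' Monocular event detection
#'
#' Finds maximal runs of supra-threshold velocity samples of length at least
#' `min_duration_samples`.  Event amplitude is the start-to-end Euclidean
#' displacement of gaze; peak velocity is the maximum combined speed within
#' the run.  Samples with undefined velocity terminate runs, so events never
#' span masked samples.
#'
#' @param vel output of [compute_velocity()].
#' @param thresholds output of [velocity_threshold()].
#' @param x,y gaze position (deg) used for amplitudes.
#' @param time_ms per-sample timestamps.
#' @param config a [detection_config()].
#' @return data frame: onset_idx, offset_idx, onset_ms, offset_ms,
#'   amplitude_deg, peak_vel_deg_s.
#' @export
detect_monocular <- function(vel, thresholds, x, y, time_ms,
                             config = detection_config()) {
  crit <- (vel$vx / thresholds["eta_x"])^2 + (vel$vy / thresholds["eta_y"])^2
  supra <- !is.na(crit) & crit > 1
  empty <- data.frame(onset_idx = integer(0), offset_idx = integer(0),
                      onset_ms = numeric(0), offset_ms = numeric(0),
                      amplitude_deg = numeric(0), peak_vel_deg_s = numeric(0))
  if (!any(supra)) return(empty)
  runs <- logical_runs(supra)
  runs <- runs[runs[, "end"] - runs[, "start"] + 1L >= config$min_duration_samples,
               , drop = FALSE]
  if (!nrow(runs)) return(empty)
  speed <- sqrt(vel$vx^2 + vel$vy^2)
  data.frame(
    onset_idx = runs[, "start"], offset_idx = runs[, "end"],
    onset_ms = time_ms[runs[, "start"]], offset_ms = time_ms[runs[, "end"]],
    amplitude_deg = sqrt((x[runs[, "end"]] - x[runs[, "start"]])^2 +
                         (y[runs[, "end"]] - y[runs[, "start"]])^2),
    peak_vel_deg_s = vapply(seq_len(nrow(runs)), function(i)
      max(speed[runs[i, "start"]:runs[i, "end"]], na.rm = TRUE), numeric(1)))
}

#' Merge monocular events into binocular events
#'
#' Retains left-eye events that temporally overlap a right-eye event by at
#' least `binocular_min_overlap` samples.  The merged event spans the union
#' of the overlapping intervals; amplitude and peak velocity are the means
#' of the two eyes' values.
#'
#' @param left_events,right_events outputs of [detect_monocular()],
#'   time-ordered.
#' @param config a [detection_config()].
#' @return data frame with the same columns as [detect_monocular()].
#' @export
merge_binocular <- function(left_events, right_events,
                            config = detection_config()) {
  empty <- data.frame(onset_idx = integer(0), offset_idx = integer(0),
                      onset_ms = numeric(0), offset_ms = numeric(0),
                      amplitude_deg = numeric(0), peak_vel_deg_s = numeric(0))
  if (!nrow(left_events) || !nrow(right_events)) return(empty)
  out <- list()
  for (i in seq_len(nrow(left_events))) {
    ov <- pmin(left_events$offset_idx[i], right_events$offset_idx) -
          pmax(left_events$onset_idx[i], right_events$onset_idx) + 1L
    j <- which(ov >= config$binocular_min_overlap)
    if (!length(j)) next
    on_idx <- min(left_events$onset_idx[i], right_events$onset_idx[j])
    off_idx <- max(left_events$offset_idx[i], right_events$offset_idx[j])
    out[[length(out) + 1L]] <- data.frame(
      onset_idx = on_idx, offset_idx = off_idx,
      onset_ms = min(left_events$onset_ms[i], right_events$onset_ms[j]),
      offset_ms = max(left_events$offset_ms[i], right_events$offset_ms[j]),
      amplitude_deg = mean(c(left_events$amplitude_deg[i],
                             mean(right_events$amplitude_deg[j]))),
      peak_vel_deg_s = mean(c(left_events$peak_vel_deg_s[i],
                              mean(right_events$peak_vel_deg_s[j]))))
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  # collapse events that merged into the same union interval
  res <- res[!duplicated(res[, c("onset_idx", "offset_idx")]), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify events as microsaccades or saccades
#'
#' Events with amplitude at or below `micro_amplitude_max` (1.5 deg) are
#' microsaccades, larger ones saccades; the partition is exhaustive and
#' exclusive.
#'
#' @param events event data frame with an amplitude_deg column.
#' @param config a [detection_config()].
#' @return `events` with a `type` column.
#' @export
classify_events <- function(events, config = detection_config()) {
  events$type <- ifelse(events$amplitude_deg <= config$micro_amplitude_max,
                        "microsaccade", "saccade")
  events
}

#' Detect binocular saccades and microsaccades for a session
#'
#' Runs the full detection chain per trial: converts gaze to degrees,
#' computes velocity per eye over continuous valid segments (validity from
#' the preprocessing mask), estimates the elliptic threshold per trial and
#' eye, detects monocular events, merges them binocularly and classifies
#' them by amplitude.  Trials whose threshold is degenerate (e.g. all
#' samples masked) yield no events.
#'
#' @param samples a sample table.
#' @param mask preprocessing mask aligned with `samples` (or NULL for all
#'   valid).
#' @param config a [detection_config()].
#' @param sim_config a [simulation_config()] supplying geometry.
#' @return data frame of events: participant, trial, type, onset_ms,
#'   offset_ms, amplitude_deg, peak_vel_deg_s, binocular.
#' @export
detect_saccades <- function(samples, mask = NULL,
                            config = detection_config(),
                            sim_config = simulation_config()) {
  if (is.null(mask)) mask <- new_mask(nrow(samples))
  valid <- mask_valid(mask)
  dt <- 1 / sim_config$sampling_rate
  out <- list()
  for (idx in trial_groups(samples)) {
    lx <- px_to_deg(samples$lx_px[idx], sim_config)
    ly <- px_to_deg(samples$ly_px[idx], sim_config)
    rx <- px_to_deg(samples$rx_px[idx], sim_config)
    ry <- px_to_deg(samples$ry_px[idx], sim_config)
    v <- valid[idx]
    tm <- samples$time_ms[idx]
    vel_l <- compute_velocity(lx, ly, dt, v)
    vel_r <- compute_velocity(rx, ry, dt, v)
    ev_l <- tryCatch({
      th_l <- velocity_threshold(vel_l, config$lambda)
      detect_monocular(vel_l, th_l, lx, ly, tm, config)
    }, error = function(e) NULL)
    ev_r <- tryCatch({
      th_r <- velocity_threshold(vel_r, config$lambda)
      detect_monocular(vel_r, th_r, rx, ry, tm, config)
    }, error = function(e) NULL)
    if (is.null(ev_l) || is.null(ev_r)) next
    bino <- merge_binocular(ev_l, ev_r, config)
    if (!nrow(bino)) next
    bino <- classify_events(bino, config)
    out[[length(out) + 1L]] <- data.frame(
      participant = samples$participant[idx[1]],
      trial = samples$trial[idx[1]],
      type = bino$type, onset_ms = bino$onset_ms, offset_ms = bino$offset_ms,
      amplitude_deg = bino$amplitude_deg,
      peak_vel_deg_s = bino$peak_vel_deg_s,
      binocular = TRUE, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(participant = integer(0), trial = integer(0),
                      type = character(0), onset_ms = numeric(0),
                      offset_ms = numeric(0), amplitude_deg = numeric(0),
                      peak_vel_deg_s = numeric(0), binocular = logical(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
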