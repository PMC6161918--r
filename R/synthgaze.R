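# Synthetic binocular recording generator.  Emulates the trial structure of
# the multiplication-with-distractors paradigm (2 s multiplication sign,
# 300 + 300 ms operands, calculation period with optional distractor onsets)
# and produces 250 Hz sample tables together with a ground-truth event log,
# so that detection and parameter extraction can be validated without any
# real recording.

#' Trial timeline
#'
#' Event anchors of a single trial, in ms relative to trial start.  The
#' multiplication sign is shown for 2 s, the two operands for 300 ms each,
#' and the calculation period runs from second-operand offset to the
#' response.  When present, the distractor appears 1.0, 1.5, 1.75, 2.0 or
#' 2.25 s after calculation onset at one of 8 positions on a 150 px circle.
#'
#' @param condition one of `"mult_no_distractor"`, `"mult_distractor"`,
#'   `"passive_viewing"`.
#' @param block `"no_distractor"` or `"distractor"`.
#' @param rt_ms response time (ms from calculation onset).
#' @param distractor_delay_ms distractor onset delay from calculation onset
#'   (ms), or `NA` for none.  Must be one of 1000, 1500, 1750, 2000, 2250.
#' @param distractor_position index 0-7 on the response circle, or `NA`.
#' @return a one-row data frame of class `trial_timeline`.
#' @export
trial_timeline <- function(condition = "mult_no_distractor",
                           block = "no_distractor",
                           rt_ms = 2600,
                           distractor_delay_ms = NA_real_,
                           distractor_position = NA_integer_) {
  stop_if(!condition %in% c("mult_no_distractor", "mult_distractor", "passive_viewing"),
          "unknown condition")
  if (!is.na(distractor_delay_ms))
    stop_if(!distractor_delay_ms %in% c(1000, 1500, 1750, 2000, 2250),
            "distractor_delay_ms must be one of 1000, 1500, 1750, 2000, 2250")
  sign_onset <- 0
  op1_onset <- sign_onset + 2000
  op2_onset <- op1_onset + 300
  calc_onset <- op2_onset + 300
  structure(data.frame(
    condition = condition, block = block,
    sign_onset_ms = sign_onset, op1_onset_ms = op1_onset,
    op2_onset_ms = op2_onset, calc_onset_ms = calc_onset,
    distractor_onset_ms = calc_onset + distractor_delay_ms,
    distractor_position = distractor_position,
    response_time_ms = calc_onset + rt_ms,
    stringsAsFactors = FALSE), class = c("trial_timeline", "data.frame"))
}

# Raised-cosine saccade displacement profile.  Duration is tied to the main
# sequence: with position x(t) = A (1 - cos(pi t / D)) / 2 the peak velocity
# is pi A / (2 D), so D = pi / (2 * slope) makes peak_velocity = slope * A
# hold exactly for every amplitude.
saccade_duration_s <- function(config) pi / (2 * config$main_sequence_slope)

saccade_profile <- function(amplitude, n_samples, fs) {
  d <- (n_samples - 1) / fs
  t <- seq(0, d, length.out = n_samples)
  amplitude * (1 - cos(pi * t / d)) / 2
}

# Draw Poisson event onsets in [t0, t1] (seconds), returns sorted times.
draw_poisson_onsets <- function(rate, t0, t1) {
  if (rate <= 0 || t1 <= t0) return(numeric(0))
  n <- rpois(1, rate * (t1 - t0))
  sort(runif(n, t0, t1))
}

#' Simulate one trial
#'
#' Generates a uniformly sampled binocular recording for one trial: 2-D
#' Gaussian random-walk drift plus white tremor, Poisson microsaccades over
#' the whole trial and larger saccades during the calculation period of
#' multiplication trials (raised-cosine profiles obeying the main sequence),
#' Poisson blinks rendered as invalid pupil and gaze, white vergence noise
#' on horizontal disparity, and a task-evoked pupil ramp from calculation
#' onset in multiplication conditions.
#'
#' @param config a [simulation_config()].
#' @param timeline a [trial_timeline()].
#' @param seed integer seed for this trial's random stream.
#' @return a list with elements `samples` (sample table in the interchange
#'   dialect, see [read_samples()]), `truth` (ground-truth event data frame:
#'   type, eye, onset_ms, offset_ms, amplitude_deg, peak_vel_deg_s) and
#'   `latent` (noise-free cyclopean gaze in deg and pupil in mm).
#' @export
simulate_trial <- function(config, timeline, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  fs <- config$sampling_rate
  dt <- 1 / fs
  step_ms <- 1000 / fs
  t_end <- timeline$response_time_ms
  time_ms <- seq(0, t_end, by = step_ms)
  n <- length(time_ms)
  t_s <- time_ms / 1000
  is_mult <- timeline$condition != "passive_viewing"

  # latent cyclopean gaze (deg, relative to screen center)
  gx <- cumsum(rnorm(n, 0, config$drift_sd))
  gy <- cumsum(rnorm(n, 0, config$drift_sd))

  # blinks first: saccadic events are placed clear of them so the ground
  # truth contains only events that survive blink masking
  blink_on <- draw_poisson_onsets(config$blink_rate, 0, t_s[n])
  blink_dur <- runif(length(blink_on), config$blink_duration_ms[1],
                     config$blink_duration_ms[2]) / 1000
  keep <- blink_on + blink_dur <= t_s[n]
  blink_on <- blink_on[keep]; blink_dur <- blink_dur[keep]
  if (length(blink_on) > 1) {            # enforce non-overlap within type
    keep <- rep(TRUE, length(blink_on))
    last_off <- -Inf
    for (i in seq_along(blink_on)) {
      if (blink_on[i] <= last_off + 3 * dt) keep[i] <- FALSE
      else last_off <- blink_on[i] + blink_dur[i]
    }
    blink_on <- blink_on[keep]; blink_dur <- blink_dur[keep]
  }
  blink_off <- blink_on + blink_dur

  # saccadic events: microsaccades over the whole trial, larger saccades in
  # the calculation period of multiplication trials only.  Event counts are
  # Poisson; onsets that would collide with another event or a (padded)
  # blink are resampled, not dropped, so the configured rates are conserved.
  dur_s <- saccade_duration_s(config)
  dur_n <- max(2L, round(dur_s * fs))
  pad <- 4 * dt
  placed_on <- numeric(0); placed_amp <- numeric(0)
  place_events <- function(rate, t0, t1, micro) {
    if (rate <= 0 || t1 - dur_s <= t0) return()
    n_ev <- rpois(1, rate * (t1 - t0))
    for (k in seq_len(n_ev)) {
      amp <- if (micro)
        min(rlnorm(1, config$amp_micro_meanlog, config$amp_micro_sdlog), 1.5)
      else
        max(rlnorm(1, config$amp_macro_meanlog, config$amp_macro_sdlog), 1.51)
      for (try in 1:50) {
        on <- runif(1, t0, t1 - dur_s)
        off <- on + dur_s
        clash <- any(on - pad < blink_off & off + pad > blink_on) ||
          any(on <= placed_on + dur_s + 2 * dt & off + 2 * dt >= placed_on)
        if (!clash) {
          placed_on <<- c(placed_on, on)
          placed_amp <<- c(placed_amp, amp)
          break
        }
      }
    }
  }
  place_events(config$microsaccade_rate, 0, t_s[n], micro = TRUE)
  if (is_mult)
    place_events(config$saccade_rate_idc, timeline$calc_onset_ms / 1000,
                 t_s[n], micro = FALSE)
  ev <- data.frame(onset_s = placed_on, amplitude = placed_amp)
  if (nrow(ev)) ev <- ev[order(ev$onset_s), , drop = FALSE]

  # inject saccadic displacements into the latent gaze
  if (nrow(ev)) {
    theta <- runif(nrow(ev), 0, 2 * pi)
    for (i in seq_len(nrow(ev))) {
      i0 <- which.min(abs(t_s - ev$onset_s[i]))
      i1 <- min(n, i0 + dur_n - 1)
      prof <- saccade_profile(ev$amplitude[i], i1 - i0 + 1, fs)
      dx <- prof * cos(theta[i]); dy <- prof * sin(theta[i])
      gx[i0:i1] <- gx[i0:i1] + dx
      gy[i0:i1] <- gy[i0:i1] + dy
      if (i1 < n) {
        gx[(i1 + 1):n] <- gx[(i1 + 1):n] + dx[length(dx)]
        gy[(i1 + 1):n] <- gy[(i1 + 1):n] + dy[length(dy)]
      }
      ev$onset_ms[i] <- time_ms[i0]
      ev$offset_ms[i] <- time_ms[i1]
    }
  }

  # tremor (common mode) and vergence disparity noise (mm -> deg)
  tx <- rnorm(n, 0, config$tremor_sd); ty <- rnorm(n, 0, config$tremor_sd)
  disp_mm <- rnorm(n, 0, config$vergence_sd)
  disp_deg <- px_to_deg(disp_mm / mm_per_px(config), config)
  lx <- gx + tx - disp_deg / 2
  rx <- gx + tx + disp_deg / 2
  ly <- ry <- gy + ty

  # pupil: baseline + task-evoked linear ramp saturating 1 s after
  # calculation onset (multiplication conditions only) + white noise
  ramp <- if (is_mult)
    pmin(pmax((time_ms - timeline$calc_onset_ms) / 1000, 0), 1) else 0
  latent_pupil <- config$pupil_baseline + config$pupil_task_gain * ramp
  lp <- latent_pupil + rnorm(n, 0, config$pupil_noise_sd)
  rp <- latent_pupil + rnorm(n, 0, config$pupil_noise_sd)

  # render blinks: pupil and gaze invalid for the blink interval
  blink_rows <- data.frame(type = character(0), eye = character(0),
                           onset_ms = numeric(0), offset_ms = numeric(0),
                           amplitude_deg = numeric(0), peak_vel_deg_s = numeric(0),
                           stringsAsFactors = FALSE)
  if (length(blink_on)) {
    for (i in seq_along(blink_on)) {
      idx <- which(t_s >= blink_on[i] & t_s <= blink_off[i])
      lp[idx] <- rp[idx] <- NA_real_
      lx[idx] <- ly[idx] <- rx[idx] <- ry[idx] <- NA_real_
    }
    blink_rows <- data.frame(type = "blink", eye = "both",
                             onset_ms = time_ms[vapply(blink_on, function(b) which(t_s >= b)[1], 1L)],
                             offset_ms = time_ms[vapply(blink_off, function(b) rev(which(t_s <= b))[1], 1L)],
                             amplitude_deg = NA_real_, peak_vel_deg_s = NA_real_,
                             stringsAsFactors = FALSE)
  }

  truth <- blink_rows
  if (nrow(ev)) {
    type <- ifelse(ev$amplitude <= 1.5, "microsaccade", "saccade")
    truth <- rbind(truth, data.frame(
      type = type, eye = "both",
      onset_ms = ev$onset_ms, offset_ms = ev$offset_ms,
      amplitude_deg = ev$amplitude,
      peak_vel_deg_s = config$main_sequence_slope * ev$amplitude,
      stringsAsFactors = FALSE))
  }
  if (nrow(truth)) truth <- truth[order(truth$onset_ms), , drop = FALSE]
  rownames(truth) <- NULL

  cx <- config$screen_center[1]; cy <- config$screen_center[2]
  samples <- data.frame(
    participant = 1L, trial = 1L, time_ms = as.integer(round(time_ms)),
    lx_px = cx + deg_to_px(lx, config), ly_px = cy + deg_to_px(ly, config),
    rx_px = cx + deg_to_px(rx, config), ry_px = cy + deg_to_px(ry, config),
    l_pupil_mm = lp, r_pupil_mm = rp)

  list(samples = samples, truth = truth,
       latent = data.frame(time_ms = samples$time_ms, gaze_x_deg = gx,
                           gaze_y_deg = gy, pupil_mm = latent_pupil))
}

# deterministic per-trial substreams from a session seed: trial order never
# changes the draws of another trial
derive_seeds <- function(master_seed, n) {
  set.seed(as.integer(master_seed))
  sample.int(2147483646L, n)
}

#' Simulate a full session for one participant
#'
#' Emits both blocks (without and with distractors) with the paradigm's trial
#' counts: 18 multiplication and 4 passive-viewing trials per block by
#' default.  In the distractor block the five onset delays (1.0, 1.5, 1.75,
#' 2.0, 2.25 s after calculation onset) are randomly assigned to four or
#' five of the 22 trials each; 1.0 s trials are flagged as catch trials.
#' Response correctness is sampled from the configured accuracy.
#'
#' @param config a [simulation_config()].
#' @param participant participant id (also offsets the random stream).
#' @return a list with `samples` (all trials stacked), `trials` (trial
#'   metadata table, see [read_trials()]) and `truth` (ground-truth events
#'   with participant and trial columns).
#' @export
simulate_session <- function(config, participant = 1L) {
  stopifnot(inherits(config, "sim_config"))
  n_mult <- config$n_mult_per_block
  n_pass <- config$n_passive_per_block
  n_per_block <- n_mult + n_pass
  session_seed <- (config$seed + 104729 * (as.integer(participant) - 1L)) %% 2147483647L
  set.seed(session_seed)
  trial_seeds <- derive_seeds(session_seed, max(1, 2 * n_per_block))

  all_samples <- list(); all_truth <- list(); trial_rows <- list()
  trial_id <- 0L
  for (block in c("no_distractor", "distractor")) {
    if (n_per_block == 0) next
    is_mult <- sample(rep(c(TRUE, FALSE), c(n_mult, n_pass)))
    if (block == "distractor") {
      delays <- c(1000, 1500, 1750, 2000, 2250)
      n_each <- rep(floor(n_per_block / 5), 5)
      extra <- n_per_block - sum(n_each)
      if (extra > 0) n_each[sample.int(5, extra)] <- n_each[sample.int(5, extra)] + 1
      delay_assign <- sample(rep(delays, n_each))
      pos_assign <- sample.int(8, n_per_block, replace = TRUE) - 1L
    }
    for (i in seq_len(n_per_block)) {
      trial_id <- trial_id + 1L
      mult <- is_mult[i]
      cond <- if (!mult) "passive_viewing"
              else if (block == "distractor") "mult_distractor" else "mult_no_distractor"
      rt <- if (mult) max(1600, min(rlnorm(1, config$rt_meanlog, config$rt_sdlog), 8000))
            else 5000 + rnorm(1, 0, 300)
      delay <- if (block == "distractor") delay_assign[i] else NA_real_
      pos <- if (block == "distractor") pos_assign[i] else NA_integer_
      if (!is.na(delay) && delay + 500 > rt) rt <- delay + 600  # distractor fits
      tl <- trial_timeline(condition = cond, block = block, rt_ms = rt,
                           distractor_delay_ms = delay, distractor_position = pos)
      sim <- simulate_trial(config, tl, seed = trial_seeds[trial_id])
      sim$samples$participant <- as.integer(participant)
      sim$samples$trial <- trial_id
      all_samples[[trial_id]] <- sim$samples
      if (nrow(sim$truth)) {
        sim$truth$participant <- as.integer(participant)
        sim$truth$trial <- trial_id
        all_truth[[trial_id]] <- sim$truth
      }
      correctness <- if (!mult) "correct"
        else sample(c("correct", "incorrect", "forgot"), 1,
                    prob = c(config$accuracy,
                             1 - config$accuracy - config$forgot_rate,
                             config$forgot_rate))
      trial_rows[[trial_id]] <- data.frame(
        participant = as.integer(participant), trial = trial_id,
        condition = cond, block = block,
        sign_onset_ms = tl$sign_onset_ms, op1_onset_ms = tl$op1_onset_ms,
        op2_onset_ms = tl$op2_onset_ms, calc_onset_ms = tl$calc_onset_ms,
        distractor_onset_ms = tl$distractor_onset_ms,
        distractor_position = tl$distractor_position,
        response_time_ms = tl$response_time_ms,
        correctness = correctness, rt_s = rt / 1000,
        catch_flag = isTRUE(!is.na(delay) && delay == 1000),
        passive_response_valid = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  trials <- if (length(trial_rows)) do.call(rbind, trial_rows) else
    data.frame(participant = integer(0), trial = integer(0),
               condition = character(0), block = character(0),
               sign_onset_ms = numeric(0), op1_onset_ms = numeric(0),
               op2_onset_ms = numeric(0), calc_onset_ms = numeric(0),
               distractor_onset_ms = numeric(0), distractor_position = integer(0),
               response_time_ms = numeric(0), correctness = character(0),
               rt_s = numeric(0), catch_flag = logical(0),
               passive_response_valid = logical(0), stringsAsFactors = FALSE)
  samples <- if (length(all_samples)) do.call(rbind, all_samples) else
    empty_samples()
  truth <- if (length(all_truth)) do.call(rbind, all_truth) else
    data.frame(type = character(0), eye = character(0), onset_ms = numeric(0),
               offset_ms = numeric(0), amplitude_deg = numeric(0),
               peak_vel_deg_s = numeric(0), participant = integer(0),
               trial = integer(0), stringsAsFactors = FALSE)
  rownames(samples) <- rownames(trials) <- rownames(truth) <- NULL
  list(samples = samples, trials = trials, truth = truth)
}

empty_samples <- function() {
  data.frame(participant = integer(0), trial = integer(0), time_ms = integer(0),
             lx_px = numeric(0), ly_px = numeric(0), rx_px = numeric(0),
             ry_px = numeric(0), l_pupil_mm = numeric(0), r_pupil_mm = numeric(0))
}
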