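# Extraction of the six eye parameters -- blink rate, saccade rate,
# microsaccade rate, fixation disparity, pupil diameter and gaze at center
# -- in contiguous 500 ms bins with trial-wise subtractive baseline
# correction, plus distractor-locked epochs and parameter intercorrelations.

#' Event onset rate per bin
#'
#' Counts event onsets whose onset time falls in the half-open interval
#' `[bin_start, bin_end)` and converts the count to Hz by multiplying with
#' `rate_multiplier` (2 for 500 ms bins).
#'
#' @param onset_ms event onset times (ms).
#' @param bin_start,bin_end bin boundaries (ms).
#' @param rate_multiplier count-to-Hz factor.
#' @return rate in Hz.
#' @export
event_rate_per_bin <- function(onset_ms, bin_start, bin_end,
                               rate_multiplier = 2) {
  sum(onset_ms >= bin_start & onset_ms < bin_end) * rate_multiplier
}

# samples eligible for continuous parameters: valid under the mask and not
# inside any blink/saccade/microsaccade interval
eligible_samples <- function(time_ms, valid, events) {
  elig <- valid
  if (nrow(events)) {
    for (i in seq_len(nrow(events)))
      elig <- elig & !(time_ms >= events$onset_ms[i] &
                       time_ms <= events$offset_ms[i])
  }
  elig
}

#' Fixation disparity per sample
#'
#' Signed horizontal vergence error: right-eye minus left-eye horizontal
#' gaze position, converted from pixels to screen millimetres.  Negative
#' values indicate crossed (convergent) eyes, positive values walled
#' (divergent) eyes.
#'
#' @param samples a sample table.
#' @param sim_config a [simulation_config()] supplying the px-to-mm pitch.
#' @return numeric vector (mm), NA where either eye is invalid.
#' @export
fixation_disparity <- function(samples, sim_config = simulation_config()) {
  disparity_mm(samples, sim_config)
}

#' Percentage of gaze-at-center samples in a bin
#'
#' The fraction of samples whose cyclopean gaze (binocular mean) lies within
#' `center_radius_deg` of the screen center, as a percentage of the full
#' bin sample count (masked samples count in the denominator but can never
#' count in the numerator).
#'
#' @param samples sample table rows of one trial.
#' @param valid per-sample validity.
#' @param bin_start,bin_end bin boundaries (ms, half-open).
#' @param binning a [binning_config()].
#' @param sim_config a [simulation_config()].
#' @return percentage in [0, 100].
#' @export
gaze_at_center <- function(samples, valid, bin_start, bin_end,
                           binning = binning_config(),
                           sim_config = simulation_config()) {
  inbin <- samples$time_ms >= bin_start & samples$time_ms < bin_end
  n_total <- sum(inbin)
  if (n_total == 0) return(NA_real_)
  cx <- sim_config$screen_center[1]; cy <- sim_config$screen_center[2]
  gx <- (samples$lx_px + samples$rx_px) / 2 - cx
  gy <- (samples$ly_px + samples$ry_px) / 2 - cy
  r_px <- deg_to_px(binning$center_radius_deg, sim_config)
  at_center <- inbin & valid & is.finite(gx) & is.finite(gy) &
    sqrt(gx^2 + gy^2) <= r_px
  100 * sum(at_center) / n_total
}

median_in_bin <- function(values, time_ms, elig, bin_start, bin_end) {
  sel <- elig & time_ms >= bin_start & time_ms < bin_end & !is.na(values)
  if (!any(sel)) return(NA_real_)
  median(values[sel])
}

param_names <- c("blink_rate", "saccade_rate", "microsaccade_rate",
                 "fixation_disparity", "pupil_diameter", "gaze_at_center")

# Raw values of the six parameters over one window of one trial.
window_parameters <- function(samples, valid, events, blinks, win,
                              binning, sim_config) {
  dur_s <- (win[2] - win[1]) / 1000
  mult <- binning$rate_multiplier * (binning$bin_width_ms / 1000) / dur_s
  elig <- eligible_samples(samples$time_ms, valid,
                           rbind(events[, c("onset_ms", "offset_ms")],
                                 blinks[, c("onset_ms", "offset_ms")]))
  disp <- fixation_disparity(samples, sim_config)
  pupil <- binocular_pupil(samples)
  sac <- events[events$type == "saccade", , drop = FALSE]
  mic <- events[events$type == "microsaccade", , drop = FALSE]
  c(blink_rate = event_rate_per_bin(blinks$onset_ms, win[1], win[2], mult),
    saccade_rate = event_rate_per_bin(sac$onset_ms, win[1], win[2], mult),
    microsaccade_rate = event_rate_per_bin(mic$onset_ms, win[1], win[2], mult),
    fixation_disparity = median_in_bin(disp, samples$time_ms, elig, win[1], win[2]),
    pupil_diameter = median_in_bin(pupil, samples$time_ms, elig, win[1], win[2]),
    gaze_at_center = gaze_at_center(samples, valid, win[1], win[2],
                                    binning, sim_config))
}

#' Pupil diameter per bin
#'
#' Median of the binocular-mean pupil diameter over eligible samples (valid
#' under the mask and outside blink, saccade and microsaccade intervals) in
#' the half-open bin.
#'
#' @param samples sample table rows of one trial.
#' @param valid per-sample validity.
#' @param events saccadic events of the trial (onset_ms, offset_ms).
#' @param bin_start,bin_end bin boundaries (ms).
#' @return mm, or NA when the bin has no eligible sample.
#' @export
pupil_per_bin <- function(samples, valid, events, bin_start, bin_end) {
  elig <- eligible_samples(samples$time_ms, valid, events)
  median_in_bin(binocular_pupil(samples), samples$time_ms, elig,
                bin_start, bin_end)
}

#' Bin the six eye parameters for all trials
#'
#' For each trial, computes the six parameters raw in the four analysis
#' bins (relative to calculation onset) and their trial-wise baselines:
#' the median of the 500 ms window preceding first-operand onset for pupil
#' diameter and fixation disparity, and the mean rate (or percentage) over
#' the 2 s sign-presentation window for the event rates and gaze at center.
#'
#' @param samples a sample table.
#' @param mask preprocessing mask (or NULL).
#' @param events binocular events from [detect_saccades()].
#' @param blinks blink events from [detect_blinks()].
#' @param trials trial metadata table.
#' @param binning a [binning_config()].
#' @param baseline a [baseline_config()].
#' @param sim_config a [simulation_config()].
#' @return long-format data frame: participant, trial, condition, block,
#'   bin (label), bin_start_ms, parameter, raw, baseline, corrected.
#' @export
bin_parameters <- function(samples, mask, events, blinks, trials,
                           binning = binning_config(),
                           baseline = baseline_config(),
                           sim_config = simulation_config()) {
  if (is.null(mask)) mask <- new_mask(nrow(samples))
  valid <- mask_valid(mask)
  bw <- binning$bin_width_ms
  bins <- cbind(binning$bin_starts_ms, binning$bin_starts_ms + bw)
  bin_labels <- sprintf("%g_to_%gs", bins[, 1] / 1000, bins[, 2] / 1000)
  out <- list()
  for (ti in seq_len(nrow(trials))) {
    tr <- trials[ti, ]
    idx <- which(samples$participant == tr$participant &
                 samples$trial == tr$trial)
    if (!length(idx)) next
    s <- samples[idx, , drop = FALSE]
    v <- valid[idx]
    ev <- events[events$participant == tr$participant &
                 events$trial == tr$trial, , drop = FALSE]
    bl <- blinks[blinks$participant == tr$participant &
                 blinks$trial == tr$trial, , drop = FALSE]
    calc <- tr$calc_onset_ms
    # baselines
    base_rate_win <- c(tr$sign_onset_ms, tr$sign_onset_ms + baseline$rate_window_ms)
    base_cont_win <- c(tr$op1_onset_ms - baseline$continuous_window_ms,
                       tr$op1_onset_ms)
    base_rates <- window_parameters(s, v, ev, bl, base_rate_win, binning, sim_config)
    base_cont <- window_parameters(s, v, ev, bl, base_cont_win, binning, sim_config)
    base <- c(blink_rate = unname(base_rates["blink_rate"]),
              saccade_rate = unname(base_rates["saccade_rate"]),
              microsaccade_rate = unname(base_rates["microsaccade_rate"]),
              fixation_disparity = unname(base_cont["fixation_disparity"]),
              pupil_diameter = unname(base_cont["pupil_diameter"]),
              gaze_at_center = unname(base_rates["gaze_at_center"]))
    for (b in seq_len(nrow(bins))) {
      win <- calc + bins[b, ]
      raw <- window_parameters(s, v, ev, bl, win, binning, sim_config)
      out[[length(out) + 1L]] <- data.frame(
        participant = tr$participant, trial = tr$trial,
        condition = tr$condition, block = tr$block,
        bin = bin_labels[b], bin_start_ms = bins[b, 1],
        parameter = param_names, raw = unname(raw[param_names]),
        baseline = unname(base[param_names]),
        stringsAsFactors = FALSE)
    }
  }
  binned <- if (length(out)) do.call(rbind, out) else
    data.frame(participant = integer(0), trial = integer(0),
               condition = character(0), block = character(0),
               bin = character(0), bin_start_ms = numeric(0),
               parameter = character(0), raw = numeric(0),
               baseline = numeric(0), stringsAsFactors = FALSE)
  rownames(binned) <- NULL
  baseline_correct(binned)
}

#' Trial-wise subtractive baseline correction
#'
#' Subtracts each trial's baseline from the raw bin values:
#' `corrected = raw - baseline`.  Bins whose baseline is missing propagate
#' as missing (flagged for listwise handling downstream).
#'
#' @param binned long-format table with raw and baseline columns.
#' @return the table with a corrected column added.
#' @export
baseline_correct <- function(binned) {
  binned$corrected <- binned$raw - binned$baseline
  binned
}

#' Distractor-locked epochs
#'
#' Re-anchors the six parameters to distractor onset: bins of
#' `bin_width_ms` tile the window (default -500 to +1000 ms around the
#' distractor), baseline-corrected with the 500 ms window preceding
#' distractor appearance (median for pupil and disparity, rate/percentage
#' for the counting parameters).
#'
#' @inheritParams bin_parameters
#' @param window epoch window around distractor onset (ms).
#' @return long-format table as in [bin_parameters()], with bins relative
#'   to distractor onset.  Trials without a distractor raise an error when
#'   `trials` contains only such trials; otherwise they are skipped.
#' @export
distractor_locked_epochs <- function(samples, mask, events, blinks, trials,
                                     window = c(-500, 1000),
                                     binning = binning_config(),
                                     sim_config = simulation_config()) {
  has_distr <- !is.na(trials$distractor_onset_ms)
  if (!any(has_distr))
    stop("no trial has a distractor onset", call. = FALSE)
  trials <- trials[has_distr, , drop = FALSE]
  if (is.null(mask)) mask <- new_mask(nrow(samples))
  valid <- mask_valid(mask)
  bw <- binning$bin_width_ms
  starts <- seq(window[1], window[2] - bw, by = bw)
  bins <- cbind(starts, starts + bw)
  dimnames(bins) <- NULL
  bin_labels <- sprintf("%g_to_%gs", bins[, 1] / 1000, bins[, 2] / 1000)
  out <- list()
  for (ti in seq_len(nrow(trials))) {
    tr <- trials[ti, ]
    idx <- which(samples$participant == tr$participant &
                 samples$trial == tr$trial)
    if (!length(idx)) next
    s <- samples[idx, , drop = FALSE]
    v <- valid[idx]
    ev <- events[events$participant == tr$participant &
                 events$trial == tr$trial, , drop = FALSE]
    bl <- blinks[blinks$participant == tr$participant &
                 blinks$trial == tr$trial, , drop = FALSE]
    anchor <- tr$distractor_onset_ms
    base <- window_parameters(s, v, ev, bl, anchor + c(-500, 0),
                              binning, sim_config)
    for (b in seq_len(nrow(bins))) {
      raw <- window_parameters(s, v, ev, bl, anchor + bins[b, ],
                               binning, sim_config)
      out[[length(out) + 1L]] <- data.frame(
        participant = tr$participant, trial = tr$trial,
        condition = tr$condition, block = tr$block,
        bin = bin_labels[b], bin_start_ms = bins[b, 1],
        parameter = param_names, raw = unname(raw[param_names]),
        baseline = unname(base[param_names]),
        stringsAsFactors = FALSE)
    }
  }
  binned <- do.call(rbind, out)
  rownames(binned) <- NULL
  baseline_correct(binned)
}

#' Intercorrelations of the six eye parameters
#'
#' Pairwise Pearson correlations of the baseline-corrected parameter values
#' over observations (trial x bin by default), using pairwise-complete
#' observations.  Constant columns yield NA entries.
#'
#' @param binned long-format table from [bin_parameters()].
#' @return symmetric 6 x 6 correlation matrix with unit diagonal.
#' @export
parameter_correlations <- function(binned) {
  obs <- interaction(binned$participant, binned$trial, binned$bin, drop = TRUE)
  wide <- sapply(param_names, function(p) {
    v <- rep(NA_real_, nlevels(obs))
    sel <- binned$parameter == p
    v[match(obs[sel], levels(obs))] <- binned$corrected[sel]
    v
  })
  suppressWarnings(r <- cor(wide, use = "pairwise.complete.obs"))
  diag(r) <- ifelse(apply(wide, 2, function(x) sum(!is.na(x)) > 0), 1, NA)
  r
}
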