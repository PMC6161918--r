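# Sample-level cleaning: blink detection on invalid-pupil runs, blink
# padding, physiological-range exclusion for pupil diameter and fixation
# disparity, and the per-participant 3-SD rule.  Masked samples are dropped
# from later analyses, never interpolated.

trial_groups <- function(samples) {
  split(seq_len(nrow(samples)),
        interaction(samples$participant, samples$trial, drop = TRUE))
}

# maximal runs of TRUE in a logical vector, as a two-column matrix of
# (start, end) indices
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect blinks as invalid-pupil runs
#'
#' A blink is a maximal run of at least `min_run` consecutive samples in
#' which the pupil of either eye is invalid (missing).  Runs are detected
#' per trial and returned time-ordered and non-overlapping.
#'
#' @param samples a sample table (see [read_samples()]).
#' @param min_run minimum run length in samples (default 3, i.e. 12 ms at
#'   250 Hz, rejecting isolated dropped samples).
#' @return a data frame of blink events: participant, trial, type,
#'   onset_ms, offset_ms, onset_idx, offset_idx (row indices into
#'   `samples`).
#' @export
detect_blinks <- function(samples, min_run = 3) {
  out <- list()
  for (idx in trial_groups(samples)) {
    invalid <- is.na(samples$l_pupil_mm[idx]) | is.na(samples$r_pupil_mm[idx])
    if (!any(invalid)) next
    runs <- logical_runs(invalid)
    runs <- runs[runs[, "end"] - runs[, "start"] + 1L >= min_run, , drop = FALSE]
    if (!nrow(runs)) next
    out[[length(out) + 1L]] <- data.frame(
      participant = samples$participant[idx[1]],
      trial = samples$trial[idx[1]], type = "blink",
      onset_ms = samples$time_ms[idx[runs[, "start"]]],
      offset_ms = samples$time_ms[idx[runs[, "end"]]],
      onset_idx = idx[runs[, "start"]], offset_idx = idx[runs[, "end"]],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(participant = integer(0), trial = integer(0),
                      type = character(0), onset_ms = numeric(0),
                      offset_ms = numeric(0), onset_idx = integer(0),
                      offset_idx = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$participant, res$trial, res$onset_ms), , drop = FALSE]
}

new_mask <- function(n) {
  data.frame(blink = logical(n), blink_pad = logical(n),
             extreme_value = logical(n), sd_outlier = logical(n))
}

mask_valid <- function(mask) {
  !(mask$blink | mask$blink_pad | mask$extreme_value | mask$sd_outlier)
}

#' Flag blink samples plus padding
#'
#' Marks every sample inside a blink, plus `blink_pad_samples` samples
#' (8 ms at 250 Hz by default) before and after it, to remove data distorted
#' by lid closure.  Overlapping padded intervals merge in the mask; padding
#' never crosses trial boundaries.
#'
#' @param samples a sample table.
#' @param blinks output of [detect_blinks()].
#' @param config an [exclusion_config()].
#' @return a per-sample mask data frame (columns blink, blink_pad,
#'   extreme_value, sd_outlier) aligned with `samples`.
#' @export
pad_and_mask_blinks <- function(samples, blinks, config = exclusion_config()) {
  mask <- new_mask(nrow(samples))
  if (!nrow(blinks)) return(mask)
  pad <- config$blink_pad_samples
  bounds <- lapply(trial_groups(samples), range)
  key <- function(p, tr) paste(p, tr, sep = ".")
  names(bounds) <- names(trial_groups(samples))
  for (i in seq_len(nrow(blinks))) {
    b <- bounds[[key(blinks$participant[i], blinks$trial[i])]]
    on <- blinks$onset_idx[i]; off <- blinks$offset_idx[i]
    mask$blink[on:off] <- TRUE
    lo <- max(b[1], on - pad); hi <- min(b[2], off + pad)
    pad_idx <- setdiff(lo:hi, on:off)
    if (length(pad_idx)) mask$blink_pad[pad_idx] <- TRUE
  }
  # a sample inside one blink's pad but another blink proper stays 'blink'
  mask$blink_pad[mask$blink] <- FALSE
  mask
}

binocular_pupil <- function(samples) {
  (samples$l_pupil_mm + samples$r_pupil_mm) / 2
}

disparity_mm <- function(samples, config) {
  px_to_mm(samples$rx_px - samples$lx_px, config)
}

#' Range and per-participant SD exclusion
#'
#' Flags samples with physiologically implausible pupil diameter (outside
#' `[pupil_min, pupil_max]` in either eye) or absolute fixation disparity
#' above `disparity_max` (measurement errors), then flags samples whose
#' pupil or disparity lies more than `sd_multiplier` standard deviations
#' from that participant's mean, computed over the participant's session on
#' samples not already masked.
#'
#' @param samples a sample table.
#' @param mask mask from [pad_and_mask_blinks()].
#' @param config an [exclusion_config()].
#' @param sim_config a [simulation_config()] supplying the px-to-mm pitch.
#' @return a list with `mask` (updated) and `summary`: one row per
#'   participant with pct_blink_discard (blink + pad, % of all samples) and
#'   pct_extreme_discard (range + SD outliers, % of the remaining samples);
#'   the two percentages deliberately use disjoint denominators.
#' @export
exclude_extremes <- function(samples, mask, config = exclusion_config(),
                             sim_config = simulation_config()) {
  if (!nrow(samples)) stop("degenerate input: no samples", call. = FALSE)
  pupil_l <- samples$l_pupil_mm; pupil_r <- samples$r_pupil_mm
  disp <- disparity_mm(samples, sim_config)
  out_range <- (!is.na(pupil_l) & (pupil_l > config$pupil_max | pupil_l < config$pupil_min)) |
               (!is.na(pupil_r) & (pupil_r > config$pupil_max | pupil_r < config$pupil_min)) |
               (!is.na(disp) & abs(disp) > config$disparity_max)
  mask$extreme_value <- mask$extreme_value | (out_range & mask_valid(mask))

  pupil <- binocular_pupil(samples)
  k <- config$sd_multiplier
  for (p in unique(samples$participant)) {
    rows <- which(samples$participant == p)
    ok <- rows[mask_valid(mask)[rows]]
    ok <- ok[!is.na(pupil[ok]) & !is.na(disp[ok])]
    if (!length(ok)) stop("degenerate input: participant ", p,
                          " has zero valid samples", call. = FALSE)
    mp <- mean(pupil[ok]); sp <- sd(pupil[ok])
    md <- mean(disp[ok]); sdd <- sd(disp[ok])
    out_sd <- logical(length(rows))
    sel <- match(ok, rows)
    if (is.finite(sp) && sp > 0)
      out_sd[sel] <- out_sd[sel] | abs(pupil[ok] - mp) > k * sp
    if (is.finite(sdd) && sdd > 0)
      out_sd[sel] <- out_sd[sel] | abs(disp[ok] - md) > k * sdd
    mask$sd_outlier[rows] <- mask$sd_outlier[rows] | out_sd
  }

  summary <- do.call(rbind, lapply(unique(samples$participant), function(p) {
    rows <- samples$participant == p
    n <- sum(rows)
    n_blink <- sum(mask$blink[rows] | mask$blink_pad[rows])
    n_rest <- n - n_blink
    n_extreme <- sum((mask$extreme_value | mask$sd_outlier)[rows])
    data.frame(participant = p,
               pct_blink_discard = 100 * n_blink / n,
               pct_extreme_discard = if (n_rest > 0) 100 * n_extreme / n_rest else NA_real_)
  }))
  rownames(summary) <- NULL
  list(mask = mask, summary = summary)
}

#' Full sample preprocessing
#'
#' Convenience wrapper running [detect_blinks()], [pad_and_mask_blinks()]
#' and [exclude_extremes()] in order.  Idempotent: applying it to already
#' clean data reproduces the same mask.
#'
#' @inheritParams exclude_extremes
#' @return a list with `mask`, `blinks` and `summary`.
#' @export
preprocess_samples <- function(samples, config = exclusion_config(),
                               sim_config = simulation_config()) {
  blinks <- detect_blinks(samples, min_run = config$blink_min_run)
  mask <- pad_and_mask_blinks(samples, blinks, config)
  ex <- exclude_extremes(samples, mask, config, sim_config)
  list(mask = ex$mask, blinks = blinks, summary = ex$summary)
}
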