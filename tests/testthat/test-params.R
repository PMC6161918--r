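# Binned eye parameters, baselines and distractor-locked epochs.

test_that("event rates count onsets in half-open bins times the multiplier", {
  expect_equal(event_rate_per_bin(c(100), 0, 500), 2)       # 1 onset -> 2 Hz
  expect_equal(event_rate_per_bin(numeric(0), 0, 500), 0)
  # onset-based, half-open: onset 1 sample before the bin is not counted,
  # onset exactly at bin start is, onset at bin end is not
  expect_equal(event_rate_per_bin(c(-4, 0, 496, 500), 0, 500), 2 * 2)
})

test_that("fixation disparity is signed right-minus-left in screen mm", {
  cfg <- simulation_config()
  s <- data.frame(participant = 1L, trial = 1L, time_ms = 0L,
                  lx_px = 960, ly_px = 540, rx_px = 960, ry_px = 540,
                  l_pupil_mm = 4, r_pupil_mm = 4)
  expect_equal(fixation_disparity(s, cfg), 0)
  s$rx_px <- 950   # right gaze 10 px left of left gaze: convergent
  expect_lt(fixation_disparity(s, cfg), 0)
  expect_equal(fixation_disparity(s, cfg), -10 * 531 / 1920)
})

test_that("gaze at center uses the full bin as denominator", {
  cfg <- simulation_config()
  bcfg <- binning_config()
  n <- 125
  s <- data.frame(participant = 1L, trial = 1L,
                  time_ms = as.integer(seq(0, by = 4, length.out = n)),
                  lx_px = 960, ly_px = 540, rx_px = 960, ry_px = 540,
                  l_pupil_mm = 4, r_pupil_mm = 4)
  valid <- rep(TRUE, n)
  expect_equal(gaze_at_center(s, valid, 0, 500, bcfg, cfg), 100)
  # 25 of 125 samples within 1 degree -> 20%
  s2 <- s
  s2$lx_px[26:125] <- s2$rx_px[26:125] <- 960 + 2 * 45  # 2 deg off center
  expect_equal(gaze_at_center(s2, valid, 0, 500, bcfg, cfg), 20)
  # bin entirely masked (blink): numerator empty -> 0%
  expect_equal(gaze_at_center(s, rep(FALSE, n), 0, 500, bcfg, cfg), 0)
  # bounded even when gaze sits exactly on the radius
  s3 <- s
  s3$lx_px <- s3$rx_px <- 960 + 45
  expect_equal(gaze_at_center(s3, valid, 0, 500, bcfg, cfg), 100)
})

test_that("pupil and disparity bins are medians over eligible samples", {
  n <- 10
  s <- data.frame(participant = 1L, trial = 1L,
                  time_ms = as.integer(seq(0, by = 4, length.out = n)),
                  lx_px = 960, ly_px = 540, rx_px = 960, ry_px = 540,
                  l_pupil_mm = 4, r_pupil_mm = 4)
  valid <- rep(TRUE, n)
  no_events <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0))
  expect_equal(pupil_per_bin(s, valid, no_events, 0, 40), 4)
  # values {3,3,5} eligible -> median 3
  s$l_pupil_mm <- s$r_pupil_mm <- c(3, 3, 5, rep(99, 7))
  expect_equal(pupil_per_bin(s, valid, no_events, 0, 12), 3)
  # samples inside a saccade interval are excluded from the median
  ev <- data.frame(onset_ms = 0, offset_ms = 4)
  expect_equal(pupil_per_bin(s, valid, ev, 0, 12), 5)
  # empty bin propagates as missing
  expect_true(is.na(pupil_per_bin(s, rep(FALSE, n), no_events, 0, 12)))
})

sim_one_trial_binned <- function(cfg, tl, seed) {
  sim <- simulate_trial(cfg, tl, seed = seed)
  trial <- data.frame(participant = 1L, trial = 1L,
                      condition = tl$condition, block = tl$block,
                      sign_onset_ms = tl$sign_onset_ms,
                      op1_onset_ms = tl$op1_onset_ms,
                      op2_onset_ms = tl$op2_onset_ms,
                      calc_onset_ms = tl$calc_onset_ms,
                      distractor_onset_ms = tl$distractor_onset_ms,
                      distractor_position = tl$distractor_position,
                      response_time_ms = tl$response_time_ms,
                      stringsAsFactors = FALSE)
  prep <- preprocess_samples(sim$samples, sim_config = cfg)
  ev <- detect_saccades(sim$samples, prep$mask, detection_config(), cfg)
  list(sim = sim, trial = trial, prep = prep, ev = ev,
       binned = bin_parameters(sim$samples, prep$mask, ev, prep$blinks,
                               trial, sim_config = cfg))
}

test_that("the four bins tile the analysis window with 125 samples each", {
  cfg <- simulation_config(seed = 51)
  tl <- trial_timeline(rt_ms = 3000)
  res <- sim_one_trial_binned(cfg, tl, 51)
  b <- res$binned
  expect_equal(sort(unique(b$bin_start_ms)), c(-500, 0, 500, 1000))
  expect_equal(nrow(b), 4 * 6)
  # 125 samples per bin at 250 Hz
  for (start in unique(b$bin_start_ms)) {
    w <- tl$calc_onset_ms + c(start, start + 500)
    expect_equal(sum(res$sim$samples$time_ms >= w[1] &
                       res$sim$samples$time_ms < w[2]), 125)
  }
})

test_that("baseline correction is subtractive with the right windows", {
  cfg <- simulation_config(blink_rate = 0, microsaccade_rate = 0,
                           saccade_rate_idc = 0, pupil_task_gain = 0,
                           seed = 52)
  tl <- trial_timeline(rt_ms = 3000)
  res <- sim_one_trial_binned(cfg, tl, 52)
  b <- res$binned
  expect_equal(b$corrected, b$raw - b$baseline)
  # stationary pupil: baseline equals the pre-operand median, computed here
  # against a direct sort-based oracle
  s <- res$sim$samples
  win <- s$time_ms >= tl$op1_onset_ms - 500 & s$time_ms < tl$op1_onset_ms
  pup <- (s$l_pupil_mm + s$r_pupil_mm) / 2
  v <- sort(pup[win])
  oracle_median <- if (length(v) %% 2 == 1) v[(length(v) + 1) / 2] else
    (v[length(v) / 2] + v[length(v) / 2 + 1]) / 2
  expect_equal(unique(b$baseline[b$parameter == "pupil_diameter"]),
               oracle_median)
})

test_that("rate baselines use the 2 s sign window as count over two", {
  # three blinks placed inside the sign window -> baseline 1.5 Hz
  cfg <- simulation_config()
  n <- trial_timeline(rt_ms = 3000)$response_time_ms / 4 + 1
  s <- data.frame(participant = 1L, trial = 1L,
                  time_ms = as.integer(seq(0, by = 4, length.out = n)),
                  lx_px = 960, ly_px = 540, rx_px = 960, ry_px = 540,
                  l_pupil_mm = 4, r_pupil_mm = 4)
  for (on in c(100, 700, 1300))
    s$l_pupil_mm[s$time_ms >= on & s$time_ms <= on + 100] <- NA
  tl <- trial_timeline(rt_ms = 3000)
  trial <- data.frame(participant = 1L, trial = 1L,
                      condition = "mult_no_distractor", block = "no_distractor",
                      sign_onset_ms = 0, op1_onset_ms = 2000, op2_onset_ms = 2300,
                      calc_onset_ms = 2600, distractor_onset_ms = NA_real_,
                      distractor_position = NA_integer_,
                      response_time_ms = tl$response_time_ms)
  prep <- preprocess_samples(s, sim_config = cfg)
  no_ev <- data.frame(participant = integer(0), trial = integer(0),
                      type = character(0), onset_ms = numeric(0),
                      offset_ms = numeric(0))
  b <- bin_parameters(s, prep$mask, no_ev, prep$blinks, trial, sim_config = cfg)
  expect_equal(unique(b$baseline[b$parameter == "blink_rate"]), 3 / 2)
})

test_that("rate conservation: bin counts sum to the onsets in the window", {
  cfg <- simulation_config(seed = 53, microsaccade_rate = 2.5)
  tl <- trial_timeline(rt_ms = 3000)
  res <- sim_one_trial_binned(cfg, tl, 53)
  b <- res$binned
  for (type in c("saccade", "microsaccade")) {
    par <- paste0(type, "_rate")
    total <- sum(b$raw[b$parameter == par]) / 2
    onsets <- res$ev$onset_ms[res$ev$type == type]
    expect_equal(total, sum(onsets >= tl$calc_onset_ms - 500 &
                              onsets < tl$calc_onset_ms + 1500))
  }
})

test_that("distractor-locked epochs recover a pupil step and tile the window", {
  cfg <- simulation_config(blink_rate = 0, microsaccade_rate = 0,
                           saccade_rate_idc = 0, pupil_task_gain = 0,
                           pupil_noise_sd = 0.001, seed = 54)
  tl <- trial_timeline(condition = "mult_distractor", block = "distractor",
                       rt_ms = 4000, distractor_delay_ms = 1500,
                       distractor_position = 0)
  sim <- simulate_trial(cfg, tl, seed = 54)
  # inject a 0.2 mm pupil step at distractor onset
  post <- sim$samples$time_ms >= tl$distractor_onset_ms
  sim$samples$l_pupil_mm[post] <- sim$samples$l_pupil_mm[post] + 0.2
  sim$samples$r_pupil_mm[post] <- sim$samples$r_pupil_mm[post] + 0.2
  trial <- data.frame(participant = 1L, trial = 1L,
                      condition = tl$condition, block = tl$block,
                      sign_onset_ms = 0, op1_onset_ms = 2000,
                      op2_onset_ms = 2300, calc_onset_ms = 2600,
                      distractor_onset_ms = tl$distractor_onset_ms,
                      distractor_position = 0,
                      response_time_ms = tl$response_time_ms)
  no_ev <- data.frame(participant = integer(0), trial = integer(0),
                      type = character(0), onset_ms = numeric(0),
                      offset_ms = numeric(0))
  no_bl <- data.frame(participant = integer(0), trial = integer(0),
                      type = character(0), onset_ms = numeric(0),
                      offset_ms = numeric(0), onset_idx = integer(0),
                      offset_idx = integer(0))
  ep <- distractor_locked_epochs(sim$samples, NULL, no_ev, no_bl, trial,
                                 sim_config = cfg)
  expect_equal(sort(unique(ep$bin_start_ms)), c(-500, 0, 500))
  pup <- ep[ep$parameter == "pupil_diameter", ]
  expect_equal(pup$corrected[pup$bin_start_ms == 0], 0.2, tolerance = 0.01)
  expect_equal(pup$corrected[pup$bin_start_ms == -500], 0, tolerance = 0.01)

  # trials without distractor are rejected
  trial$distractor_onset_ms <- NA_real_
  expect_error(distractor_locked_epochs(sim$samples, NULL, no_ev, no_bl,
                                        trial, sim_config = cfg),
               "no trial has a distractor")
})

test_that("parameter correlations form a symmetric unit-diagonal matrix", {
  cfg <- simulation_config(seed = 55)
  ses <- simulate_session(cfg, 1)
  prep <- preprocess_samples(ses$samples, sim_config = cfg)
  ev <- detect_saccades(ses$samples, prep$mask, detection_config(), cfg)
  b <- bin_parameters(ses$samples, prep$mask, ev, prep$blinks, ses$trials,
                      sim_config = cfg)
  r <- parameter_correlations(b)
  expect_equal(dim(r), c(6, 6))
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 6))
  # duplicated column correlates perfectly
  b2 <- b
  b2$corrected[b2$parameter == "pupil_diameter"] <-
    b2$corrected[b2$parameter == "fixation_disparity"]
  r2 <- parameter_correlations(b2)
  expect_equal(unname(r2["pupil_diameter", "fixation_disparity"]), 1)
})

test_that("correlations recover a constructed coefficient", {
  set.seed(56)
  n <- 10000
  z <- rnorm(n)
  x <- z; y <- 0.5 * z + sqrt(1 - 0.25) * rnorm(n)  # population r = 0.5
  b <- rbind(
    data.frame(participant = 1L, trial = seq_len(n), bin = "b1",
               parameter = "pupil_diameter", corrected = x),
    data.frame(participant = 1L, trial = seq_len(n), bin = "b1",
               parameter = "fixation_disparity", corrected = y))
  b$condition <- "mult_no_distractor"; b$block <- "no_distractor"
  b$bin_start_ms <- 0; b$raw <- b$corrected; b$baseline <- 0
  r <- parameter_correlations(b)
  expect_equal(unname(r["pupil_diameter", "fixation_disparity"]),
               cor(x, y), tolerance = 1e-12)
  expect_equal(unname(r["pupil_diameter", "fixation_disparity"]), 0.5,
               tolerance = 0.03)
})
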