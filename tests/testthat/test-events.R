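# Velocity computation, median-based thresholds, event detection, binocular
# merging and classification.

test_that("5-point differentiator is exact on constant and linear signals", {
  dt <- 1 / 250
  v0 <- compute_velocity(rep(1, 50), rep(2, 50), dt)
  expect_true(all(v0$vx[3:48] == 0))
  expect_true(all(is.na(v0$vx[c(1, 2, 49, 50)])))

  c_per_sample <- 0.01
  x <- c_per_sample * (1:100)
  v <- compute_velocity(x, rep(0, 100), dt)
  expect_equal(v$vx[3:98], rep(c_per_sample / dt, 96))
})

test_that("a single-sample spike yields symmetric excursions summing to zero", {
  dt <- 1 / 250
  x <- rep(0, 41); x[21] <- 1
  v <- compute_velocity(x, rep(0, 41), dt)
  expect_equal(sum(v$vx[3:39]), 0)
  expect_equal(v$vx[19], -v$vx[23])  # antisymmetric around the spike
})

test_that("velocity is undefined next to masked gaps", {
  dt <- 1 / 250
  x <- seq(0, 1, length.out = 30)
  valid <- rep(TRUE, 30); valid[15] <- FALSE
  v <- compute_velocity(x, x, dt, valid)
  expect_true(all(is.na(v$vx[13:17])))  # any window touching sample 15
  expect_false(anyNA(v$vx[3:12]))
  v_short <- compute_velocity(1:4 / 10, rep(0, 4), dt)
  expect_true(all(is.na(v_short$vx)))
})

test_that("median-based threshold matches a direct computation and scales with lambda", {
  vx <- c(-2, -1, -1, 0, 0, 1, 1, 2, 5, -5)
  vy <- c(1, -1, 2, -2, 0, 0, 1, -1, 3, -3)
  vel <- data.frame(vx = vx, vy = vy)
  sx <- sqrt(median(vx^2) - median(vx)^2)
  sy <- sqrt(median(vy^2) - median(vy)^2)
  th <- velocity_threshold(vel, lambda = 6)
  expect_equal(unname(th), c(6 * sx, 6 * sy))
  expect_equal(unname(velocity_threshold(vel, lambda = 12)), 2 * unname(th))
  expect_error(velocity_threshold(data.frame(vx = rep(1, 10), vy = rep(1, 10))),
               "degenerate")
})

test_that("median-based sigma is smaller for heavy-tailed noise of equal SD", {
  set.seed(6)
  n <- 20000
  gauss <- rnorm(n)
  heavy <- rt(n, df = 3); heavy <- heavy / sd(heavy)  # unit SD, heavy tails
  sig <- function(v) sqrt(median(v^2) - median(v)^2)
  expect_lt(sig(heavy), sig(gauss))
})

test_that("minimum duration of two samples is enforced", {
  vx <- rep(0, 20); vx[10] <- 20           # 1-sample excursion
  vel <- data.frame(vx = vx, vy = 0)
  th <- c(eta_x = 10, eta_y = 10)
  pos <- rep(0, 20); tm <- (0:19) * 4
  expect_equal(nrow(detect_monocular(vel, th, pos, pos, tm,
                                     detection_config(min_duration_samples = 2))), 0)
  expect_equal(nrow(detect_monocular(vel, th, pos, pos, tm,
                                     detection_config(min_duration_samples = 1))), 1)
  vel$vx[11] <- 20                          # 2-sample run passes
  ev <- detect_monocular(vel, th, pos, pos, tm, detection_config())
  expect_equal(nrow(ev), 1)
  expect_equal(ev$peak_vel_deg_s, 20)
  # exactly-at-threshold samples are sub-threshold (strict inequality)
  vel2 <- data.frame(vx = rep(10, 20), vy = 0)
  expect_equal(nrow(detect_monocular(vel2, th, pos, pos, tm,
                                     detection_config())), 0)
})

test_that("an injected 2-degree saccade is recovered with accurate amplitude", {
  s <- make_trace(n = 500, amp = 2, onset = 200, dur = 8, noise_sd = 0.01,
                  seed = 12)
  ev <- detect_saccades(s, NULL)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$amplitude_deg - 2) / 2, 0.05)
  expect_equal(ev$type, "saccade")

  # drift-only trace: no events
  s0 <- make_trace(n = 500, amp = 0, noise_sd = 0.01, seed = 13)
  expect_equal(nrow(detect_saccades(s0, NULL)), 0)
})

test_that("binocular merging requires a one-sample overlap and unions intervals", {
  ev <- function(on, off) data.frame(
    onset_idx = on, offset_idx = off, onset_ms = on * 4, offset_ms = off * 4,
    amplitude_deg = 1, peak_vel_deg_s = 50)
  cfg <- detection_config()
  # identical events merge to the same interval
  m <- merge_binocular(ev(10, 20), ev(10, 20), cfg)
  expect_equal(c(m$onset_idx, m$offset_idx), c(10, 20))
  # one-sample overlap retained, interval is the union
  m2 <- merge_binocular(ev(10, 20), ev(20, 25), cfg)
  expect_equal(nrow(m2), 1)
  expect_equal(c(m2$onset_idx, m2$offset_idx), c(10, 25))
  # disjoint events dropped
  expect_equal(nrow(merge_binocular(ev(10, 20), ev(22, 30), cfg)), 0)
  # amplitude is the mean of the two eyes
  l <- ev(10, 20); l$amplitude_deg <- 1
  r <- ev(12, 22); r$amplitude_deg <- 2
  expect_equal(merge_binocular(l, r, cfg)$amplitude_deg, 1.5)
})

test_that("classification partitions events at the 1.5 degree boundary", {
  ev <- data.frame(amplitude_deg = c(1.5, 1.51, 0.1, 3))
  cl <- classify_events(ev, detection_config())
  expect_equal(cl$type, c("microsaccade", "saccade", "microsaccade", "saccade"))
  set.seed(31)
  amps <- data.frame(amplitude_deg = rlnorm(100, 0, 1))
  cl2 <- classify_events(amps, detection_config())
  expect_equal(sum(cl2$type == "microsaccade") + sum(cl2$type == "saccade"), 100)
})

test_that("vectorized detection equals the brute-force criterion scan", {
  cfg <- simulation_config(seed = 1)
  dcfg <- detection_config()
  for (seed in 1:20) {
    sim <- simulate_trial(cfg, trial_timeline(rt_ms = 3000), seed = seed)
    s <- sim$samples
    x <- px_to_deg(s$lx_px - 960, cfg); y <- px_to_deg(s$ly_px - 540, cfg)
    vel <- compute_velocity(x, y, 1 / cfg$sampling_rate)
    th <- velocity_threshold(vel, dcfg$lambda)
    fast <- detect_monocular(vel, th, x, y, s$time_ms, dcfg)
    slow <- brute_force_detect(vel, th, x, y, s$time_ms,
                               dcfg$min_duration_samples)
    expect_equal(fast, slow, ignore_attr = TRUE)
  }
})

test_that("raising lambda never adds an event", {
  cfg <- simulation_config(seed = 2)
  sim <- simulate_trial(cfg, trial_timeline(rt_ms = 4000), seed = 40)
  counts <- vapply(c(3, 4, 5, 6, 8, 10, 14), function(lam)
    nrow(detect_saccades(sim$samples, NULL,
                         detection_config(lambda = lam), cfg)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("events never overlap masked samples", {
  cfg <- simulation_config(blink_rate = 1.2, seed = 77)
  ses <- simulate_session(cfg, 1)
  prep <- preprocess_samples(ses$samples)
  ev <- detect_saccades(ses$samples, prep$mask, detection_config(), cfg)
  valid <- !(prep$mask$blink | prep$mask$blink_pad |
               prep$mask$extreme_value | prep$mask$sd_outlier)
  for (i in seq_len(nrow(ev))) {
    idx <- which(ses$samples$participant == ev$participant[i] &
                   ses$samples$trial == ev$trial[i] &
                   ses$samples$time_ms >= ev$onset_ms[i] &
                   ses$samples$time_ms <= ev$offset_ms[i])
    expect_true(all(valid[idx]))
  }
})
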