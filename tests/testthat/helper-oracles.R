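# Independent oracles used across the suite.  They deliberately use the
# slowest, most literal formulation of each computation so that they stay
# independent of the vectorized implementation paths they check.

# sample-by-sample scan of the elliptic velocity criterion
brute_force_detect <- function(vel, eta, x, y, time_ms, min_dur = 2) {
  n <- nrow(vel)
  supra <- logical(n)
  for (i in seq_len(n)) {
    vx <- vel$vx[i]; vy <- vel$vy[i]
    supra[i] <- !is.na(vx) && !is.na(vy) &&
      (vx / eta[["eta_x"]])^2 + (vy / eta[["eta_y"]])^2 > 1
  }
  events <- list()
  i <- 1
  while (i <= n) {
    if (supra[i]) {
      j <- i
      while (j < n && supra[j + 1]) j <- j + 1
      if (j - i + 1 >= min_dur) {
        speed <- max(sqrt(vel$vx[i:j]^2 + vel$vy[i:j]^2))
        events[[length(events) + 1]] <- data.frame(
          onset_idx = i, offset_idx = j,
          onset_ms = time_ms[i], offset_ms = time_ms[j],
          amplitude_deg = sqrt((x[j] - x[i])^2 + (y[j] - y[i])^2),
          peak_vel_deg_s = speed)
      }
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(events))
    return(data.frame(onset_idx = integer(0), offset_idx = integer(0),
                      onset_ms = numeric(0), offset_ms = numeric(0),
                      amplitude_deg = numeric(0), peak_vel_deg_s = numeric(0)))
  do.call(rbind, events)
}

# fine-grid quadrature oracle for the JZS Bayes factor: transform
# g = u / (1 - u) and apply the composite trapezoid rule on a dense grid
jzs_bf_oracle <- function(t, n, r = sqrt(2) / 2, n_grid = 200001) {
  nu <- n - 1
  u <- seq(1e-9, 1 - 1e-9, length.out = n_grid)
  g <- u / (1 - u)
  jac <- 1 / (1 - u)^2
  a <- 1 + n * g * r^2
  f <- a^(-1/2) * (1 + t^2 / (a * nu))^(-(nu + 1) / 2) *
    (2 * pi)^(-1/2) * g^(-3/2) * exp(-1 / (2 * g)) * jac
  den <- sum((f[-1] + f[-n_grid]) / 2 * diff(u))
  num <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  den / num
}

# noise-free synthetic trace with one injected raised-cosine saccade,
# returned in the interchange sample dialect (both eyes identical)
make_trace <- function(n = 500, amp = 2, onset = 200, dur = 8,
                       noise_sd = 0.02, seed = 1, fs = 250,
                       sim_config = simulation_config()) {
  set.seed(seed)
  x <- rnorm(n, 0, noise_sd)
  y <- rnorm(n, 0, noise_sd)
  if (amp > 0) {
    t <- seq(0, 1, length.out = dur)
    prof <- amp * (1 - cos(pi * t)) / 2
    idx <- onset:(onset + dur - 1)
    x[idx] <- x[idx] + prof
    x[(onset + dur):n] <- x[(onset + dur):n] + amp
  }
  cx <- sim_config$screen_center[1]; cy <- sim_config$screen_center[2]
  data.frame(participant = 1L, trial = 1L,
             time_ms = as.integer(seq(0, by = 1000 / fs, length.out = n)),
             lx_px = cx + deg_to_px(x, sim_config),
             ly_px = cy + deg_to_px(y, sim_config),
             rx_px = cx + deg_to_px(x, sim_config),
             ry_px = cy + deg_to_px(y, sim_config),
             l_pupil_mm = 4, r_pupil_mm = 4)
}

# deg_to_px / px_to_deg are internal; re-derive here so helpers do not
# depend on unexported functions
deg_to_px <- function(deg, config) deg * config$px_per_deg
px_to_deg <- function(px, config) px / config$px_per_deg
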