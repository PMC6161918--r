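# Configuration objects for every pipeline stage.  Each constructor returns a
# validated, classed list; defaults reproduce the study settings (250 Hz SMI
# recording, 1920x1080 display at 70 cm, lambda = 6 detection, 500 ms bins).

stop_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

check_finite_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  stop_if(!is.numeric(x) || any(!is.finite(x)),
          sprintf("configuration error: '%s' must be finite numeric", name))
  if (positive) stop_if(any(x <= 0), sprintf("configuration error: '%s' must be > 0", name))
  if (nonneg) stop_if(any(x < 0), sprintf("configuration error: '%s' must be >= 0", name))
  x
}

#' Simulation configuration
#'
#' Parameters of the synthetic binocular recording generator.  Display
#' geometry follows the study apparatus (24-inch 1920 x 1080 screen viewed at
#' 70 cm; 45 px per degree of visual angle); oculomotor process parameters
#' are literature-plausible defaults, not fitted values.
#'
#' @param sampling_rate samples per second (Hz).
#' @param px_per_deg pixels per degree of visual angle.
#' @param screen_size width, height in pixels.
#' @param screen_center screen center in pixels.
#' @param screen_width_mm physical screen width (mm), sets the px-to-mm pitch.
#' @param n_participants number of simulated participants (session level).
#' @param n_mult_per_block multiplication trials per block.
#' @param n_passive_per_block passive-viewing trials per block.
#' @param drift_sd fixational drift random-walk step (deg per sample).
#' @param tremor_sd white positional tremor (deg), common to both eyes.
#' @param microsaccade_rate Poisson rate of injected microsaccades (Hz).
#' @param saccade_rate_idc Poisson rate of larger saccades during the
#'   calculation period of multiplication trials (Hz).
#' @param blink_rate Poisson blink rate (Hz).
#' @param blink_duration_ms blink duration range (ms), uniform.
#' @param main_sequence_slope peak velocity per unit amplitude ((deg/s)/deg);
#'   injected events satisfy peak_velocity = slope * amplitude exactly.
#' @param amp_micro_meanlog,amp_micro_sdlog log-normal amplitude parameters
#'   for microsaccades (truncated at the 1.5 deg class boundary).
#' @param amp_macro_meanlog,amp_macro_sdlog log-normal amplitude parameters
#'   for larger saccades.
#' @param vergence_sd white fixation-disparity noise (mm on screen).
#' @param pupil_baseline resting pupil diameter (mm).
#' @param pupil_task_gain task-evoked dilation amplitude (mm), reached after
#'   a 1 s linear ramp from calculation onset in multiplication trials.
#' @param pupil_noise_sd white pupil measurement noise per eye (mm).
#' @param accuracy,forgot_rate probabilities of a correct / forgotten
#'   response in multiplication trials (incorrect takes the remainder).
#' @param rt_meanlog,rt_sdlog log-normal response-time parameters (ms) for
#'   the calculation period.
#' @param seed integer seed; identical seeds give identical output.
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(sampling_rate = 250,
                              px_per_deg = 45,
                              screen_size = c(1920, 1080),
                              screen_center = c(960, 540),
                              screen_width_mm = 531,
                              n_participants = 36,
                              n_mult_per_block = 18,
                              n_passive_per_block = 4,
                              drift_sd = 0.002,
                              tremor_sd = 0.005,
                              microsaccade_rate = 1.2,
                              saccade_rate_idc = 0.8,
                              blink_rate = 0.25,
                              blink_duration_ms = c(100, 300),
                              main_sequence_slope = 65,
                              amp_micro_meanlog = log(0.5), amp_micro_sdlog = 0.45,
                              amp_macro_meanlog = log(3.0), amp_macro_sdlog = 0.35,
                              vergence_sd = 0.3,
                              pupil_baseline = 4.0,
                              pupil_task_gain = 0.3,
                              pupil_noise_sd = 0.02,
                              accuracy = 0.85,
                              forgot_rate = 0.07,
                              rt_meanlog = log(2500), rt_sdlog = 0.30,
                              seed = 1L) {
  check_finite_num(sampling_rate, "sampling_rate", positive = TRUE)
  check_finite_num(px_per_deg, "px_per_deg", positive = TRUE)
  check_finite_num(c(drift_sd, tremor_sd, vergence_sd, pupil_noise_sd),
                   "noise sds", nonneg = TRUE)
  check_finite_num(c(microsaccade_rate, saccade_rate_idc, blink_rate),
                   "event rates", nonneg = TRUE)
  check_finite_num(blink_duration_ms, "blink_duration_ms", positive = TRUE)
  stop_if(blink_duration_ms[1] > blink_duration_ms[2],
          "configuration error: blink_duration_ms range must be ordered")
  check_finite_num(main_sequence_slope, "main_sequence_slope", positive = TRUE)
  check_finite_num(pupil_baseline, "pupil_baseline", positive = TRUE)
  stop_if(accuracy + forgot_rate > 1,
          "configuration error: accuracy + forgot_rate must be <= 1")
  structure(as.list(environment()), class = "sim_config")
}

#' Sample-exclusion configuration
#'
#' Thresholds for artifact exclusion: blink padding, physiological ranges for
#' pupil diameter and fixation disparity, and the per-participant
#' standard-deviation rule.
#'
#' @param blink_pad_samples samples flagged before and after each blink.
#' @param pupil_min,pupil_max admissible pupil diameter (mm).
#' @param disparity_max admissible absolute fixation disparity (mm); the
#'   default is the mean inter-pupil distance.
#' @param sd_multiplier per-participant outlier cut in standard deviations.
#' @param blink_min_run minimum run of invalid-pupil samples counted as a
#'   blink (shorter dropouts are treated as isolated missing samples).
#' @return an object of class `exclusion_config`.
#' @export
exclusion_config <- function(blink_pad_samples = 2,
                             pupil_min = 1.8, pupil_max = 15,
                             disparity_max = 60,
                             sd_multiplier = 3,
                             blink_min_run = 3) {
  check_finite_num(blink_pad_samples, "blink_pad_samples", nonneg = TRUE)
  check_finite_num(c(pupil_min, pupil_max), "pupil range", positive = TRUE)
  stop_if(pupil_min >= pupil_max, "configuration error: pupil_min must be < pupil_max")
  check_finite_num(disparity_max, "disparity_max", positive = TRUE)
  check_finite_num(sd_multiplier, "sd_multiplier", positive = TRUE)
  check_finite_num(blink_min_run, "blink_min_run", positive = TRUE)
  structure(as.list(environment()), class = "exclusion_config")
}

#' Saccade-detection configuration
#'
#' Settings of the velocity-threshold (Engbert-Kliegl style) detector:
#' median-based elliptic velocity threshold with multiplier `lambda`, minimum
#' event duration, binocular overlap requirement and the amplitude boundary
#' separating microsaccades from saccades.
#'
#' @param lambda velocity-threshold multiplier (unitless).
#' @param min_duration_samples minimum supra-threshold run length.
#' @param binocular_min_overlap minimum left/right temporal overlap (samples).
#' @param micro_amplitude_max amplitude at or below which an event is
#'   classified as a microsaccade (deg).
#' @param velocity_window moving-average differentiator span (samples).
#' @return an object of class `detection_config`.
#' @export
detection_config <- function(lambda = 6,
                             min_duration_samples = 2,
                             binocular_min_overlap = 1,
                             micro_amplitude_max = 1.5,
                             velocity_window = 5) {
  check_finite_num(lambda, "lambda", positive = TRUE)
  stop_if(min_duration_samples < 1, "configuration error: min_duration_samples must be >= 1")
  check_finite_num(binocular_min_overlap, "binocular_min_overlap", positive = TRUE)
  check_finite_num(micro_amplitude_max, "micro_amplitude_max", positive = TRUE)
  stop_if(velocity_window != 5, "only the 5-point differentiator is supported")
  structure(as.list(environment()), class = "detection_config")
}

#' Binning configuration
#'
#' The analysis window: four contiguous 500 ms bins relative to calculation
#' onset, the first covering operand presentation (starting 100 ms after
#' first-operand onset so all bins are equally sized), plus the gaze-at-center
#' radius and the count-to-rate multiplier.
#'
#' @param bin_width_ms bin width (ms).
#' @param bin_starts_ms bin start times relative to calculation onset (ms).
#' @param center_radius_deg radius of the central region (deg).
#' @param rate_multiplier converts an onset count per bin to Hz (2 for
#'   500 ms bins).
#' @return an object of class `binning_config`.
#' @export
binning_config <- function(bin_width_ms = 500,
                           bin_starts_ms = c(-500, 0, 500, 1000),
                           center_radius_deg = 1.0,
                           rate_multiplier = 2) {
  check_finite_num(bin_width_ms, "bin_width_ms", positive = TRUE)
  stop_if(any(diff(bin_starts_ms) != bin_width_ms),
          "configuration error: bins must be contiguous and equal width")
  check_finite_num(center_radius_deg, "center_radius_deg", positive = TRUE)
  check_finite_num(rate_multiplier, "rate_multiplier", positive = TRUE)
  structure(as.list(environment()), class = "binning_config")
}

#' Baseline-correction configuration
#'
#' Trial-wise subtractive baselines: the median of the 500 ms window
#' preceding first-operand onset for pupil diameter and fixation disparity,
#' and the mean rate (or percentage) over the full 2 s presentation of the
#' multiplication sign for the event rates and gaze at center.
#'
#' @param continuous_window_ms width of the pre-operand window (ms).
#' @param rate_window_ms width of the sign-presentation window (ms).
#' @return an object of class `baseline_config`.
#' @export
baseline_config <- function(continuous_window_ms = 500,
                            rate_window_ms = 2000) {
  check_finite_num(continuous_window_ms, "continuous_window_ms", positive = TRUE)
  check_finite_num(rate_window_ms, "rate_window_ms", positive = TRUE)
  structure(as.list(environment()), class = "baseline_config")
}

#' Bayes-factor configuration
#'
#' @param prior_scale Cauchy prior scale on standardized effect size
#'   (default 0.707, the conventional "medium" setting sqrt(2)/2).
#' @param rel_tol relative tolerance of the numerical integration.
#' @return an object of class `bayes_config`.
#' @export
bayes_config <- function(prior_scale = sqrt(2) / 2, rel_tol = 1e-6) {
  check_finite_num(prior_scale, "prior_scale", positive = TRUE)
  check_finite_num(rel_tol, "rel_tol", positive = TRUE)
  structure(list(prior_scale = prior_scale, rel_tol = rel_tol),
            class = "bayes_config")
}

#' Full pipeline configuration
#'
#' Bundles the per-stage configurations, the master seed and the output
#' directory for [run_pipeline()].
#'
#' @param sim [simulation_config()].
#' @param exclusion [exclusion_config()].
#' @param detection [detection_config()].
#' @param binning [binning_config()].
#' @param baseline [baseline_config()].
#' @param bayes [bayes_config()].
#' @param seed master seed (overrides `sim$seed`).
#' @param out_dir output directory.
#' @param verbose print per-stage progress.
#' @return an object of class `run_config`.
#' @export
run_config <- function(sim = simulation_config(),
                       exclusion = exclusion_config(),
                       detection = detection_config(),
                       binning = binning_config(),
                       baseline = baseline_config(),
                       bayes = bayes_config(),
                       seed = sim$seed,
                       out_dir = "idcgaze-results",
                       verbose = FALSE) {
  stopifnot(inherits(sim, "sim_config"), inherits(exclusion, "exclusion_config"),
            inherits(detection, "detection_config"), inherits(binning, "binning_config"),
            inherits(baseline, "baseline_config"), inherits(bayes, "bayes_config"))
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, exclusion = exclusion, detection = detection,
                 binning = binning, baseline = baseline, bayes = bayes,
                 seed = as.integer(seed), out_dir = out_dir, verbose = verbose),
            class = "run_config")
}

# geometry helpers ------------------------------------------------------------

mm_per_px <- function(config) config$screen_width_mm / config$screen_size[1]

px_to_deg <- function(px, config) px / config$px_per_deg
deg_to_px <- function(deg, config) deg * config$px_per_deg
px_to_mm <- function(px, config) px * mm_per_px(config)
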