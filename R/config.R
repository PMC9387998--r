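#' Per-condition generative parameters for the cohort simulator
#'
#' One row per disease group x response type, giving the location of the
#' shifted-gamma latency distribution, the mean damping ratio and the mean
#' saccade gain (amplitude plateau, degrees). Defaults encode the effect
#' structure this package's analyses are designed to detect in a
#' Parkinson's-disease (PD) versus healthy-control cohort:
#'
#' * latencies increase from prosaccades (PS) through antisaccade (AS)
#'   directional errors to correct antisaccades, with PD slower than
#'   controls (PS +19 ms, correct AS +45 ms; AS errors sit ~14 ms above PS,
#'   consistent with their interpretation as failed inhibition of a
#'   reflexive prosaccade);
#' * damping ratios increase from PS to correct AS (+0.09 in PD, +0.06 in
#'   controls), with AS errors damped like prosaccades in PD but closer to
#'   antisaccades in controls;
#' * correct antisaccades overshoot the 10 degree target eccentricity in
#'   controls (mean 12.3 degrees) but not in PD (10.5 degrees) — a relative
#'   hypometria.
#'
#' @return a tibble with columns `group`, `response_type`,
#'   `latency_mean_ms`, `latency_shift_ms`, `latency_shape`, `sigma_mean`,
#'   `gain_mean_deg`.
#' @export
default_condition_params <- function() {
  tibble::tribble(
    ~group,    ~response_type, ~latency_mean_ms, ~latency_shift_ms, ~latency_shape, ~sigma_mean, ~gain_mean_deg,
    "control", "ps_correct",   200.0,            100,               9,              1.00,        10.0,
    "control", "as_error",     214.6,            100,               9,              1.03,        10.0,
    "control", "as_correct",   320.9,            140,               9,              1.06,        12.31,
    "pd",      "ps_correct",   219.0,            100,               9,              1.05,        10.0,
    "pd",      "as_error",     232.9,            100,               9,              1.07,        10.0,
    "pd",      "as_correct",   366.1,            140,               9,              1.14,        10.52
  )
}

#' Simulation configuration
#'
#' Assembles and validates the full parameter set for [simulate_cohort()].
#' Defaults describe a step-paradigm saccadometry session: fixation target
#' at 0 degrees, peripheral targets at +/-10 degrees, a 1.0-2.0 s
#' truncated-exponential foreperiod, eye position sampled every 5 ms from
#' 25 ms before saccade initiation to 20 ms after the velocity criterion
#' terminates the saccade, and a cohort of 25 PD patients and 26 controls
#' performing prosaccade and antisaccade blocks.
#'
#' Between-participant heterogeneity enters as Gaussian random intercepts
#' (per participant) on latency, damping ratio, natural frequency and gain;
#' within-participant trial-to-trial variation uses a shifted-gamma law for
#' latency (right-skewed, positive support) and zero-truncated normals for
#' damping ratio, natural frequency and gain.
#'
#' @param n_pd,n_control number of participants per group.
#' @param trials_per_task trials per participant in each of the two tasks.
#' @param dt_ms sampling interval of the position trace, ms.
#' @param eccentricity_deg peripheral-target eccentricity, degrees.
#' @param foreperiod_range_s length-2 numeric, fixation foreperiod bounds (s).
#' @param foreperiod_rate rate of the truncated exponential foreperiod.
#' @param condition_params tibble as returned by
#'   [default_condition_params()].
#' @param as_error_rate named numeric, probability that an antisaccade trial
#'   is answered with a reflexive prosaccade, per group.
#' @param omega0_mean_rad_s mean natural frequency (rad/s); with the default
#'   damping near 1 this makes a 10 degree saccade last roughly 40-60 ms.
#' @param between_sd named list of between-participant SDs
#'   (`latency_ms`, `sigma`, `omega0`, `gain_deg`).
#' @param within_sd named list of within-participant SDs
#'   (`sigma`, `omega0`, `gain_deg`); latency spread comes from the gamma
#'   shape.
#' @param noise_sd_deg SD of additive Gaussian measurement noise on each
#'   position sample, degrees.
#' @param velocity_threshold_deg_s velocity criterion defining saccade
#'   termination in the recording window, deg/s.
#' @param trajectories if `FALSE`, generate trial metadata and per-saccade
#'   summaries only (no sampled position traces); useful when only the
#'   metric-level structure is needed.
#' @return an object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_pd = 25,
                              n_control = 26,
                              trials_per_task = 100,
                              dt_ms = 5,
                              eccentricity_deg = 10,
                              foreperiod_range_s = c(1.0, 2.0),
                              foreperiod_rate = 1.0,
                              condition_params = default_condition_params(),
                              as_error_rate = c(pd = 0.25, control = 0.20),
                              omega0_mean_rad_s = 60,
                              between_sd = list(latency_ms = 20, sigma = 0.08,
                                                omega0 = 5, gain_deg = 0.8),
                              within_sd = list(sigma = 0.18, omega0 = 8,
                                               gain_deg = 1.5),
                              noise_sd_deg = 0.15,
                              velocity_threshold_deg_s = 5,
                              trajectories = TRUE) {
  cfg <- list(
    n_pd = n_pd, n_control = n_control, trials_per_task = trials_per_task,
    dt_ms = dt_ms, eccentricity_deg = eccentricity_deg,
    foreperiod_range_s = foreperiod_range_s,
    foreperiod_rate = foreperiod_rate,
    condition_params = as_tibble(condition_params),
    as_error_rate = as_error_rate,
    omega0_mean_rad_s = omega0_mean_rad_s,
    between_sd = between_sd, within_sd = within_sd,
    noise_sd_deg = noise_sd_deg,
    velocity_threshold_deg_s = velocity_threshold_deg_s,
    trajectories = isTRUE(trajectories)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  counts <- c(cfg$n_pd, cfg$n_control, cfg$trials_per_task)
  if (any(!is.finite(counts)) || any(counts <= 0) || any(counts != round(counts)))
    abort("participant and trial counts must be positive integers.",
          class = "saccadom_config_error")
  if (cfg$dt_ms <= 0)
    abort("`dt_ms` must be positive.", class = "saccadom_config_error")
  fr <- cfg$foreperiod_range_s
  if (length(fr) != 2 || fr[1] >= fr[2])
    abort("`foreperiod_range_s` must be an increasing pair.",
          class = "saccadom_config_error")
  if (cfg$foreperiod_rate <= 0)
    abort("`foreperiod_rate` must be positive.", class = "saccadom_config_error")
  p <- cfg$condition_params
  need <- c("group", "response_type", "latency_mean_ms", "latency_shift_ms",
            "latency_shape", "sigma_mean", "gain_mean_deg")
  if (!all(need %in% names(p)))
    abort(paste("`condition_params` must have columns:",
                paste(need, collapse = ", ")), class = "saccadom_config_error")
  if (any(p$sigma_mean <= 0))
    abort("damping-ratio means must be positive.", class = "saccadom_config_error")
  if (cfg$omega0_mean_rad_s <= 0)
    abort("`omega0_mean_rad_s` must be positive.", class = "saccadom_config_error")
  er <- cfg$as_error_rate
  if (!all(c("pd", "control") %in% names(er)) || any(er < 0) || any(er > 1))
    abort("`as_error_rate` must contain pd and control probabilities in [0, 1].",
          class = "saccadom_config_error")
  if (cfg$noise_sd_deg < 0)
    abort("`noise_sd_deg` must be non-negative.", class = "saccadom_config_error")
  invisible(cfg)
}

#' Quality-control thresholds for recorded saccades
#'
#' Saccades are excluded as likely recording errors when latency is below
#' `latency_min_ms` or above `latency_max_ms`, amplitude exceeds
#' `amplitude_max_deg`, or peak velocity exceeds
#' `peak_velocity_max_deg_s` (all strict inequalities). `sigma_se_max`
#' bounds the standard error of the fitted damping ratio; less precise fits
#' are excluded from damping analyses. `velocity_threshold_deg_s` defines
#' the saccade as the period during which speed exceeds the threshold.
#'
#' @param latency_min_ms,latency_max_ms latency acceptance window, ms.
#' @param amplitude_max_deg maximum plausible amplitude, degrees.
#' @param peak_velocity_max_deg_s maximum plausible peak velocity, deg/s.
#' @param velocity_threshold_deg_s saccade detection threshold, deg/s.
#' @param sigma_se_max maximum admissible standard error of the fitted
#'   damping ratio.
#' @return an object of class `qc_config`.
#' @export
qc_config <- function(latency_min_ms = 100,
                      latency_max_ms = 1000,
                      amplitude_max_deg = 40,
                      peak_velocity_max_deg_s = 1000,
                      velocity_threshold_deg_s = 5,
                      sigma_se_max = 0.5) {
  vals <- c(latency_min_ms, latency_max_ms, amplitude_max_deg,
            peak_velocity_max_deg_s, velocity_threshold_deg_s, sigma_se_max)
  if (any(!is.finite(vals)) || any(vals <= 0))
    abort("all QC thresholds must be positive and finite.",
          class = "saccadom_config_error")
  if (latency_min_ms >= latency_max_ms)
    abort("`latency_min_ms` must be below `latency_max_ms`.",
          class = "saccadom_config_error")
  structure(list(latency_min_ms = latency_min_ms,
                 latency_max_ms = latency_max_ms,
                 amplitude_max_deg = amplitude_max_deg,
                 peak_velocity_max_deg_s = peak_velocity_max_deg_s,
                 velocity_threshold_deg_s = velocity_threshold_deg_s,
                 sigma_se_max = sigma_se_max),
            class = "qc_config")
}
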