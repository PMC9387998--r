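#' Draw foreperiods from a truncated exponential distribution
#'
#' Fixation foreperiods are drawn from an exponential density restricted to
#' `range_s` (default 1.0-2.0 s), by inverse-CDF sampling. As `rate`
#' approaches 0 the distribution flattens to uniform on the interval.
#'
#' @param n number of draws.
#' @param range_s length-2 increasing numeric, interval bounds (seconds).
#' @param rate exponential rate parameter (> 0).
#' @param seed optional RNG seed.
#' @return numeric vector of `n` foreperiods in `[range_s[1], range_s[2]]`.
#' @export
draw_foreperiod <- function(n, range_s = c(1.0, 2.0), rate = 1.0, seed = NULL) {
  if (length(range_s) != 2 || range_s[1] >= range_s[2])
    abort("`range_s` must be an increasing pair.", class = "saccadom_domain_error")
  if (rate <= 0) abort("`rate` must be positive.", class = "saccadom_domain_error")
  with_seed_(seed, {
    u <- runif(n)
    lo <- range_s[1]; hi <- range_s[2]
    # inverse CDF of exp(rate) truncated to [lo, hi]
    flo <- -expm1(-rate * lo)
    fhi <- -expm1(-rate * hi)
    -log1p(-(flo + u * (fhi - flo))) / rate
  })
}

# Zero-truncated (lower-bounded) normal draws by inverse CDF.
rtnorm <- function(n, mean, sd, lower) {
  plo <- pnorm(lower, mean, sd)
  qnorm(plo + runif(n) * (1 - plo), mean, sd)
}

#' Simulate one saccade trajectory
#'
#' Forward model of the second-order step response: samples
#' \eqn{\phi(t) = A\,g_{\sigma,\omega_0}(t) + \epsilon_t} at times
#' `0, dt, 2dt, ...` up to `duration_ms`, with iid Gaussian measurement
#' noise. With `noise_sd = 0` the samples equal [step_response()] exactly.
#'
#' @param A gain (degrees; sign encodes direction).
#' @param sigma damping ratio (> 0).
#' @param omega0 natural frequency, rad/s (> 0).
#' @param dt_ms sampling interval, ms.
#' @param duration_ms total sampled duration, ms.
#' @param noise_sd SD of additive Gaussian noise, degrees.
#' @param seed optional RNG seed.
#' @return tibble with columns `t_ms`, `position_deg`.
#' @examples
#' tr <- simulate_trajectory(10, 0.7, 60, duration_ms = 300)
#' tail(tr$position_deg, 1)  # ~10: the step-response plateau
#' @export
simulate_trajectory <- function(A, sigma, omega0, dt_ms = 5, duration_ms = 300,
                                noise_sd = 0, seed = NULL) {
  check_second_order_params(sigma, omega0)
  if (dt_ms <= 0) abort("`dt_ms` must be positive.", class = "saccadom_domain_error")
  t_ms <- seq(0, duration_ms, by = dt_ms)
  pos <- step_response(t_ms, A, sigma, omega0)
  if (noise_sd > 0)
    pos <- pos + with_seed_(seed, rnorm(length(pos), 0, noise_sd))
  tibble(t_ms = t_ms, position_deg = pos)
}

#' Simulate a saccadometry cohort
#'
#' Generates trial metadata, per-saccade summaries and (optionally) sampled
#' position traces for a two-group (PD / control), two-task (prosaccade /
#' antisaccade) cohort under the step paradigm described in
#' [simulation_config()]. Each trial:
#'
#' 1. draws a foreperiod from the truncated exponential and a target side
#'    with equal probability;
#' 2. decides the response type (antisaccade trials become directional
#'    errors — reflexive prosaccades toward the target — with the
#'    configured per-group probability);
#' 3. draws latency (shifted gamma), damping ratio, natural frequency and
#'    gain from the per-condition distributions, around per-participant
#'    random intercepts;
#' 4. derives device-style summaries (amplitude at termination, analytic
#'    peak velocity, termination by the velocity-threshold criterion) and
#'    samples the position trace every `dt_ms` ms from 25 ms before
#'    initiation to 20 ms after termination, with additive Gaussian noise.
#'
#' Positive positions are rightward. Times are milliseconds from
#' peripheral-target onset, so saccade initiation occurs at `t = latency`.
#' Output is deterministic given `seed`.
#'
#' @param config a [simulation_config()].
#' @param seed RNG seed (recorded in the result).
#' @return an object of class `saccade_cohort`: a list with tibbles
#'   `trials` (one row per trial: identifiers, labels, foreperiod,
#'   generative parameter draws and per-saccade summaries) and `samples`
#'   (long format: `participant_id`, `task`, `trial_index`, `t_ms`,
#'   `position_deg`; empty when `config$trajectories` is `FALSE`).
#' @export
simulate_cohort <- function(config = simulation_config(), seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed_(seed, simulate_cohort_impl(config, seed))
}

simulate_cohort_impl <- function(config, seed) {
  ids <- c(sprintf("pd_%02d", seq_len(config$n_pd)),
           sprintf("hc_%02d", seq_len(config$n_control)))
  groups <- rep(c("pd", "control"), c(config$n_pd, config$n_control))

  bs <- config$between_sd
  participants <- tibble(
    participant_id = ids, group = groups,
    latency_offset = rnorm(length(ids), 0, bs$latency_ms),
    sigma_offset   = rnorm(length(ids), 0, bs$sigma),
    omega0_offset  = rnorm(length(ids), 0, bs$omega0),
    gain_offset    = rnorm(length(ids), 0, bs$gain_deg)
  )

  trials <- tidyr::expand_grid(
    participant_id = ids,
    task = c("ps", "as"),
    trial_index = seq_len(config$trials_per_task)
  ) %>%
    left_join(participants, by = "participant_id") %>%
    arrange(.data$participant_id, .data$task, .data$trial_index)

  n <- nrow(trials)
  trials$foreperiod_s <- draw_foreperiod(n, config$foreperiod_range_s,
                                         config$foreperiod_rate)
  trials$target_side <- sample(c("left", "right"), n, replace = TRUE)

  err_p <- unname(config$as_error_rate[trials$group])
  is_error <- trials$task == "as" & runif(n) < err_p
  trials$response_type <- dplyr::case_when(
    trials$task == "ps" ~ "ps_correct",
    is_error ~ "as_error",
    TRUE ~ "as_correct"
  )
  # AS errors are reflexive prosaccades toward the target; correct AS away.
  toward <- ifelse(trials$target_side == "right", 1, -1)
  trials$direction <- ifelse(trials$response_type == "as_correct", -toward, toward)

  trials <- trials %>%
    left_join(config$condition_params, by = c("group", "response_type"))

  ws <- config$within_sd
  gamma_mean <- pmax(trials$latency_mean_ms + trials$latency_offset -
                       trials$latency_shift_ms, 10)
  trials$latency_ms <- trials$latency_shift_ms +
    rgamma(n, shape = trials$latency_shape,
           scale = gamma_mean / trials$latency_shape)
  trials$sigma_true <- rtnorm(n, trials$sigma_mean + trials$sigma_offset,
                              ws$sigma, lower = 0.05)
  trials$omega0_true <- rtnorm(n, config$omega0_mean_rad_s + trials$omega0_offset,
                               ws$omega0, lower = 10)
  trials$gain_true <- rtnorm(n, trials$gain_mean_deg + trials$gain_offset,
                             ws$gain_deg, lower = 0.5)

  kin <- saccade_kinematics(trials$gain_true, trials$sigma_true,
                            trials$omega0_true,
                            config$velocity_threshold_deg_s)
  trials$duration_ms <- kin$end_ms
  trials$amplitude_deg <- kin$amplitude
  trials$peak_velocity_deg_s <- kin$peak_velocity
  trials$direction_error <- trials$response_type == "as_error"

  trials <- trials %>%
    select("participant_id", "group", "task", "trial_index", "target_side",
           "foreperiod_s", "response_type", "direction", "direction_error",
           "latency_ms", "amplitude_deg", "peak_velocity_deg_s",
           "duration_ms", "sigma_true", "omega0_true", "gain_true")

  samples <- if (config$trajectories) {
    cohort_samples(trials, config)
  } else {
    tibble(participant_id = character(), task = character(),
           trial_index = integer(), t_ms = numeric(), position_deg = numeric())
  }

  structure(list(trials = trials, samples = samples,
                 config = config, seed = seed),
            class = "saccade_cohort")
}

# Termination time, net displacement at termination and peak velocity of a
# noiseless model saccade; vectorised over parameter draws.
saccade_kinematics <- function(A, sigma, omega0, threshold) {
  n <- length(A)
  end_ms <- numeric(n); amp <- numeric(n); pv <- numeric(n)
  grid <- seq(0.25, 400, by = 0.25)
  for (i in seq_len(n)) {
    v <- abs(step_response_velocity(grid, A[i], sigma[i], omega0[i]))
    above <- v > threshold
    if (!any(above)) {
      end_ms[i] <- NA_real_; amp[i] <- 0; pv[i] <- max(v)
    } else {
      end_ms[i] <- grid[max(which(above))]
      amp[i] <- abs(step_response(end_ms[i], A[i], sigma[i], omega0[i]))
      pv[i] <- max(v)
    }
  }
  list(end_ms = end_ms, amplitude = amp, peak_velocity = pv)
}

# Sample the recording window (initiation - 25 ms to termination + 20 ms)
# for every trial, on the device's dt grid, with additive position noise.
cohort_samples <- function(trials, config) {
  dt <- config$dt_ms
  rows <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    lat <- trials$latency_ms[i]
    dur <- trials$duration_ms[i]
    if (is.na(dur)) dur <- 100
    rel <- seq(-25, ceiling((dur + 20) / dt) * dt, by = dt)
    pos <- step_response(rel, trials$direction[i] * trials$gain_true[i],
                         trials$sigma_true[i], trials$omega0_true[i])
    if (config$noise_sd_deg > 0)
      pos <- pos + rnorm(length(pos), 0, config$noise_sd_deg)
    rows[[i]] <- tibble(
      participant_id = trials$participant_id[i],
      task = trials$task[i],
      trial_index = trials$trial_index[i],
      t_ms = lat + rel,
      position_deg = pos
    )
  }
  dplyr::bind_rows(rows)
}

#' @export
print.saccade_cohort <- function(x, ...) {
  cat("<saccade_cohort>\n")
  cat("  participants:", dplyr::n_distinct(x$trials$participant_id),
      " trials:", nrow(x$trials),
      " samples:", nrow(x$samples), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
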