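#' Finite-difference velocity of a sampled trajectory
#'
#' Central differences at interior samples, one-sided differences at the
#' ends; requires at least three samples on a constant time grid.
#'
#' @param position_deg numeric vector of positions (degrees).
#' @param dt_ms sampling interval (ms).
#' @return numeric vector of velocities (deg/s), same length as input.
#' @export
compute_velocity <- function(position_deg, dt_ms) {
  n <- length(position_deg)
  if (n < 3)
    abort("at least 3 samples are required to compute velocity.",
          class = "saccadom_domain_error")
  if (dt_ms <= 0) abort("`dt_ms` must be positive.", class = "saccadom_domain_error")
  dt_s <- dt_ms / 1000
  v <- numeric(n)
  v[1] <- (position_deg[2] - position_deg[1]) / dt_s
  v[n] <- (position_deg[n] - position_deg[n - 1]) / dt_s
  idx <- 2:(n - 1)
  v[idx] <- (position_deg[idx + 1] - position_deg[idx - 1]) / (2 * dt_s)
  v
}

#' Detect a saccade in a velocity series
#'
#' The saccade is the first contiguous run of samples whose absolute
#' velocity exceeds `threshold_deg_s`. Returns the start and end indices
#' of that run, or `NULL` when the threshold is never exceeded (a valid
#' outcome, not an error).
#'
#' @param velocity numeric vector (deg/s).
#' @param threshold_deg_s detection threshold (deg/s), default 5.
#' @return integer vector `c(start, end)` or `NULL`.
#' @examples
#' detect_saccade(c(0, 0, 10, 200, 10, 0))  # c(3, 6) in 1-based indexing
#' @export
detect_saccade <- function(velocity, threshold_deg_s = 5) {
  if (!length(velocity))
    abort("`velocity` must be non-empty.", class = "saccadom_domain_error")
  above <- abs(velocity) > threshold_deg_s
  if (!any(above)) return(NULL)
  start <- which(above)[1]
  run_end <- start
  while (run_end < length(velocity) && above[run_end + 1L]) run_end <- run_end + 1L
  c(start = start, end = run_end)
}

#' Classify trial responses by movement direction
#'
#' Prosaccade trials answered toward the target are `ps_correct`;
#' antisaccade trials answered away from the target are `as_correct` and
#' toward the target are `as_error` (a reflexive prosaccade).
#' Prosaccade trials answered away from the target (`ps_error`) are not
#' analysed downstream, and trials with zero net displacement are
#' `invalid`.
#'
#' @param task character vector, `"ps"` or `"as"`.
#' @param target_side character vector, `"left"` or `"right"`.
#' @param displacement_deg signed net displacement (positive rightward).
#' @return character vector of response types.
#' @export
label_direction_error <- function(task, target_side, displacement_deg) {
  toward <- ifelse(target_side == "right", 1, -1)
  s <- sign(displacement_deg)
  dplyr::case_when(
    s == 0 ~ "invalid",
    task == "ps" & s == toward ~ "ps_correct",
    task == "ps" ~ "ps_error",
    s == -toward ~ "as_correct",
    TRUE ~ "as_error"
  )
}

#' Apply kinematic quality-control filters to per-saccade summaries
#'
#' A saccade is excluded as a likely recording error when its latency is
#' below 100 ms or above 1000 ms, its amplitude exceeds 40 degrees, or its
#' peak velocity exceeds 1000 deg/s (strict inequalities, thresholds from
#' [qc_config()]). Each rejected saccade carries the first matching reason
#' (`latency_low`, `latency_high`, `amplitude_high`,
#' `peak_velocity_high`); saccades with missing summaries are rejected as
#' `invalid`. Kept and rejected rows partition the input; the result does
#' not depend on row order and the filter is idempotent.
#'
#' @param trials tibble with columns `latency_ms`, `amplitude_deg`,
#'   `peak_velocity_deg_s` (other columns pass through).
#' @param config a [qc_config()].
#' @return list with tibbles `kept` and `rejected` (the latter with a
#'   `reject_reason` column).
#' @export
qc_filter <- function(trials, config = qc_config()) {
  stopifnot(inherits(config, "qc_config"))
  need <- c("latency_ms", "amplitude_deg", "peak_velocity_deg_s")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    abort(paste0("missing summary columns: ", paste(miss, collapse = ", ")),
          class = "saccadom_schema_error")
  lat <- trials$latency_ms
  amp <- trials$amplitude_deg
  pv <- trials$peak_velocity_deg_s
  reason <- dplyr::case_when(
    is.na(lat) | is.na(amp) | is.na(pv) ~ "invalid",
    lat < config$latency_min_ms ~ "latency_low",
    lat > config$latency_max_ms ~ "latency_high",
    amp > config$amplitude_max_deg ~ "amplitude_high",
    pv > config$peak_velocity_max_deg_s ~ "peak_velocity_high",
    TRUE ~ NA_character_
  )
  rejected <- trials[!is.na(reason), , drop = FALSE]
  if (nrow(rejected)) rejected$reject_reason <- reason[!is.na(reason)]
  else rejected$reject_reason <- character(0)
  list(kept = as_tibble(trials[is.na(reason), , drop = FALSE]),
       rejected = as_tibble(rejected))
}

#' Preprocess a cohort: label responses and apply QC
#'
#' Re-derives each trial's response type from its movement direction
#' (`direction * amplitude_deg`, or a `direction` column when present),
#' applies [qc_filter()], and drops prosaccade directional errors and
#' invalid trials, which are never analysed.
#'
#' @param trials per-trial summary tibble (as in `saccade_cohort$trials`).
#' @param config a [qc_config()].
#' @return list with tibbles `kept` and `rejected`.
#' @export
preprocess_trials <- function(trials, config = qc_config()) {
  displacement <- if ("direction" %in% names(trials)) {
    trials$direction * trials$amplitude_deg
  } else {
    trials$amplitude_deg
  }
  trials$response_type <- label_direction_error(trials$task,
                                                trials$target_side,
                                                displacement)
  out <- qc_filter(trials, config)
  drop <- out$kept$response_type %in% c("ps_error", "invalid")
  if (any(drop)) {
    extra <- out$kept[drop, , drop = FALSE]
    extra$reject_reason <- paste0("response_", extra$response_type)
    out$rejected <- bind_rows(out$rejected, extra)
    out$kept <- out$kept[!drop, , drop = FALSE]
  }
  out
}
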