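test_that("finite-difference velocity recovers simple motions", {
  # 1 degree per 5 ms sample step = 200 deg/s
  ramp <- seq(0, 10, by = 1)
  v <- compute_velocity(ramp, dt_ms = 5)
  expect_true(all(abs(v - 200) < 1e-9))
  expect_true(all(compute_velocity(rep(3, 10), 5) == 0))
  expect_error(compute_velocity(c(1, 2), 5), class = "saccadom_domain_error")
})

test_that("finite-difference peak velocity matches the analytic maximum", {
  tr <- simulate_trajectory(10, 0.7, 60, dt_ms = 5, duration_ms = 120)
  v <- compute_velocity(tr$position_deg, 5)
  fine <- seq(0, 120, by = 0.01)
  v_true <- max(abs(step_response_velocity(fine, 10, 0.7, 60)))
  expect_equal(max(abs(v)), v_true, tolerance = 0.02)
})

test_that("saccade detection finds the first supra-threshold run", {
  expect_identical(detect_saccade(c(0, 0, 10, 200, 10, 0), 5),
                   c(start = 3L, end = 5L))
  expect_null(detect_saccade(c(0, 1, -4, 5, 0), 5))  # never strictly above
  expect_error(detect_saccade(numeric(0)), class = "saccadom_domain_error")
  # on a noiseless model saccade the detected duration matches the
  # analytic supra-threshold interval to within one sample
  tr <- simulate_trajectory(10, 0.8, 60, dt_ms = 5, duration_ms = 200)
  v <- compute_velocity(tr$position_deg, 5)
  idx <- detect_saccade(v, 5)
  expect_false(is.null(idx))
  detected_ms <- (idx["end"] - idx["start"]) * 5
  fine <- seq(0.01, 200, by = 0.01)
  above <- abs(step_response_velocity(fine, 10, 0.8, 60)) > 5
  analytic_ms <- fine[max(which(above))] - fine[min(which(above))]
  expect_lt(abs(detected_ms - analytic_ms), 5 + 1e-9)
})

test_that("detection always finds the saccade on noiseless trajectories", {
  for (s in c(0.5, 1, 1.5)) {
    tr <- simulate_trajectory(10, s, 60, dt_ms = 5, duration_ms = 300)
    v <- compute_velocity(tr$position_deg, 5)
    idx <- detect_saccade(v, 5)
    expect_false(is.null(idx))
    expect_identical(unname(idx["start"]), which(abs(v) > 5)[1])
    expect_gt(idx["end"], idx["start"])
    # critically and overdamped responses have a single supra-threshold run
    if (s >= 1) {
      runs <- rle(abs(v) > 5)
      expect_identical(sum(runs$values), 1L)
    }
  }
})

test_that("QC rejects exactly the saccades outside the printed thresholds", {
  toy <- tibble::tibble(
    latency_ms = c(90, 150, 1200, 300, 400, 500),
    amplitude_deg = 10, peak_velocity_deg_s = 400)
  out <- qc_filter(toy)
  expect_identical(nrow(out$kept), 4L)
  expect_identical(out$rejected$reject_reason, c("latency_low", "latency_high"))

  cases <- tibble::tibble(
    latency_ms = c(90, 250, 100, 1000, 500, 500, 500),
    amplitude_deg = c(10, 10.2, 10, 10, 40, 41, 10),
    peak_velocity_deg_s = c(400, 420, 400, 400, 400, 400, 1001))
  out <- qc_filter(cases)
  # boundary values (exactly 100, 1000 ms, 40 deg) are kept: strict inequalities
  expect_identical(nrow(out$kept), 4L)
  expect_identical(out$rejected$reject_reason,
                   c("latency_low", "amplitude_high", "peak_velocity_high"))

  missing <- tibble::tibble(latency_ms = NA_real_, amplitude_deg = 10,
                            peak_velocity_deg_s = 100)
  expect_identical(qc_filter(missing)$rejected$reject_reason, "invalid")
})

test_that("QC is idempotent and order-invariant", {
  co <- small_cohort()
  trials <- co$trials
  trials$latency_ms[1:5] <- c(50, 2000, 90, 300, 400)
  once <- qc_filter(trials)
  twice <- qc_filter(once$kept)
  expect_identical(nrow(twice$rejected), 0L)
  expect_equal(as.data.frame(twice$kept), as.data.frame(once$kept))
  perm <- withr::with_seed(9, trials[sample(nrow(trials)), ])
  out_perm <- qc_filter(perm)
  expect_setequal(
    paste(once$kept$participant_id, once$kept$task, once$kept$trial_index),
    paste(out_perm$kept$participant_id, out_perm$kept$task,
          out_perm$kept$trial_index))
})

test_that("responses are classified by movement direction", {
  expect_identical(label_direction_error("as", "right", -9.8), "as_correct")
  expect_identical(label_direction_error("as", "right", 9.5), "as_error")
  expect_identical(label_direction_error("ps", "left", -10.1), "ps_correct")
  expect_identical(label_direction_error("ps", "left", 10.1), "ps_error")
  expect_identical(label_direction_error("as", "left", 0), "invalid")
})

test_that("preprocessing drops prosaccade errors and invalid responses", {
  trials <- tibble::tibble(
    participant_id = "p1", group = "pd", task = c("ps", "ps", "as"),
    trial_index = 1:3, target_side = "right",
    direction = c(1, -1, 1), latency_ms = 200, amplitude_deg = 10,
    peak_velocity_deg_s = 400)
  out <- preprocess_trials(trials)
  expect_identical(out$kept$response_type, c("ps_correct", "as_error"))
  expect_true("response_ps_error" %in% out$rejected$reject_reason)
})
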