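test_that("foreperiods respect their bounds and truncated-exponential law", {
  x <- draw_foreperiod(1e5, c(1, 2), rate = 3, seed = 11)
  expect_true(all(x >= 1 & x <= 2))
  expect_equal(mean(x), truncexp_mean(3, 1, 2), tolerance = 3 * sd(x) / sqrt(1e5))
  # rate -> 0 flattens to uniform on the interval
  u <- draw_foreperiod(1e5, c(1, 2), rate = 1e-9, seed = 12)
  ks <- suppressWarnings(ks.test(u, "punif", 1, 2))
  expect_gt(ks$p.value, 0.01)
  expect_error(draw_foreperiod(1, c(2, 1)), class = "saccadom_domain_error")
  expect_error(draw_foreperiod(1, c(1, 2), rate = 0),
               class = "saccadom_domain_error")
})

test_that("noiseless trajectories equal the analytic step response exactly", {
  tr <- simulate_trajectory(10, 0.7, 60, dt_ms = 5, duration_ms = 300)
  expect_lt(max(abs(tr$position_deg - step_response(tr$t_ms, 10, 0.7, 60))),
            1e-10)
  expect_equal(tr$t_ms, seq(0, 300, by = 5))
  # overdamped: monotone non-decreasing, never exceeds the gain
  ov <- simulate_trajectory(1, 1.5, 50, duration_ms = 400)
  expect_true(all(diff(ov$position_deg) >= -1e-12))
  expect_true(all(ov$position_deg <= 1 + 1e-12))
})

test_that("trajectory noise is seeded and reproducible", {
  a <- simulate_trajectory(10, 0.7, 60, duration_ms = 100, noise_sd = 0.2,
                           seed = 5)
  b <- simulate_trajectory(10, 0.7, 60, duration_ms = 100, noise_sd = 0.2,
                           seed = 5)
  expect_identical(a, b)
})

test_that("cohort simulation is deterministic given config and seed", {
  cfg <- simulation_config(n_pd = 2, n_control = 2, trials_per_task = 10)
  a <- simulate_cohort(cfg, seed = 1)
  b <- simulate_cohort(cfg, seed = 1)
  expect_identical(a$trials, b$trials)
  expect_identical(a$samples, b$samples)
  expect_equal(nrow(a$trials), 2 * 2 * 10 * 2)
  expect_true(all(a$trials$foreperiod_s >= 1 & a$trials$foreperiod_s <= 2))
})

test_that("a zero antisaccade error rate yields no directional errors", {
  cfg <- simulation_config(n_pd = 2, n_control = 2, trials_per_task = 20,
                           as_error_rate = c(pd = 0, control = 0),
                           trajectories = FALSE)
  co <- simulate_cohort(cfg, seed = 2)
  expect_identical(sum(co$trials$direction_error), 0L)
  expect_true(all(co$trials$response_type[co$trials$task == "as"] ==
                    "as_correct"))
})

test_that("configured group/task effects are recovered by sample means", {
  cfg <- simulation_config(n_pd = 12, n_control = 12, trials_per_task = 200,
                           trajectories = FALSE)
  co <- simulate_cohort(cfg, seed = 31)
  tr <- co$trials
  shift <- function(g) {
    asc <- tr$sigma_true[tr$group == g & tr$response_type == "as_correct"]
    ps <- tr$sigma_true[tr$group == g & tr$response_type == "ps_correct"]
    mean(asc) - mean(ps)
  }
  # configured AS-PS damping shifts: control +0.06, pd +0.09
  expect_equal(shift("control"), 0.06, tolerance = 0.02)
  expect_equal(shift("pd"), 0.09, tolerance = 0.02)
  # latency task contrast (as_correct - ps_correct), configured +120.9 ms
  lat <- tr[tr$group == "control", ]
  d <- mean(lat$latency_ms[lat$response_type == "as_correct"]) -
    mean(lat$latency_ms[lat$response_type == "ps_correct"])
  expect_equal(d, 120.9, tolerance = 15)
  # AS error rates close to configured probabilities
  as_tr <- tr[tr$task == "as", ]
  er <- tapply(as_tr$direction_error, as_tr$group, mean)
  expect_equal(unname(er["pd"]), 0.25, tolerance = 0.04)
  expect_equal(unname(er["control"]), 0.20, tolerance = 0.04)
})

test_that("recording windows cover initiation - 25 ms to termination + 20 ms", {
  co <- small_cohort()
  one <- co$samples[co$samples$participant_id == co$trials$participant_id[1] &
                      co$samples$task == co$trials$task[1] &
                      co$samples$trial_index == co$trials$trial_index[1], ]
  lat <- co$trials$latency_ms[1]
  expect_equal(min(one$t_ms), lat - 25)
  expect_gte(max(one$t_ms) - lat, co$trials$duration_ms[1] + 20 - 5)
  expect_equal(unique(round(diff(one$t_ms), 9)), 5)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simulation_config(n_pd = 0), class = "saccadom_config_error")
  expect_error(simulation_config(foreperiod_range_s = c(2, 1)),
               class = "saccadom_config_error")
  expect_error(simulation_config(as_error_rate = c(pd = 1.2, control = 0)),
               class = "saccadom_config_error")
  bad <- default_condition_params()
  bad$sigma_mean[1] <- -1
  expect_error(simulation_config(condition_params = bad),
               class = "saccadom_config_error")
})
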