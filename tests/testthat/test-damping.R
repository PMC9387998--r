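test_that("noiseless parameters are recovered near-exactly", {
  for (s in c(0.5, 1.0, 1.3)) {
    tr <- simulate_trajectory(1, s, 60, dt_ms = 5, duration_ms = 120)
    fit <- fit_second_order(tr$t_ms, tr$position_deg, 1)
    expect_true(fit$converged)
    expect_equal(fit$sigma, s, tolerance = 0.01)
    expect_equal(fit$omega0, 60, tolerance = 0.6)
    expect_equal(fit$A, 1, tolerance = 0.01)
    expect_lt(fit$mse, 1e-8)
  }
})

test_that("a time-shifted trajectory is recovered through delta_t", {
  tt <- seq(0, 100, by = 5)
  pos <- step_response(tt - 3, 1, 0.7, 60)
  fit <- fit_second_order(tt, pos, 1)
  expect_equal(fit$delta_t, 3, tolerance = 1)
  expect_equal(fit$sigma, 0.7, tolerance = 0.02)
})

test_that("fits are scale-equivariant through amplitude normalisation", {
  tr <- simulate_trajectory(1, 0.8, 55, duration_ms = 100, noise_sd = 0.005,
                            seed = 4)
  f1 <- fit_second_order(tr$t_ms, tr$position_deg, 1)
  f2 <- fit_second_order(tr$t_ms, 12 * tr$position_deg, 12)
  expect_equal(f1$sigma, f2$sigma, tolerance = 1e-4)
  expect_equal(f1$omega0, f2$omega0, tolerance = 1e-4)
  expect_equal(f1$delta_t, f2$delta_t, tolerance = 1e-3)
  # leftward saccades fit identically up to sign
  f3 <- fit_second_order(tr$t_ms, -tr$position_deg, 1)
  expect_equal(f1$sigma, f3$sigma, tolerance = 1e-6)
})

test_that("the sigma standard error is calibrated within a factor of two", {
  sg <- 0.7
  est <- se <- numeric(60)
  for (i in seq_len(60)) {
    tr <- simulate_trajectory(10, sg, 60, duration_ms = 80, noise_sd = 0.15,
                              seed = 500 + i)
    f <- fit_second_order(tr$t_ms, tr$position_deg, 10)
    est[i] <- f$sigma; se[i] <- f$sigma_se
  }
  expect_lt(abs(mean(est) - sg), 0.05)
  ratio <- median(se) / sd(est)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("degenerate trajectories flag non-convergence, short ones error", {
  flat <- fit_second_order(seq(0, 50, by = 5), rep(1, 11), 10)
  expect_false(flat$converged)
  expect_identical(flat$sigma_se, Inf)
  expect_error(fit_second_order(c(0, 5, 10), c(0, 1, 2)),
               class = "saccadom_domain_error")
})

test_that("imprecise damping estimates are excluded by the SE filter", {
  fits <- tibble::tibble(sigma_se = c(0.1, 0.49, 0.51, 2.0),
                         converged = TRUE)
  expect_identical(nrow(filter_by_sigma_se(fits, 0.5)), 2L)
  # exactly 0.5 is kept (the exclusion rule is strictly greater than)
  expect_identical(nrow(filter_by_sigma_se(
    tibble::tibble(sigma_se = 0.5, converged = TRUE), 0.5)), 1L)
  expect_identical(nrow(filter_by_sigma_se(fits, Inf)), 4L)
  expect_identical(nrow(filter_by_sigma_se(fits[0, ], 0.5)), 0L)
  # non-converged fits are always excluded
  nc <- tibble::tibble(sigma_se = c(0.1, Inf), converged = c(FALSE, FALSE))
  expect_identical(nrow(filter_by_sigma_se(nc, 0.5)), 0L)
})

test_that("cohort-level fitting recovers the generating damping ratios", {
  co <- small_cohort()
  pre <- preprocess_trials(co$trials)
  kept <- pre$kept[1:25, ]
  fits <- fit_saccades(kept, co$samples)
  expect_identical(nrow(fits), 25L)
  ok <- filter_by_sigma_se(fits, 0.5)
  joined <- dplyr::left_join(
    ok, kept[, c("participant_id", "task", "trial_index", "sigma_true")],
    by = c("participant_id", "task", "trial_index"))
  expect_gt(nrow(joined), 15)
  expect_lt(abs(mean(joined$sigma - joined$sigma_true)), 0.06)
  expect_gt(cor(joined$sigma, joined$sigma_true), 0.5)
})

test_that("tidy and glance summarise a fit", {
  tr <- simulate_trajectory(1, 0.7, 60, duration_ms = 100)
  f <- fit_second_order(tr$t_ms, tr$position_deg, 1)
  td <- tidy(f)
  expect_identical(td$term, c("A", "sigma", "omega0", "delta_t"))
  expect_equal(td$estimate[2], 0.7, tolerance = 0.01)
  g <- glance(f)
  expect_true(g$converged)
  expect_lt(g$mse, 1e-8)
})
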