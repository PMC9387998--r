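#' Fit the second-order step response to one saccade trajectory
#'
#' Estimates gain `A`, damping ratio `sigma`, natural frequency `omega0`
#' and a time shift `delta_t` by bounded nonlinear least squares on the
#' post-initiation position profile. The trajectory is first normalised:
#' positions are divided by the measured amplitude (net displacement), so
#' the fit is scale-free and `A` expresses over/undershoot of the plateau
#' relative to the measured amplitude. The residual minimised is
#' \deqn{\sum_i \left(\phi_{obs}(t_i) - \hat\phi(t_i - \delta t)\right)^2}
#' with `|delta_t| <= 5` ms, so a positive `delta_t` means the saccade
#' started after the nominal initiation time; the continuous shift
#' compensates for the finite sampling resolution.
#'
#' Optimisation uses Levenberg-Marquardt least squares
#' ([minpack.lm::nls.lm()]) with a multi-start grid over
#' `sigma` in \{0.5, 1, 1.5\} and `omega0` in \{30, 60, 120\} rad/s to
#' avoid branch-local minima; the best sum of squares wins, with ties
#' broken toward smaller `sigma`. The standard error of `sigma` comes from
#' the linearised covariance \eqn{s^2 (J^T J)^{-1}} at the optimum
#' (`J` the residual Jacobian, `s^2` the residual variance); when the
#' optimiser fails, the trajectory is degenerate, or `A`, `sigma` or
#' `omega0` lands on a box bound, the fit is flagged non-converged and
#' `sigma_se` is `Inf` so that precision filters always exclude it.
#'
#' @param t_ms sample times in ms, measured from saccade initiation
#'   (first sample at 0); at least 6 samples.
#' @param position_deg sampled angular positions (degrees, signed).
#' @param amplitude_deg measured saccade amplitude used for
#'   normalisation; defaults to the absolute net displacement of the
#'   trajectory.
#' @return an object of class `second_order_fit`: a list with elements
#'   `A`, `sigma`, `omega0`, `delta_t`, `mse` (mean squared residual in
#'   normalised units squared), `sigma_se`, `converged`, `n`.
#' @examples
#' tr <- simulate_trajectory(10, 0.7, 60, duration_ms = 80)
#' fit_second_order(tr$t_ms, tr$position_deg)
#' @export
fit_second_order <- function(t_ms, position_deg, amplitude_deg = NULL) {
  n <- length(t_ms)
  if (n != length(position_deg))
    abort("`t_ms` and `position_deg` must have equal length.",
          class = "saccadom_domain_error")
  if (n < 6)
    abort("at least 6 post-initiation samples are required.",
          class = "saccadom_domain_error")

  net <- position_deg[n] - 0  # displacement from initiation (position 0 origin)
  dir <- if (sign(net) != 0) sign(net) else 1
  if (is.null(amplitude_deg)) amplitude_deg <- abs(net)
  if (!is.finite(amplitude_deg) || amplitude_deg <= 0 ||
      isTRUE(all.equal(var(position_deg), 0))) {
    return(new_second_order_fit(NA, NA, NA, NA, NA, Inf, FALSE, n))
  }
  y <- dir * position_deg / amplitude_deg

  lower <- c(A = 0.05, sigma = 0.05, omega0 = 5, delta_t = -5)
  upper <- c(A = 3,    sigma = 5,    omega0 = 500, delta_t = 5)
  resid_fn <- function(par) {
    y - so_model(t_ms - par[4], par[1], par[2], par[3])
  }

  # Multi-start exploration at coarse tolerance, then a polishing run at
  # tight tolerance from the best start; perfect fits end the search early.
  starts <- tidyr::expand_grid(sigma = c(0.5, 1, 1.5),
                               omega0 = c(30, 60, 120))
  coarse <- minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-7,
                                       ptol = 1e-7)
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    par0 <- c(A = 1, sigma = starts$sigma[k], omega0 = starts$omega0[k],
              delta_t = 0)
    fit <- run_lm(par0, resid_fn, lower, upper, coarse)
    if (is.null(fit)) next
    ssq <- sum(fit$fvec^2)
    if (is.null(best) || ssq < best$ssq - 1e-12 ||
        (abs(ssq - best$ssq) <= 1e-12 && fit$par[2] < best$par[2])) {
      best <- list(ssq = ssq, par = fit$par, info = fit$info)
    }
    if (best$ssq < n * 1e-16) break
  }
  if (is.null(best))
    return(new_second_order_fit(NA, NA, NA, NA, NA, Inf, FALSE, n))

  polish <- run_lm(best$par, resid_fn, lower, upper,
                   minpack.lm::nls.lm.control(maxiter = 200))
  if (!is.null(polish) && sum(polish$fvec^2) <= best$ssq)
    best <- list(ssq = sum(polish$fvec^2), par = polish$par,
                 info = polish$info)

  par <- best$par
  mse <- best$ssq / n
  on_bound <- any(abs(par[1:3] - lower[1:3]) < 1e-8) ||
    any(abs(par[1:3] - upper[1:3]) < 1e-8)
  converged <- best$info %in% 1:3 && !on_bound
  se <- sigma_standard_error(par, resid_fn, best$ssq, n)
  if (!converged) se <- Inf
  new_second_order_fit(par[1], par[2], par[3], par[4], mse, se, converged, n)
}

# Levenberg-Marquardt with box constraints. The unconstrained solver is run
# first (it is much faster); the constrained solver is used only when the
# unconstrained optimum leaves the box. The residual function guards the
# parameter domain by clamping sigma and omega0 to positive values.
run_lm <- function(par0, resid_fn, lower, upper, control) {
  safe_fn <- function(par) {
    par[2] <- max(par[2], 1e-4)   # sigma
    par[3] <- max(par[3], 1e-2)   # omega0
    r <- resid_fn(par)
    r[!is.finite(r)] <- 1e6
    r
  }
  fit <- tryCatch(minpack.lm::nls.lm(par = par0, fn = safe_fn,
                                     control = control),
                  error = function(e) NULL)
  if (!is.null(fit) && all(fit$par >= lower) && all(fit$par <= upper))
    return(fit)
  tryCatch(minpack.lm::nls.lm(par = par0, fn = resid_fn, lower = lower,
                              upper = upper, control = control),
           error = function(e) NULL)
}

# Unit step response evaluated at (possibly negative) times in ms.
so_model <- function(t_ms, A, sigma, omega0) {
  t <- t_ms / 1000
  out <- numeric(length(t))
  pos <- t > 0
  if (any(pos)) out[pos] <- A * step_response_unit(t[pos], sigma, omega0)
  out
}

# Linearised covariance of the damping ratio: s^2 (J'J)^{-1}, J by central
# finite differences in the free parameters.
sigma_standard_error <- function(par, resid_fn, ssq, n) {
  p <- length(par)
  if (n <= p) return(Inf)
  J <- matrix(NA_real_, n, p)
  h <- pmax(1e-6, abs(par) * 1e-6)
  for (j in seq_len(p)) {
    up <- par; up[j] <- up[j] + h[j]
    dn <- par; dn[j] <- dn[j] - h[j]
    J[, j] <- -(resid_fn(up) - resid_fn(dn)) / (2 * h[j])
  }
  s2 <- ssq / (n - p)
  cov <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
  if (is.null(cov) || !is.finite(cov[2, 2]) || cov[2, 2] < 0) return(Inf)
  sqrt(cov[2, 2])
}

new_second_order_fit <- function(A, sigma, omega0, delta_t, mse, sigma_se,
                                 converged, n) {
  structure(list(A = unname(A), sigma = unname(sigma),
                 omega0 = unname(omega0), delta_t = unname(delta_t),
                 mse = unname(mse), sigma_se = unname(sigma_se),
                 converged = converged, n = n),
            class = "second_order_fit")
}

#' @export
print.second_order_fit <- function(x, ...) {
  cat("<second_order_fit>",
      sprintf("A=%.3f sigma=%.3f omega0=%.1f delta_t=%.2f ms",
              x$A, x$sigma, x$omega0, x$delta_t),
      sprintf("mse=%.3g sigma_se=%.3g converged=%s n=%d",
              x$mse, x$sigma_se, x$converged, x$n), sep = "\n  ")
  invisible(x)
}

#' @rdname fit_second_order
#' @param x a `second_order_fit`.
#' @param ... unused.
#' @export
tidy.second_order_fit <- function(x, ...) {
  tibble(term = c("A", "sigma", "omega0", "delta_t"),
         estimate = c(x$A, x$sigma, x$omega0, x$delta_t),
         std.error = c(NA, x$sigma_se, NA, NA))
}

#' @rdname fit_second_order
#' @export
glance.second_order_fit <- function(x, ...) {
  tibble(mse = x$mse, sigma_se = x$sigma_se, converged = x$converged,
         n = x$n)
}

#' Fit the second-order model to every saccade in a cohort
#'
#' Segments each trial's samples from initiation onward (samples at
#' `t_ms >= latency_ms`, re-origined so initiation is time 0; initiation
#' is the device-reported latency) and applies [fit_second_order()].
#'
#' @param trials per-trial summary tibble (must contain `participant_id`,
#'   `task`, `trial_index`, `latency_ms`, `amplitude_deg`).
#' @param samples long-format samples tibble.
#' @return tibble with one row per trial: identifiers plus `A`, `sigma`,
#'   `omega0`, `delta_t`, `fit_mse`, `sigma_se`, `converged`.
#' @export
fit_saccades <- function(trials, samples) {
  key <- paste(samples$participant_id, samples$task, samples$trial_index)
  split_idx <- split(seq_len(nrow(samples)), key)
  out <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tk <- paste(trials$participant_id[i], trials$task[i],
                trials$trial_index[i])
    idx <- split_idx[[tk]]
    fit <- NULL
    if (!is.null(idx)) {
      t_ms <- samples$t_ms[idx]
      pos <- samples$position_deg[idx]
      keep <- t_ms >= trials$latency_ms[i] - 1e-9
      if (sum(keep) >= 6) {
        t_rel <- t_ms[keep] - trials$latency_ms[i]
        fit <- tryCatch(
          fit_second_order(t_rel, pos[keep], trials$amplitude_deg[i]),
          error = function(e) NULL)
      }
    }
    if (is.null(fit)) fit <- new_second_order_fit(NA, NA, NA, NA, NA, Inf,
                                                  FALSE, 0L)
    out[[i]] <- tibble(
      participant_id = trials$participant_id[i], task = trials$task[i],
      trial_index = trials$trial_index[i],
      A = fit$A, sigma = fit$sigma, omega0 = fit$omega0,
      delta_t = fit$delta_t, fit_mse = fit$mse, sigma_se = fit$sigma_se,
      converged = fit$converged)
  }
  bind_rows(out)
}

#' Filter damping fits by the precision of the damping-ratio estimate
#'
#' Keeps converged fits whose damping-ratio standard error does not
#' exceed `max_se` (default 0.5); fits with `sigma_se > max_se`
#' (strictly) or failed convergence are excluded from damping analyses.
#'
#' @param fits tibble with `sigma_se` and `converged` columns.
#' @param max_se threshold on the standard error of sigma.
#' @return the kept rows of `fits`.
#' @export
filter_by_sigma_se <- function(fits, max_se = 0.5) {
  fits[is.finite(fits$sigma_se) & fits$sigma_se <= max_se &
         fits$converged, , drop = FALSE]
}
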