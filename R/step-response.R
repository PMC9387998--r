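#' Step response of a second-order system
#'
#' Analytic angular-position profile of a saccade modelled as the unit-step
#' response of a linear second-order system with gain `A`, damping ratio
#' `sigma` and natural frequency `omega0`, evaluated at times `t_ms`
#' (milliseconds). The three closed-form branches are
#' \deqn{\phi(t) = A\left(1 - \frac{e^{-\sigma\omega_0 t}}{\sqrt{1-\sigma^2}}
#'   \sin(\omega_0\sqrt{1-\sigma^2}\,t + \arccos\sigma)\right), \quad \sigma < 1}
#' \deqn{\phi(t) = A\left(1 - e^{-\omega_0 t} - \omega_0 t e^{-\omega_0 t}\right),
#'   \quad \sigma = 1}
#' \deqn{\phi(t) = A\left(1 + \frac{(\sigma - r)e^{-\omega_0 t(\sigma + r)} -
#'   (\sigma + r)e^{-\omega_0 t(\sigma - r)}}{2r}\right), \quad r =
#'   \sqrt{\sigma^2 - 1}, \ \sigma > 1}
#' multiplied by the Heaviside step (the value is 0 for `t < 0`). All branches
#' start at rest and converge to the gain `A` as `t` grows.
#'
#' The critical branch is evaluated only within `1e-6` of `sigma = 1`; the
#' open branches are numerically stable elsewhere and continuous across the
#' boundary to well below sampling noise.
#'
#' @param t_ms numeric vector of times in milliseconds (may include t < 0).
#' @param A gain: asymptotic displacement (degrees, or 1 after normalisation).
#' @param sigma damping ratio (> 0); < 1 underdamped, 1 critical, > 1
#'   overdamped.
#' @param omega0 natural frequency in rad/s (> 0).
#' @return numeric vector of displacements, same length as `t_ms`.
#' @examples
#' step_response(c(0, 25, 50, 300), A = 10, sigma = 0.7, omega0 = 60)
#' @export
step_response <- function(t_ms, A, sigma, omega0) {
  check_second_order_params(sigma, omega0)
  t <- t_ms / 1000
  out <- numeric(length(t))
  pos <- which(t > 0)
  if (length(pos)) {
    tp <- t[pos]
    out[pos] <- A * step_response_unit(tp, sigma, omega0)
  }
  out
}

# Unit-gain step response at times t (seconds, all > 0).
step_response_unit <- function(t, sigma, omega0) {
  if (abs(sigma - 1) < 1e-6) {
    w <- omega0 * t
    1 - exp(-w) - w * exp(-w)
  } else if (sigma < 1) {
    wd <- omega0 * sqrt(1 - sigma^2)
    1 - exp(-sigma * omega0 * t) / sqrt(1 - sigma^2) *
      sin(wd * t + acos(sigma))
  } else {
    r <- sqrt(sigma^2 - 1)
    1 + ((sigma - r) * exp(-omega0 * t * (sigma + r)) -
           (sigma + r) * exp(-omega0 * t * (sigma - r))) / (2 * r)
  }
}

#' Analytic velocity of the second-order step response
#'
#' Time derivative of [step_response()], in degrees per second, used to
#' locate saccade termination (velocity-threshold criterion) and to compute
#' peak velocities of noiseless model saccades.
#'
#' @inheritParams step_response
#' @return numeric vector of velocities (deg/s), same length as `t_ms`.
#' @export
step_response_velocity <- function(t_ms, A, sigma, omega0) {
  check_second_order_params(sigma, omega0)
  t <- t_ms / 1000
  out <- numeric(length(t))
  pos <- which(t > 0)
  if (!length(pos)) return(out)
  tp <- t[pos]
  v <- if (abs(sigma - 1) < 1e-6) {
    omega0^2 * tp * exp(-omega0 * tp)
  } else if (sigma < 1) {
    wd <- omega0 * sqrt(1 - sigma^2)
    omega0 * exp(-sigma * omega0 * tp) * sin(wd * tp) / sqrt(1 - sigma^2)
  } else {
    r <- sqrt(sigma^2 - 1)
    omega0 / (2 * r) * (exp(-omega0 * tp * (sigma - r)) -
                          exp(-omega0 * tp * (sigma + r)))
  }
  out[pos] <- A * v
  out
}

#' Peak overshoot fraction of an underdamped second-order system
#'
#' Closed-form overshoot of the unit step response,
#' \eqn{\exp(-\sigma\pi/\sqrt{1-\sigma^2})}, defined for `sigma < 1`.
#' Overdamped and critically damped systems do not overshoot (returns 0).
#'
#' @param sigma damping ratio (> 0).
#' @return overshoot as a fraction of the gain.
#' @export
overshoot_fraction <- function(sigma) {
  stopifnot(is.numeric(sigma), all(sigma > 0))
  ifelse(sigma < 1, exp(-sigma * pi / sqrt(pmax(1 - sigma^2, 0))), 0)
}

# Time (ms) at which a noiseless model saccade terminates: the end of the
# first interval during which |velocity| exceeds `threshold` deg/s.
# Searched on a 0.25 ms grid out to `t_max_ms`.
saccade_end_time <- function(A, sigma, omega0, threshold = 5, t_max_ms = 400) {
  grid <- seq(0.25, t_max_ms, by = 0.25)
  v <- abs(step_response_velocity(grid, A, sigma, omega0))
  above <- v > threshold
  if (!any(above)) return(NA_real_)
  grid[max(which(above))]
}

check_second_order_params <- function(sigma, omega0) {
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) || sigma <= 0)
    abort("`sigma` must be a single positive number.", class = "saccadom_domain_error")
  if (!is.numeric(omega0) || length(omega0) != 1 || !is.finite(omega0) || omega0 <= 0)
    abort("`omega0` must be a single positive number.", class = "saccadom_domain_error")
  invisible(TRUE)
}
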