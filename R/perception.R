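#' Evidence-accumulation velocity perception
#'
#' Drivers observe the other vehicle's position and acceleration perfectly,
#' but perceive its velocity through noisy evidence accumulation: at every
#' time step the perceived velocity moves a fraction `alpha` towards the true
#' velocity and picks up a Wiener-process increment scaled by `beta`. The
#' stationary error standard deviation is
#' `sqrt(beta^2 * dt / (1 - (1 - alpha)^2))`, about 0.155 m/s at the defaults.
#'
#' @param prev Previous perceived velocity, m/s.
#' @param v_real True velocity of the observed vehicle, m/s.
#' @param alpha Update rate per step, in (0, 1].
#' @param beta Noise level; 0 disables perception noise.
#' @param dt Time step, s (the Wiener increment has variance `dt`).
#' @return Updated perceived velocity, m/s.
#' @export
#' @examples
#' update_perceived_velocity(9, 10, alpha = 1, beta = 0, dt = 0.05) # 10
update_perceived_velocity <- function(prev, v_real, alpha, beta, dt) {
  stopifnot(dt > 0, alpha > 0, alpha <= 1)
  dW <- if (beta > 0) rnorm(1L, 0, sqrt(dt)) else 0
  prev + alpha * (v_real - prev) + beta * dW
}

#' Expected acceleration from recent observations
#'
#' The belief over the other vehicle's future motion assumes a normally
#' distributed constant acceleration. Its mean is the average of the
#' accelerations observed over the last `Tm` seconds; its variance combines a
#' comfortable-acceleration prior `(ac/3)^2` (so that +/- `ac` spans 99.7% of
#' expected accelerations) with the population variance of the recent
#' observations -- inconsistent recent behavior widens the belief.
#'
#' @param memory Numeric vector of recent acceleration observations, m/s^2,
#'   oldest first, spanning at most `Tm` seconds.
#' @param ac Maximum comfortable acceleration, m/s^2.
#' @return A list with `mu_a` (m/s^2) and `var_a` ((m/s^2)^2).
#' @export
#' @examples
#' expected_acceleration(rep(0, 10), ac = 1) # mu 0, var 1/9
expected_acceleration <- function(memory, ac) {
  if (length(memory) == 0) {
    stop("acceleration memory is empty; seed it with the first observation",
         call. = FALSE)
  }
  mu <- mean(memory)
  pop_var <- mean((memory - mu)^2)
  list(mu_a = mu, var_a = (ac / 3)^2 + pop_var)
}

# belief-point lead times: k/fb for k = 1..T*fb (the current instant excluded)
belief_times <- function(params) {
  n <- round(params$T_horizon * params$fb)
  seq_len(n) / params$fb
}

# fast internal belief projection; returns plain vectors
belief_project <- function(position, v_perceived, mu_a, var_a, params) {
  dtk <- belief_times(params)
  half_t2 <- 0.5 * dtk^2
  mu <- half_t2 * mu_a + v_perceived * dtk + position
  sigma <- if (params$belief_sigma_mode == "sd") {
    half_t2 * sqrt(var_a)
  } else {
    sqrt(half_t2 * var_a)
  }
  list(t_ahead = dtk, mu = mu, sigma = sigma)
}

#' Project a belief over the other vehicle's future positions
#'
#' Builds the communication-based belief: at each of the `T * fb` belief
#' points (lead times `1/fb, 2/fb, ..., T`), the other vehicle's position is
#' a two-component Gaussian mixture centered on the constant-acceleration
#' projection of the observed position, the perceived velocity, and the
#' expected acceleration from [expected_acceleration()]. The narrow component
#' captures kinematically plausible motion; the second component, with
#' variance inflated by `phi`, reserves probability mass for unexpected
#' maneuvers such as emergency braking.
#'
#' @param position Observed position of the other vehicle, m.
#' @param v_perceived Perceived velocity of the other vehicle, m/s.
#' @param memory Acceleration observation memory, m/s^2 (see
#'   [expected_acceleration()]).
#' @param params A [cei_params()] list.
#' @return A tibble with one row per belief point: `t_ahead` (s), `mu` (m),
#'   `sigma` (m), `phi`.
#' @export
#' @examples
#' project_belief(60, 10, memory = 0, params = cei_params())
project_belief <- function(position, v_perceived, memory,
                           params = cei_params()) {
  ea <- expected_acceleration(memory, params$ac)
  b <- belief_project(position, v_perceived, ea$mu_a, ea$var_a, params)
  tibble::tibble(t_ahead = b$t_ahead, mu = b$mu, sigma = b$sigma,
                 phi = params$phi)
}

# vectorized probability mass of the half-half Gaussian mixture
# N(mu, sigma^2) and N(mu, phi * sigma^2) inside [lo, hi]
mix_interval_prob <- function(mu, sigma, phi, lo, hi) {
  p <- numeric(length(mu))
  deg <- sigma <= 0
  if (any(deg)) {
    p[deg] <- as.numeric(lo[deg] <= mu[deg] & mu[deg] <= hi[deg])
  }
  if (any(!deg)) {
    i <- !deg
    s1 <- sigma[i]
    s2 <- sigma[i] * sqrt(phi)
    p[i] <- 0.5 * (pnorm(hi[i], mu[i], s1) - pnorm(lo[i], mu[i], s1)) +
      0.5 * (pnorm(hi[i], mu[i], s2) - pnorm(lo[i], mu[i], s2))
  }
  p
}

#' Probability that a belief point falls inside an interval
#'
#' Integrates the two-component Gaussian-mixture density of a belief point
#' (equal weights, variances `sigma^2` and `phi * sigma^2`) over `[lo, hi]`.
#' A degenerate point (`sigma = 0`) contributes an indicator of `mu` lying in
#' the interval. All arguments are vectorized and recycled.
#'
#' @param mu Mean position, m.
#' @param sigma Position standard deviation of the narrow component, m.
#' @param lo,hi Interval bounds, m (`lo <= hi`; infinite bounds allowed).
#' @param phi Variance scaling of the wide component.
#' @return Probability in \[0, 1\].
#' @export
#' @examples
#' interval_probability(0, 1, -Inf, 0) # 0.5
interval_probability <- function(mu, sigma, lo, hi, phi = 3) {
  if (any(lo > hi)) stop("interval_probability() requires lo <= hi", call. = FALSE)
  n <- max(length(mu), length(sigma), length(lo), length(hi))
  mix_interval_prob(rep_len(mu, n), rep_len(sigma, n), phi,
                    rep_len(lo, n), rep_len(hi, n))
}
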