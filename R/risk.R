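#' Fitted per-driver base risk thresholds
#'
#' The personal base values of the lower and upper risk thresholds for the 18
#' drivers (9 fixed pairs) of the merging study, obtained from the grid-search
#' plus mixed-effects calibration. These are the default driver population for
#' [run_batch()].
#'
#' @return A tibble with columns `pair`, `side` (`"left"`/`"right"`),
#'   `theta_l`, `theta_u`.
#' @export
#' @examples
#' driver_thresholds()
driver_thresholds <- function() {
  tibble::tibble(
    pair = rep(1:9, each = 2),
    side = rep(c("left", "right"), 9),
    theta_l = c(0.165, 0.260, 0.245, 0.058, 0.058, 0.245, 0.183, 0.201,
                0.113, 0.269, 0.246, 0.161, 0.320, 0.201, 0.165, 0.246,
                0.178, 0.227),
    theta_u = c(0.495, 0.562, 0.635, 0.493, 0.488, 0.631, 0.537, 0.524,
                0.498, 0.585, 0.550, 0.546, 0.736, 0.522, 0.525, 0.586,
                0.519, 0.543)
  )
}

#' Population-level incentive coefficients
#'
#' The fitted linear incentive-function coefficients shared by all drivers:
#' sensitivities of the upper and lower risk thresholds to the relative
#' position (per m), relative velocity (per m/s), and their interaction, from
#' the driver's own perspective. A following driver (negative relative
#' position) gets lowered thresholds and hence more incentive to act, encoding
#' common traffic customs.
#'
#' @return A list with numeric length-3 vectors `lambda_u` and `lambda_l`
#'   (position, velocity, interaction coefficients).
#' @export
incentive_defaults <- function() {
  list(lambda_u = c(0.003, 0.018, -0.006),
       lambda_l = c(0.004, 0.016, -0.003))
}

#' Per-driver risk threshold set
#'
#' Bundles a driver's base thresholds with the population incentive
#' coefficients. Setting both lambda vectors to zero yields the
#' static-threshold model variant.
#'
#' @param theta_l,theta_u Base lower and upper thresholds, probabilities with
#'   `0 < theta_l < theta_u < 1`.
#' @param lambda_u,lambda_l Length-3 incentive coefficient vectors (position,
#'   velocity, interaction); defaults from [incentive_defaults()].
#' @return A list of class `cei_thresholds`.
#' @export
risk_thresholds <- function(theta_l, theta_u,
                            lambda_u = incentive_defaults()$lambda_u,
                            lambda_l = incentive_defaults()$lambda_l) {
  stopifnot(theta_l > 0, theta_l < theta_u, theta_u < 1,
            length(lambda_u) == 3, length(lambda_l) == 3)
  structure(list(theta_l = theta_l, theta_u = theta_u,
                 lambda_u = as.numeric(lambda_u),
                 lambda_l = as.numeric(lambda_l)),
            class = "cei_thresholds")
}

#' Dynamic risk thresholds
#'
#' Adjusts a driver's base thresholds with the linear incentive function of
#' the relative position `delta_p = s_ego - s_other` (m) and relative velocity
#' `delta_v = v_ego - v_other_perceived` (m/s), both from the driver's own
#' perspective:
#' `rho = theta + lambda_1 * delta_p + lambda_2 * delta_v +
#' lambda_3 * delta_p * delta_v`.
#' Results are clamped to (1e-6, 1 - 1e-6) and the lower threshold is kept
#' strictly below the upper one; these guards matter only at extreme relative
#' states where the linear terms would otherwise invert the thresholds.
#'
#' @param thresholds A [risk_thresholds()] object.
#' @param delta_p,delta_v Relative position (m) and velocity (m/s), ego minus
#'   other; vectorized.
#' @return A tibble with columns `rho_l`, `rho_u`.
#' @export
#' @examples
#' th <- risk_thresholds(0.058, 0.488)
#' dynamic_thresholds(th, delta_p = 4, delta_v = 0.8)
dynamic_thresholds <- function(thresholds, delta_p, delta_v) {
  eps <- 1e-6
  inc <- function(theta, lam) {
    theta + lam[1] * delta_p + lam[2] * delta_v + lam[3] * delta_p * delta_v
  }
  rho_u <- pmin(pmax(inc(thresholds$theta_u, thresholds$lambda_u), eps), 1 - eps)
  rho_l <- pmin(pmax(inc(thresholds$theta_l, thresholds$lambda_l), eps), 1 - eps)
  # keep the lower threshold strictly below the upper one but positive, so
  # the relaxation trigger stays reachable at extreme relative states
  rho_l <- pmin(rho_l, 0.99 * rho_u)
  tibble::tibble(rho_l = rho_l, rho_u = rho_u)
}

#' Collision bounds around an ego position
#'
#' The extremum positions of the other vehicle that would collide with the
#' ego vehicle at a given ego position. Before the shared corridor (ego
#' front bumper at most one vehicle length before the merge point) no
#' position of the other vehicle can collide; inside it, the other vehicle
#' collides when within one vehicle length of the ego, with the lower bound
#' clipped at the start of the shared corridor.
#'
#' @param ego_position Ego front-bumper position(s), m.
#' @param track A [track_geometry()].
#' @return A tibble with columns `ego_position`, `lo`, `hi` (`NA` when no
#'   collision is possible).
#' @export
#' @examples
#' collision_bounds(c(90, 96, 103))
collision_bounds <- function(ego_position, track = track_geometry()) {
  L <- track$vehicle_length
  corridor <- track$merge_point - L
  possible <- ego_position > corridor
  lo <- ifelse(possible, pmax(ego_position - L, corridor), NA_real_)
  hi <- ifelse(possible, ego_position + L, NA_real_)
  tibble::tibble(ego_position = ego_position, lo = lo, hi = hi)
}

# scalar hot path of dynamic_thresholds(); returns c(rho_l, rho_u)
thresholds_fast <- function(th, dp, dv) {
  eps <- 1e-6
  lu <- th$lambda_u; ll <- th$lambda_l
  pdv <- dp * dv
  rho_u <- th$theta_u + lu[1] * dp + lu[2] * dv + lu[3] * pdv
  rho_l <- th$theta_l + ll[1] * dp + ll[2] * dv + ll[3] * pdv
  rho_u <- min(max(rho_u, eps), 1 - eps)
  rho_l <- min(max(rho_l, eps), 1 - eps, 0.99 * rho_u)
  c(rho_l, rho_u)
}

# fast internal risk evaluation: ego positions and belief vectors aligned on
# the belief times; returns per-point probabilities
risk_per_point <- function(ego_pos, mu, sigma, phi, track) {
  L <- track$vehicle_length
  corridor <- track$merge_point - L
  p <- numeric(length(ego_pos))
  possible <- ego_pos > corridor
  if (any(possible)) {
    e <- ego_pos[possible]
    p[possible] <- mix_interval_prob(mu[possible], sigma[possible], phi,
                                     pmax(e - L, corridor), e + L)
  }
  p
}

risk_aggregate <- function(per_point, aggregation) {
  if (aggregation == "max") max(per_point, 0) else min(1, sum(per_point))
}

#' Perceived collision risk of a plan against a belief
#'
#' For every belief point, the probability mass of the two-component mixture
#' between the collision bounds implied by the ego's planned position at that
#' lead time; the scalar perceived risk aggregates the per-point
#' probabilities (maximum by default, sum capped at 1 optionally).
#'
#' @param ego_positions Ego front-bumper positions at the belief lead times, m
#'   (same length and ordering as `belief` rows); see [plan_positions()].
#' @param belief A belief tibble from [project_belief()].
#' @param track A [track_geometry()].
#' @param aggregation `"max"` (default) or `"sum"`.
#' @return A list of class `cei_risk` with elements `risk` (scalar in
#'   \[0, 1\]) and `per_point` (tibble `t_ahead`, `ego_position`,
#'   `probability`).
#' @export
perceived_risk <- function(ego_positions, belief, track = track_geometry(),
                           aggregation = c("max", "sum")) {
  aggregation <- match.arg(aggregation)
  stopifnot(length(ego_positions) == nrow(belief))
  phi <- belief$phi[1]
  p <- risk_per_point(ego_positions, belief$mu, belief$sigma, phi, track)
  structure(list(
    risk = risk_aggregate(p, aggregation),
    per_point = tibble::tibble(t_ahead = belief$t_ahead,
                               ego_position = ego_positions,
                               probability = p)
  ), class = "cei_risk")
}
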