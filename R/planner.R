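#' Comfort/speed cost of a constant-acceleration plan
#'
#' Rolls the ego vehicle out under a constant control input for the whole
#' planning horizon (semi-implicit Euler at `dt`, with the velocity-dependent
#' resistance included by default and velocities clamped at zero) and scores
#' the trajectory by summed squared deviation from the desired velocity plus
#' summed squared input: `sum_k (v_k - v_d)^2 + sum_k a^2` over the
#' `T_horizon / dt` steps after the current instant. Collision avoidance is
#' deliberately absent from the cost; safety enters the planner only as a
#' risk constraint.
#'
#' @param a Constant control input, m/s^2 (vectorized).
#' @param state Ego state: list with `s` (m) and `v` (m/s).
#' @param v_d Desired velocity, m/s.
#' @param params A [cei_params()] list.
#' @return Dimensionless cost (same length as `a`).
#' @export
#' @examples
#' p <- cei_params(include_resistance_in_rollout = FALSE)
#' plan_cost(0, list(s = 0, v = 10), v_d = 10, params = p) # 0
plan_cost <- function(a, state, v_d, params = cei_params()) {
  n <- round(params$T_horizon / params$dt)
  vapply(a, function(ai) {
    v <- cpp_rollout_vel(state$v, ai, n, params$dt,
                         params$include_resistance_in_rollout)
    sum((v - v_d)^2) + n * ai^2
  }, numeric(1))
}

new_plan <- function(a, state, params, origin, created_at = state$t %||% 0) {
  n <- round(params$T_horizon / params$dt)
  v <- cpp_rollout_vel(state$v, a, n, params$dt,
                       params$include_resistance_in_rollout)
  s <- state$s + cumsum(v) * params$dt
  structure(list(
    a_planned = a, a_executed = a, created_at = created_at,
    s_at_creation = state$s, v_at_creation = state$v,
    waypoints = s, velocities = v, origin = origin
  ), class = "cei_plan")
}

#' Ego positions at the belief lead times under a plan
#'
#' Predicts the ego vehicle's front-bumper positions at every belief point
#' lead time (`1/fb, ..., T_horizon`), starting from a given current state
#' and applying the plan's constant planned input with the same rollout
#' dynamics used by the planner. This is the ego trajectory the perceived
#' risk is evaluated against.
#'
#' @param plan A `cei_plan` (from [optimize_plan()], [fallback_plan()], or
#'   internally created).
#' @param state Current ego state: list with `s` and `v`.
#' @param params A [cei_params()] list.
#' @return Numeric vector of positions, one per belief point.
#' @export
plan_positions <- function(plan, state, params = cei_params()) {
  n <- round(params$T_horizon / params$dt)
  stride <- round(1 / (params$dt * params$fb))
  cpp_rollout_pos(state$s, state$v, plan$a_planned, n, params$dt, stride,
                  params$include_resistance_in_rollout)
}

# vectorized candidate evaluation: cost and risk for a grid of inputs
scan_candidates <- function(a_grid, state, v_d, bel, params, track, risk_fn) {
  n <- round(params$T_horizon / params$dt)
  stride <- round(1 / (params$dt * params$fb))
  if (!is.null(risk_fn)) {
    cost <- plan_cost(a_grid, state, v_d, params)
    risk <- vapply(a_grid, function(ai) {
      risk_fn(cpp_rollout_pos(state$s, state$v, ai, n, params$dt, stride,
                              params$include_resistance_in_rollout))
    }, numeric(1))
    return(list(cost = cost, risk = risk))
  }
  cpp_plan_scan(state$s, state$v, a_grid, n, params$dt, v_d, stride,
                params$include_resistance_in_rollout,
                bel$mu, bel$sigma, params$phi,
                track$merge_point - track$vehicle_length,
                track$vehicle_length, params$risk_aggregation == "max")
}

#' Optimize a constant-acceleration plan under a risk cap
#'
#' Finds the constant control input in `[-a_max, a_max]` minimizing
#' [plan_cost()] subject to the perceived risk of the candidate rollout not
#' exceeding `risk_cap`. Because the decision variable is a single scalar,
#' the solver is a deterministic two-stage grid scan: a 401-point coarse scan
#' over the full input range followed by a 1e-4-resolution refinement around
#' the best feasible candidate (falling back to a full 1e-3 sweep before
#' declaring infeasibility). The result matches a 1e-3-step brute-force grid
#' minimizer to within 1e-3 m/s^2.
#'
#' @param state Ego state: list with `s`, `v` (and optionally `t`).
#' @param belief A belief tibble from [project_belief()] (ignored when a
#'   custom `risk_fn` is supplied).
#' @param risk_cap Maximum admissible perceived risk, in \[0, 1\]; 1 makes
#'   the constraint inactive.
#' @param v_d Desired velocity, m/s.
#' @param params A [cei_params()] list.
#' @param track A [track_geometry()].
#' @param risk_fn Optional function mapping a vector of ego positions at the
#'   belief lead times to a scalar risk, replacing the internal
#'   mixture-belief evaluation.
#' @return A `cei_plan`. If no input satisfies the risk cap, an error
#'   condition of class `cei_infeasible` is signalled; callers respond with
#'   [fallback_plan()].
#' @export
optimize_plan <- function(state, belief, risk_cap, v_d,
                          params = cei_params(), track = track_geometry(),
                          risk_fn = NULL) {
  stopifnot(risk_cap >= 0, risk_cap <= 1)
  a_max <- params$a_max
  tol <- 1e-12
  coarse <- seq(-a_max, a_max, length.out = 401L)
  sc <- scan_candidates(coarse, state, v_d, belief, params, track, risk_fn)
  feasible <- sc$risk <= risk_cap + tol
  if (!any(feasible)) {
    fine_all <- seq(-a_max, a_max, by = 1e-3)
    sc_all <- scan_candidates(fine_all, state, v_d, belief, params, track,
                              risk_fn)
    feas_all <- sc_all$risk <= risk_cap + tol
    if (!any(feas_all)) {
      rlang::abort("no constant input satisfies the risk cap",
                   class = "cei_infeasible")
    }
    best <- fine_all[feas_all][which.min(sc_all$cost[feas_all])]
    return(new_plan(best, state, params, origin = "optimized"))
  }
  a0 <- coarse[feasible][which.min(sc$cost[feasible])]
  step <- coarse[2] - coarse[1]
  fine <- seq(max(-a_max, a0 - 1.1 * step), min(a_max, a0 + 1.1 * step),
              by = 1e-4)
  sf <- scan_candidates(fine, state, v_d, belief, params, track, risk_fn)
  feas_f <- sf$risk <= risk_cap + tol
  if (!any(feas_f)) { # numerical edge: keep the coarse solution
    return(new_plan(a0, state, params, origin = "optimized"))
  }
  a_best <- fine[feas_f][which.min(sf$cost[feas_f])]
  new_plan(a_best, state, params, origin = "optimized")
}

#' Fallback plan when no feasible input exists
#'
#' When the constrained optimization is infeasible, the driver resorts to an
#' extreme open-loop action: full braking when behind the other vehicle
#' (heading for a collision from the rear) and full acceleration when ahead.
#' Equal positions are treated as being behind (brake), the conservative
#' choice. A fresh optimization is attempted at the next time step.
#'
#' @param state Ego state: list with `s`, `v` (and optionally `t`).
#' @param other_position Observed front-bumper position of the other
#'   vehicle, m.
#' @param params A [cei_params()] list.
#' @return A `cei_plan` with `origin = "fallback"`.
#' @export
#' @examples
#' fallback_plan(list(s = 60, v = 10), other_position = 70)$a_planned # -2
fallback_plan <- function(state, other_position, params = cei_params()) {
  a <- if (state$s <= other_position) -params$a_max else params$a_max
  new_plan(a, state, params, origin = "fallback")
}

#' Add frozen execution noise to a plan
#'
#' The executed input is the planned one plus a single normal draw
#' representing the discrepancy between the intended acceleration and the
#' realized pedal input; the draw is made once per (re)plan and stays
#' constant until the next replan.
#'
#' @param plan A `cei_plan`.
#' @param noise_sd Execution-noise standard deviation, m/s^2 (see
#'   [execution_noise_sd()]); 0 leaves the plan unchanged.
#' @return The plan with `a_executed` set.
#' @export
perturb_plan <- function(plan, noise_sd) {
  stopifnot(noise_sd >= 0)
  plan$a_executed <- plan$a_planned +
    (if (noise_sd > 0) rnorm(1L, 0, noise_sd) else 0)
  plan
}
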