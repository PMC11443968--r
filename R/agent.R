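#' Create a CEI driver agent
#'
#' A driver agent holds the per-driver state of the CEI model: the perceived
#' velocity of the other vehicle, the acceleration-observation memory, the
#' current constant-acceleration plan, and the below-lower-threshold timer.
#' Agents are mutable environments; [agent_observe()] and [agent_step()]
#' update them in place as the coupled simulation advances.
#'
#' @param side `"left"` or `"right"`.
#' @param thresholds A [risk_thresholds()] object.
#' @param v_initial Initial (and desired) velocity, m/s.
#' @param params A [cei_params()] list.
#' @param track A [track_geometry()].
#' @param noisy Enable perception and execution noise? `FALSE` makes the
#'   agent fully deterministic (used by the calibration grid and the
#'   noise-off tests).
#' @return An environment of class `cei_agent`.
#' @export
new_agent <- function(side, thresholds, v_initial = 10,
                      params = cei_params(), track = track_geometry(),
                      noisy = TRUE) {
  side <- match.arg(side, c("left", "right"))
  a <- new.env(parent = emptyenv())
  a$side <- side
  a$th <- thresholds
  a$params <- params
  a$track <- track
  a$v_d <- v_initial
  a$v_initial <- v_initial
  a$beta <- if (noisy) params$beta else 0
  a$noise_sd <- if (noisy) execution_noise_sd(params) else 0
  a$mem_len <- round(params$Tm / params$dt)
  a$mem <- 0            # seeded with one zero-acceleration observation
  a$vp <- NA_real_      # initialized from the first observation
  a$plan <- NULL
  a$below_since <- NA_real_
  a$pending <- NULL     # trigger type being retried after a fallback
  a$prev_v <- v_initial
  a$obs <- NULL
  class(a) <- "cei_agent"
  a
}

#' Update an agent's perception of the other vehicle
#'
#' Feeds one observation of the other vehicle's public state into the agent:
#' the perceived velocity is updated by noisy evidence accumulation and the
#' observed (net) acceleration is appended to the memory buffer, evicting
#' entries older than `Tm`. Perception runs from the first tunnel instant on,
#' so the perceived velocity has reached its stationary noise distribution by
#' the time control begins.
#'
#' @param agent A `cei_agent`.
#' @param s,v,a_net The other vehicle's front-bumper position (m), true
#'   velocity (m/s), and realized net acceleration (m/s^2).
#' @return The agent, invisibly.
#' @export
agent_observe <- function(agent, s, v, a_net) {
  if (is.na(agent$vp)) {
    agent$vp <- v # perceived velocity starts at the true initial velocity
  } else {
    agent$vp <- update_perceived_velocity(agent$vp, v, agent$params$alpha,
                                          agent$beta, agent$params$dt)
  }
  m <- c(agent$mem, a_net)
  if (length(m) > agent$mem_len) m <- m[(length(m) - agent$mem_len + 1):length(m)]
  agent$mem <- m
  agent$obs <- list(s = s, v = v)
  invisible(agent)
}

# attempt an optimization; on infeasibility return a fallback plan and record
# the trigger being retried
try_replan <- function(agent, ego, bel, cap, trigger) {
  plan <- tryCatch(
    optimize_plan(list(s = ego$s, v = ego$v, t = ego$t), bel, cap,
                  agent$v_d, agent$params, agent$track),
    cei_infeasible = function(e) NULL
  )
  if (is.null(plan)) {
    agent$pending <- trigger
    plan <- fallback_plan(list(s = ego$s, v = ego$v, t = ego$t),
                          agent$obs$s, agent$params)
    event <- "fallback"
  } else {
    agent$pending <- NULL
    event <- trigger
  }
  agent$plan <- perturb_plan(plan, agent$noise_sd)
  agent$plan$created_at <- ego$t
  event
}

trigger_cap <- function(trigger, rho_l, rho_u) {
  switch(trigger,
         upper = 0.8 * rho_l,
         relax = 0.6 * rho_u,
         vd_reached = 1,
         initial = 1)
}

#' Advance an agent one control step
#'
#' The replanning state machine, run once per time step while the agent has
#' control (past the tunnel). Requires [agent_observe()] to have been called
#' for this step. The agent projects its belief, evaluates the perceived
#' collision risk of its current plan from its current state, updates the
#' dynamic thresholds, and then replans if (in priority order) the risk
#' exceeds the upper threshold (risk cap `0.8 rho_l`), the risk has stayed
#' below the lower threshold for at least the saturation time `tau` (cap
#' `0.6 rho_u`), or the desired velocity is reached while a nonzero input is
#' being applied. Infeasible optimizations fall back to full braking (behind)
#' or full acceleration (ahead), retried every subsequent step.
#'
#' @param agent A `cei_agent`.
#' @param ego Current ego state: list with `s` (m), `v` (m/s), `t` (s).
#' @return A list: `input` (executed acceleration, m/s^2), `risk` (perceived
#'   risk of the plan held when entering the step), `rho_l`, `rho_u`, and
#'   `event` (`"none"`, `"initial"`, `"upper"`, `"relax"`, `"vd_reached"`, or
#'   `"fallback"`).
#' @export
agent_step <- function(agent, ego) {
  params <- agent$params
  obs <- agent$obs
  ea <- expected_acceleration(agent$mem, params$ac)
  bel <- belief_project(obs$s, agent$vp, ea$mu_a, ea$var_a, params)

  cov <- incentive_covariates(ego$s, ego$v, obs$s, agent$vp,
                              agent$track$merge_point, params)
  rho <- thresholds_fast(agent$th, cov[1], cov[2])
  rho_l <- rho[1]; rho_u <- rho[2]

  event <- "none"
  if (is.null(agent$plan)) {
    # control onset: adopt an unconstrained plan so the first risk
    # evaluation has a concrete trajectory
    event <- try_replan(agent, ego, bel, 1, "initial")
    risk <- plan_risk(agent, ego, bel)
  } else {
    risk <- plan_risk(agent, ego, bel)

    if (!is.null(agent$pending)) {
      # fallback in force: retry the original trigger's optimization
      cap <- trigger_cap(agent$pending, rho_l, rho_u)
      retry <- tryCatch(
        optimize_plan(list(s = ego$s, v = ego$v, t = ego$t), bel, cap,
                      agent$v_d, params, agent$track),
        cei_infeasible = function(e) NULL
      )
      if (!is.null(retry)) {
        event <- agent$pending
        agent$pending <- NULL
        agent$plan <- perturb_plan(retry, agent$noise_sd)
        agent$plan$created_at <- ego$t
      } else if (sign(agent$plan$a_planned) !=
                 (if (ego$s <= obs$s) -1 else 1)) {
        # relative order flipped while infeasible: refresh the fallback
        agent$plan <- perturb_plan(
          fallback_plan(list(s = ego$s, v = ego$v, t = ego$t), obs$s, params),
          agent$noise_sd)
        agent$plan$created_at <- ego$t
        event <- "fallback"
      }
    } else if (risk > rho_u) {
      event <- try_replan(agent, ego, bel, 0.8 * rho_l, "upper")
      agent$below_since <- NA_real_
    } else {
      if (risk < rho_l) {
        if (is.na(agent$below_since)) agent$below_since <- ego$t
        if (ego$t - agent$below_since >= params$tau - 1e-9) {
          event <- try_replan(agent, ego, bel, 0.6 * rho_u, "relax")
          agent$below_since <- NA_real_
        }
      } else {
        agent$below_since <- NA_real_
      }
      if (event == "none" && agent$plan$a_executed != 0) {
        crossed <- (agent$prev_v - agent$v_d) * (ego$v - agent$v_d) < 0
        settled <- abs(ego$v - agent$v_d) < params$vd_tolerance &&
          abs(agent$plan$v_at_creation - agent$v_d) > params$vd_tolerance
        if (crossed || settled) {
          event <- try_replan(agent, ego, bel, 1, "vd_reached")
        }
      }
    }
  }
  agent$prev_v <- ego$v
  list(input = agent$plan$a_executed, risk = risk,
       rho_l = rho_l, rho_u = rho_u, event = event)
}

# incentive-function covariates from the ego driver's perspective: the
# projected headway at the merge point under the current (ego true, other
# perceived) velocities, and the current relative velocity -- the same
# quantities that index the kinematic conditions the incentive coefficients
# are fitted on. Both are clamped to the fitted design support.
incentive_covariates <- function(s_e, v_e, s_o, v_o, merge_point, params) {
  t_e <- if (v_e > 1e-6 && s_e < merge_point) (merge_point - s_e) / v_e else
    if (s_e >= merge_point) 0 else Inf
  t_o <- if (v_o > 1e-6 && s_o < merge_point) (merge_point - s_o) / v_o else
    if (s_o >= merge_point) 0 else Inf
  t_arr <- min(t_e, t_o)
  if (!is.finite(t_arr)) t_arr <- 0
  dp <- (s_e - s_o) + (v_e - v_o) * t_arr
  dv <- v_e - v_o
  c(max(-params$incentive_dp_max, min(params$incentive_dp_max, dp)),
    max(-params$incentive_dv_max, min(params$incentive_dv_max, dv)))
}

# perceived risk of the agent's current plan: the ego positions are the
# plan's own waypoints (rolled out from the state at plan creation under the
# planned, noise-free input), read at the current belief lead times. The
# driver believes they are on-plan; drift accumulated through execution
# noise goes unnoticed until a replan re-anchors the plan, which is the
# model's mechanism for occasional collisions.
plan_risk <- function(agent, ego, bel) {
  params <- agent$params
  stride <- round(1 / (params$dt * params$fb))
  n_points <- round(params$T_horizon * params$fb)
  base <- round((ego$t - agent$plan$created_at) / params$dt)
  need <- base + n_points * stride
  wp <- agent$plan$waypoints
  if (length(wp) < need) {
    wp <- cpp_rollout_pos(agent$plan$s_at_creation, agent$plan$v_at_creation,
                          agent$plan$a_planned, max(need, 2 * length(wp)),
                          params$dt, 1L, params$include_resistance_in_rollout)
    agent$plan$waypoints <- wp
  }
  pos <- wp[base + seq_len(n_points) * stride]
  track <- agent$track
  p <- risk_per_point(pos, bel$mu, bel$sigma, params$phi, track)
  risk_aggregate(p, params$risk_aggregation)
}
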