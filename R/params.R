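#' Model and simulation parameters
#'
#' Bundles the fixed, manually designed constants of the CEI merging model and
#' the simulation it runs in. The defaults are the values used throughout:
#' a 6 s planning/belief horizon sampled at 4 belief points per second, a 4 s
#' acceleration memory, evidence-accumulation velocity perception with update
#' rate 0.5 per step and Wiener noise level 0.6, a comfortable acceleration of
#' 1 m/s^2 (so that +/- a_c covers 99.7% of expected accelerations), belief
#' variance scaling 3, saturation time 1.6 s, and an execution-noise scale
#' parameter of 140 (see [execution_noise_sd()] for the mapping to m/s^2).
#'
#' @param dt Simulation time step, s.
#' @param T_horizon Planning and belief horizon, s.
#' @param Tm Memory span for acceleration observations, s.
#' @param fb Belief frequency, belief points per second of the horizon.
#' @param sigma_n Execution-noise scale parameter (dimensionless as printed;
#'   converted to a standard deviation in m/s^2 by [execution_noise_sd()]).
#' @param beta Velocity-perception noise level.
#' @param tau Saturation time, s: how long perceived risk must stay below the
#'   lower threshold before a relaxation replan fires.
#' @param phi Variance scaling of the wide belief component.
#' @param alpha Velocity-perception update rate per time step.
#' @param ac Maximum comfortable acceleration, m/s^2.
#' @param a_max Control input bound, m/s^2 (full braking/acceleration).
#' @param v_desired Desired velocity, m/s; per driver this equals the initial
#'   velocity and is overridden per trial.
#' @param belief_sigma_mode How the lead time scales the belief width:
#'   `"sd"` (default) sets the belief point's position standard deviation to
#'   half the squared lead time times the acceleration standard deviation
#'   (exact propagation of a constant random acceleration, matching the
#'   kinematic mean formula); `"variance"` applies the same factor to the
#'   variance instead, giving much narrower beliefs at long lead times.
#' @param risk_aggregation `"max"` (default) or `"sum"` (capped at 1) over
#'   belief points.
#' @param include_resistance_in_rollout Should the planner's internal rollout
#'   include the velocity-dependent resistance (default `TRUE`, matching the
#'   executed dynamics)?
#' @param vd_tolerance Velocity tolerance, m/s, for the desired-velocity
#'   replanning trigger.
#' @param incentive_dp_max,incentive_dv_max Saturation of the incentive
#'   covariates, m and m/s. The incentive coefficients are fitted on the
#'   kinematic design (projected headways within +/-4 m, relative velocities
#'   within +/-0.8 m/s); the covariates fed to the incentive function are
#'   clamped to that support so the fitted linear model is never
#'   extrapolated far outside it.
#'
#' @return A list of class `cei_params`.
#' @export
#' @examples
#' p <- cei_params()
#' p$T_horizon * p$fb # number of belief points
cei_params <- function(dt = 0.05, T_horizon = 6.0, Tm = 4.0, fb = 4,
                       sigma_n = 140, beta = 0.6, tau = 1.6, phi = 3.0,
                       alpha = 0.5, ac = 1.0, a_max = 2.0, v_desired = 10,
                       belief_sigma_mode = c("sd", "variance"),
                       risk_aggregation = c("max", "sum"),
                       include_resistance_in_rollout = TRUE,
                       vd_tolerance = 0.01,
                       incentive_dp_max = 4, incentive_dv_max = 0.8) {
  stopifnot(dt > 0, T_horizon > 0, Tm > 0, fb > 0, alpha > 0, alpha <= 1,
            beta >= 0, tau >= 0, phi >= 1, ac > 0, a_max > 0)
  stride <- 1 / (dt * fb)
  if (abs(stride - round(stride)) > 1e-9) {
    stop("1/(dt*fb) must be an integer number of simulation steps", call. = FALSE)
  }
  structure(list(
    dt = dt, T_horizon = T_horizon, Tm = Tm, fb = fb,
    sigma_n = sigma_n, beta = beta, tau = tau, phi = phi,
    alpha = alpha, ac = ac, a_max = a_max, v_desired = v_desired,
    belief_sigma_mode = match.arg(belief_sigma_mode),
    risk_aggregation = match.arg(risk_aggregation),
    include_resistance_in_rollout = include_resistance_in_rollout,
    vd_tolerance = vd_tolerance,
    incentive_dp_max = incentive_dp_max, incentive_dv_max = incentive_dv_max
  ), class = "cei_params")
}

#' Execution-noise standard deviation
#'
#' Maps the printed execution-noise scale parameter `sigma_n` to a standard
#' deviation in physical units. The scale parameter is dimensionless; the
#' adopted mapping divides by 1000, giving 0.14 m/s^2 for the default 140 --
#' a plausible motor-noise magnitude relative to the 1 m/s^2 comfortable
#' acceleration. The mapping is isolated here so alternative scalings can be
#' swapped in one place.
#'
#' @param params A [cei_params()] list.
#' @return Standard deviation of the frozen execution noise, m/s^2.
#' @export
execution_noise_sd <- function(params) params$sigma_n / 1000

#' Merging track geometry
#'
#' The simplified merging track: two approach roads that join at a single
#' merge point, preceded by a tunnel and followed by a car-following section.
#' The three sections have equal length by default (50 m each, 150 m total),
#' and the merge point sits at the tunnel + approach distance. Vehicles are
#' point masses; their rectangular dimensions are used only for collision
#' detection.
#'
#' @param tunnel_length,approach_length,follow_length Section lengths, m.
#' @param vehicle_length,vehicle_width Vehicle dimensions, m.
#' @return A list of class `cei_track` with the section lengths, the derived
#'   `merge_point` and `total_length`, and the vehicle dimensions.
#' @export
#' @examples
#' track_geometry()$merge_point # 100
track_geometry <- function(tunnel_length = 50, approach_length = 50,
                           follow_length = 50, vehicle_length = 4.5,
                           vehicle_width = 1.8) {
  stopifnot(tunnel_length > 0, approach_length > 0, follow_length > 0,
            vehicle_length > 0, vehicle_width > 0)
  structure(list(
    tunnel_length = tunnel_length,
    approach_length = approach_length,
    follow_length = follow_length,
    merge_point = tunnel_length + approach_length,
    total_length = tunnel_length + approach_length + follow_length,
    vehicle_length = vehicle_length,
    vehicle_width = vehicle_width
  ), class = "cei_track")
}

#' Read and write scenario configuration files
#'
#' A plain-text (YAML) configuration with `track`, `sim`, and `conditions`
#' sections. Every fixed model constant and the track geometry can be
#' overridden; conditions are given as label strings (see [condition()]).
#'
#' @param path File path.
#' @return `read_cei_config()` returns a list with elements `params`
#'   ([cei_params]), `track` ([track_geometry]) and `conditions` (tibble).
#' @export
read_cei_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  params <- do.call(cei_params, cfg$sim %||% list())
  track <- do.call(track_geometry, cfg$track %||% list())
  conditions <- if (is.null(cfg$conditions)) {
    default_conditions()
  } else {
    purrr::map_dfr(cfg$conditions, condition)
  }
  list(params = params, track = track, conditions = conditions)
}

#' @rdname read_cei_config
#' @param params,track,conditions Components to serialize; defaults are used
#'   for any left `NULL`.
#' @export
write_cei_config <- function(path, params = cei_params(),
                             track = track_geometry(),
                             conditions = default_conditions()) {
  sim <- unclass(params)
  trk <- unclass(track)[c("tunnel_length", "approach_length", "follow_length",
                          "vehicle_length", "vehicle_width")]
  yaml::write_yaml(
    list(track = trk, sim = sim, conditions = as.list(conditions$label)),
    path
  )
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
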