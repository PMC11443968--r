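#' Velocity-dependent resistance
#'
#' Deceleration a vehicle experiences from rolling and air resistance,
#' `0.5 + 0.005 v^2` m/s^2. Strictly increasing in velocity, so a constant
#' positive input has a stable equilibrium speed.
#'
#' @param v Velocity, m/s (non-negative).
#' @return Deceleration magnitude, m/s^2.
#' @export
#' @examples
#' resistance(10) # 1.0
resistance <- function(v) {
  if (any(v < 0)) stop("resistance() requires non-negative velocity", call. = FALSE)
  0.5 + 0.005 * v^2
}

#' Advance a vehicle state one time step
#'
#' Semi-implicit Euler update of a point-mass vehicle: the velocity is updated
#' first from the applied input minus resistance (clamped at zero -- velocities
#' are always non-negative), then the position advances with the new velocity.
#' Inside the tunnel the vehicle has no control authority and travels at
#' exactly constant velocity (resistance is compensated and the input ignored).
#'
#' @param state A list or one-row data frame with `s` (front-bumper position,
#'   m), `v` (velocity, m/s), `t` (time, s).
#' @param input Applied control input, m/s^2.
#' @param dt Time step, s.
#' @param in_tunnel Is the vehicle still inside the tunnel?
#' @return A tibble row with the updated `s`, `v`, `a_input`, `t`.
#' @export
#' @examples
#' step_vehicle(list(s = 0, v = 10, t = 0), input = 1, dt = 0.05, in_tunnel = FALSE)
step_vehicle <- function(state, input, dt, in_tunnel = FALSE) {
  stopifnot(dt > 0)
  if (in_tunnel) {
    v_new <- state$v
    a_rec <- 0
  } else {
    v_new <- max(0, state$v + (input - resistance(state$v)) * dt)
    a_rec <- input
  }
  tibble::tibble(s = state$s + v_new * dt, v = v_new, a_input = a_rec,
                 t = state$t + dt)
}

#' Kinematic conditions
#'
#' A condition is a cell of the merging scenario's kinematic design: the
#' projected headway the two vehicles would have at the merge point if both
#' kept their initial velocity, and the initial relative velocity. Positive
#' values denote an advantage for the left driver. Labels follow the
#' `<headway>_<relative velocity x 10>` convention, e.g. `"4_-8"` is a 4 m
#' projected headway with a 0.8 m/s velocity advantage for the right driver.
#'
#' @param label A condition label, or `NULL` when `projected_headway` and
#'   `relative_velocity` are given directly.
#' @param projected_headway Front-bumper-to-front-bumper distance at the merge
#'   point under constant initial velocities, m.
#' @param relative_velocity Initial velocity of the left minus the right
#'   vehicle, m/s.
#' @return A one-row tibble with `label`, `projected_headway`,
#'   `relative_velocity`.
#' @export
#' @examples
#' condition("4_-8")
#' condition(projected_headway = 0, relative_velocity = 0.8)
condition <- function(label = NULL, projected_headway = NULL,
                      relative_velocity = NULL) {
  if (!is.null(label)) {
    parts <- strsplit(label, "_", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed condition label: ", label, call. = FALSE)
    projected_headway <- as.numeric(parts[1])
    relative_velocity <- as.numeric(parts[2]) / 10
    if (anyNA(c(projected_headway, relative_velocity))) {
      stop("malformed condition label: ", label, call. = FALSE)
    }
  } else {
    label <- condition_label(projected_headway, relative_velocity)
  }
  tibble::tibble(label = label, projected_headway = projected_headway,
                 relative_velocity = relative_velocity)
}

condition_label <- function(projected_headway, relative_velocity) {
  paste0(format(projected_headway, trim = TRUE), "_",
         format(round(relative_velocity * 10), trim = TRUE))
}

#' Default condition set
#'
#' The 11 kinematic conditions of the merging study: all five projected
#' headways (-4, -2, 0, 2, 4 m) at equal initial velocities, and the three
#' headways -4, 0, 4 m combined with a +/-0.8 m/s relative velocity. Every
#' cell ends in a collision if both vehicles keep their initial velocity
#' (all projected headways are smaller than the 4.5 m vehicle length).
#'
#' @return A tibble with 11 rows: `label`, `projected_headway`,
#'   `relative_velocity`.
#' @export
#' @examples
#' default_conditions()
default_conditions <- function() {
  dplyr::bind_rows(
    purrr::map_dfr(c(-4, -2, 0, 2, 4), ~condition(projected_headway = .x,
                                                  relative_velocity = 0)),
    purrr::map_dfr(c(-4, 0, 4), ~condition(projected_headway = .x,
                                           relative_velocity = -0.8)),
    purrr::map_dfr(c(-4, 0, 4), ~condition(projected_headway = .x,
                                           relative_velocity = 0.8))
  )
}

#' Initial vehicle states for a condition
#'
#' Places the two vehicles so that, under constant initial velocities, the
#' front-to-front distance at the instant the first vehicle reaches the merge
#' point equals the condition's projected headway. Initial velocities are
#' 10 m/s for both vehicles, or 10.4 and 9.6 m/s when the condition specifies
#' a 0.8 m/s advantage. The slower (or, at equal speeds, the disadvantaged)
#' vehicle starts at `s = 0`; the other vehicle's start offset is solved
#' analytically and may be negative, conceptually extending the tunnel
#' backwards.
#'
#' @param cond A one-row condition tibble (see [condition()]).
#' @param track A [track_geometry()].
#' @return A two-row tibble (`side`, `s`, `v`, `t`).
#' @export
#' @examples
#' initial_states(condition("0_8"))
initial_states <- function(cond, track = track_geometry()) {
  h <- cond$projected_headway
  dv <- cond$relative_velocity
  m <- track$merge_point
  v_l <- if (dv > 0) 10.4 else if (dv < 0) 9.6 else 10
  v_r <- if (dv > 0) 9.6 else if (dv < 0) 10.4 else 10
  if (v_l == v_r) {
    # constant distance h at all times; the disadvantaged vehicle is the
    # reference at s = 0 (keeps mirrored conditions exact swaps)
    if (h >= 0) { s_l <- h; s_r <- 0 } else { s_l <- 0; s_r <- -h }
  } else if (v_l > v_r) {
    # right is slower: right at s = 0, solve the left offset c so that the
    # front-to-front distance is h when the first front bumper reaches m
    s_r <- 0
    s_l <- if (h >= 0) {
      m - v_l * (m - h) / v_r   # left arrives first, at t = (m - h)/v_r
    } else {
      h + m - v_l * m / v_r     # right arrives first, at t = m/v_r
    }
  } else {
    # left is slower: left at s = 0, solve the right offset
    s_l <- 0
    s_r <- if (h <= 0) {
      m - v_r * (m + h) / v_l   # right arrives first, at t = (m + h)/v_l
    } else {
      m - h - v_r * m / v_l     # left arrives first, at t = m/v_l
    }
  }
  out <- tibble::tibble(side = c("left", "right"), s = c(s_l, s_r),
                        v = c(v_l, v_r), t = 0)
  # verify the solve by constant-velocity projection to first merge arrival
  t_star <- min((m - out$s) / out$v)
  gap <- (out$s[1] + out$v[1] * t_star) - (out$s[2] + out$v[2] * t_star)
  if (abs(gap - h) > 1e-6) {
    stop("initial_states(): no consistent placement for condition ",
         cond$label, call. = FALSE)
  }
  out
}

#' Collision detection
#'
#' The two approach roads share a corridor only within one vehicle length of
#' the merge point and beyond it. Two vehicles collide when both front bumpers
#' are past `merge_point - vehicle_length` and the along-track front-bumper
#' distance is smaller than one vehicle length.
#'
#' @param s_left,s_right Front-bumper positions, m.
#' @param track A [track_geometry()].
#' @return Logical.
#' @export
#' @examples
#' detect_collision(101, 97) # TRUE
detect_collision <- function(s_left, s_right, track = track_geometry()) {
  L <- track$vehicle_length
  pmin(s_left, s_right) > track$merge_point - L & abs(s_left - s_right) < L
}
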