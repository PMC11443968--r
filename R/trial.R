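#' Simulate one dyadic merging trial
#'
#' Runs the coupled two-driver simulation for one kinematic condition: both
#' vehicles traverse the tunnel at constant velocity while the drivers'
#' velocity perception develops, then each driver gains control of their
#' acceleration as their front bumper passes the tunnel exit and the CEI
#' replanning state machine takes over. The trial ends when both vehicles
#' have left the track, on a collision, or at `max_duration`. Both agents
#' update synchronously from the previous step's public states, and a fixed
#' seed makes the whole trial bit-reproducible.
#'
#' @param cond A one-row condition tibble (see [condition()]).
#' @param thresholds_left,thresholds_right [risk_thresholds()] for the two
#'   drivers.
#' @param seed Integer seed for the trial's noise draws; `NULL` leaves the
#'   RNG state untouched.
#' @param params A [cei_params()] list.
#' @param track A [track_geometry()].
#' @param noisy Enable perception and execution noise?
#' @param constant_side `NULL` (both drivers are CEI agents) or `"left"`/
#'   `"right"` to replace that driver with a vehicle that simply holds its
#'   initial velocity (used by the calibration grid).
#' @param stop_after_onset If not `NULL`, stop this many seconds after the
#'   first CEI driver gains control (calibration probes only need ~1 s).
#' @param max_duration Hard cap on simulated time, s.
#' @return A list of class `cei_trial`: the condition, seed, a per-timestep
#'   `log` tibble (time, and per driver: position, velocity, executed input,
#'   perceived risk, dynamic thresholds, replan event), control-onset times,
#'   and an `outcome` list from [trial_metrics()].
#' @export
#' @examples
#' th <- driver_thresholds()[5:6, ]
#' tr <- run_trial(condition("0_0"),
#'                 risk_thresholds(th$theta_l[1], th$theta_u[1]),
#'                 risk_thresholds(th$theta_l[2], th$theta_u[2]),
#'                 seed = 1)
#' tr$outcome$who_first
run_trial <- function(cond, thresholds_left, thresholds_right, seed = NULL,
                      params = cei_params(), track = track_geometry(),
                      noisy = TRUE, constant_side = NULL,
                      stop_after_onset = NULL, max_duration = 60) {
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  init <- initial_states(cond, track)
  dt <- params$dt
  n_max <- ceiling(max_duration / dt)

  v_init <- init$v
  agents <- list(left = NULL, right = NULL)
  for (k in 1:2) {
    side <- init$side[k]
    if (is.null(constant_side) || constant_side != side) {
      th <- if (side == "left") thresholds_left else thresholds_right
      agents[[side]] <- new_agent(side, th, v_initial = v_init[k],
                                  params = params, track = track,
                                  noisy = noisy)
    }
  }

  s <- init$s; v <- init$v
  prev_v <- v
  n_alloc <- n_max + 1
  S <- matrix(NA_real_, n_alloc, 2); V <- matrix(NA_real_, n_alloc, 2)
  A <- matrix(0, n_alloc, 2); RISK <- matrix(NA_real_, n_alloc, 2)
  RU <- matrix(NA_real_, n_alloc, 2); RL <- matrix(NA_real_, n_alloc, 2)
  EV <- matrix("none", n_alloc, 2)
  S[1, ] <- s; V[1, ] <- v
  onset <- c(NA_real_, NA_real_)
  collision <- FALSE
  last <- 1

  for (i in seq_len(n_max)) {
    t_now <- (i - 1) * dt
    a_net <- (v - prev_v) / dt
    # synchronous observation of the other vehicle's public state
    for (k in 1:2) {
      ag <- agents[[init$side[k]]]
      if (!is.null(ag)) {
        o <- if (k == 1) 2 else 1
        agent_observe(ag, s[o], v[o], a_net[o])
      }
    }
    input <- c(0, 0)
    tunnel <- s <= track$tunnel_length
    for (k in 1:2) {
      ag <- agents[[init$side[k]]]
      if (!is.null(ag) && !tunnel[k]) {
        if (is.na(onset[k])) onset[k] <- t_now
        res <- agent_step(ag, list(s = s[k], v = v[k], t = t_now))
        input[k] <- res$input
        RISK[i, k] <- res$risk; RU[i, k] <- res$rho_u; RL[i, k] <- res$rho_l
        EV[i, k] <- res$event
      }
    }
    prev_v <- v
    for (k in 1:2) {
      held <- tunnel[k] || (!is.null(constant_side) &&
                            constant_side == init$side[k])
      if (held) {
        A[i + 1, k] <- 0
      } else {
        v[k] <- max(0, v[k] + (input[k] - resistance(v[k])) * dt)
        A[i + 1, k] <- input[k]
      }
      s[k] <- s[k] + v[k] * dt
    }
    S[i + 1, ] <- s; V[i + 1, ] <- v
    last <- i + 1
    if (detect_collision(s[1], s[2], track)) { collision <- TRUE; break }
    if (all(s > track$total_length)) break
    if (!is.null(stop_after_onset) && any(!is.na(onset)) &&
        (i * dt) >= min(onset, na.rm = TRUE) + stop_after_onset) break
  }

  idx <- seq_len(last)
  log <- tibble::tibble(
    t = (idx - 1) * dt,
    s_left = S[idx, 1], v_left = V[idx, 1], a_left = A[idx, 1],
    risk_left = RISK[idx, 1], rho_u_left = RU[idx, 1], rho_l_left = RL[idx, 1],
    event_left = EV[idx, 1],
    s_right = S[idx, 2], v_right = V[idx, 2], a_right = A[idx, 2],
    risk_right = RISK[idx, 2], rho_u_right = RU[idx, 2],
    rho_l_right = RL[idx, 2], event_right = EV[idx, 2]
  )
  trial <- structure(list(
    condition = cond, seed = seed, log = log, collision = collision,
    onset = setNames(onset, c("left", "right")),
    v_initial = setNames(v_init, c("left", "right")),
    duration = (last - 1) * dt, track = track, params = params
  ), class = "cei_trial")
  trial$outcome <- trial_metrics(trial)
  trial
}

#' @export
print.cei_trial <- function(x, ...) {
  cat("<cei_trial> condition", x$condition$label,
      "| duration", format(x$duration), "s",
      if (x$collision) "| COLLISION" else
        paste("| first:", x$outcome$who_first,
              "gap:", format(round(x$outcome$merge_gap, 2)), "m"), "\n")
  invisible(x)
}

# deterministic per-trial seed below 2^31, mixed from the batch seed and the
# pair/condition/repetition indices so any single trial is reproducible
trial_seed <- function(base_seed, pair_idx, cond_idx, rep_idx) {
  x <- (abs(base_seed) %% 2147483647) * 1000003 +
    pair_idx * 10007 + cond_idx * 101 + rep_idx
  x <- x %% 2147483647
  as.integer((x * 48271) %% 2147483647)
}

#' Simulate a full batch of trials
#'
#' Crosses driver pairs, kinematic conditions, and repetitions into a
#' campaign of dyadic trials (the default population of 9 fitted pairs, 11
#' conditions, and 10 repetitions gives 990 trials), with a deterministic
#' per-trial seed derived from `base_seed`. Outcome metrics are extracted per
#' trial; full per-timestep logs can optionally be kept or streamed to CSV.
#'
#' @param pairs A tibble like [driver_thresholds()]: columns `pair`, `side`,
#'   `theta_l`, `theta_u`.
#' @param conditions A condition tibble (default [default_conditions()]).
#' @param reps Repetitions of each condition per pair.
#' @param base_seed Integer batch seed.
#' @param incentives Incentive coefficients shared by all drivers
#'   (see [incentive_defaults()]); pass zero vectors for the static-threshold
#'   variant.
#' @param params,track,noisy As in [run_trial()].
#' @param keep_log Keep each trial's full log as a list-column?
#' @param out_csv,summary_json Optional paths: stream all per-timestep rows
#'   to one trials CSV, and write the per-trial outcome summary as JSON.
#' @return A tibble of class `cei_batch`, one row per trial: `pair`,
#'   `condition`, `rep`, `seed`, `collision`, `who_first`, `merge_gap`,
#'   signed and absolute velocity-deviation extrema per driver, and
#'   `duration`.
#' @export
run_batch <- function(pairs = driver_thresholds(),
                      conditions = default_conditions(), reps = 10,
                      base_seed = 1, incentives = incentive_defaults(),
                      params = cei_params(), track = track_geometry(),
                      noisy = TRUE, keep_log = FALSE, out_csv = NULL,
                      summary_json = NULL) {
  pair_ids <- unique(pairs$pair)
  rows <- vector("list", length(pair_ids) * nrow(conditions) * reps)
  logs <- if (keep_log) vector("list", length(rows)) else NULL
  if (!is.null(out_csv) && file.exists(out_csv)) file.remove(out_csv)
  ri <- 0L
  for (pi in seq_along(pair_ids)) {
    pd <- pairs[pairs$pair == pair_ids[pi], ]
    th_l <- with(pd[pd$side == "left", ],
                 risk_thresholds(theta_l, theta_u,
                                 incentives$lambda_u, incentives$lambda_l))
    th_r <- with(pd[pd$side == "right", ],
                 risk_thresholds(theta_l, theta_u,
                                 incentives$lambda_u, incentives$lambda_l))
    for (ci in seq_len(nrow(conditions))) {
      cond <- conditions[ci, ]
      for (r in seq_len(reps)) {
        seed <- trial_seed(base_seed, pi, ci, r)
        tr <- run_trial(cond, th_l, th_r, seed = seed, params = params,
                        track = track, noisy = noisy)
        ri <- ri + 1L
        m <- tr$outcome
        rows[[ri]] <- tibble::tibble(
          pair = pair_ids[pi], condition = cond$label, rep = r, seed = seed,
          collision = tr$collision, who_first = m$who_first,
          merge_gap = m$merge_gap,
          max_dev_left = m$max_dev["left"], min_dev_left = m$min_dev["left"],
          max_abs_dev_left = m$max_abs_dev["left"],
          max_dev_right = m$max_dev["right"],
          min_dev_right = m$min_dev["right"],
          max_abs_dev_right = m$max_abs_dev["right"],
          duration = tr$duration
        )
        if (keep_log) logs[[ri]] <- tr$log
        if (!is.null(out_csv)) {
          lg <- dplyr::mutate(tr$log, pair = pair_ids[pi],
                              condition = cond$label, rep = r, seed = seed,
                              .before = 1)
          new_file <- !file.exists(out_csv)
          utils::write.table(lg, out_csv, sep = ",", row.names = FALSE,
                             col.names = new_file, append = !new_file)
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows[seq_len(ri)])
  if (keep_log) out$log <- logs[seq_len(ri)]
  class(out) <- c("cei_batch", class(out))
  attr(out, "base_seed") <- base_seed
  if (!is.null(summary_json)) {
    jsonlite::write_json(dplyr::select(out, -dplyr::any_of("log")),
                         summary_json, digits = NA)
  }
  out
}
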