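#' Behavioral metrics of a single trial
#'
#' Extracts the three-level behavioral measures from a trial record: the
#' joint safety margin (merge gap), the high-level outcome (who merged
#' first), and the control-input statistics (signed and absolute extrema of
#' each driver's deviation from their initial velocity, measured from control
#' onset). Crossing times of the merge point are linearly interpolated
#' between time steps.
#'
#' @param trial A `cei_trial` from [run_trial()].
#' @return A list: `collision`, `who_first` (`"left"`/`"right"`/`NA`),
#'   `merge_gap` (m; `NA` for collision or unfinished trials), `max_dev`,
#'   `min_dev`, `max_abs_dev` (named numeric, m/s), `duration` (s).
#' @export
trial_metrics <- function(trial) {
  log <- trial$log
  track <- trial$track
  cl <- crossing_info(log$t, log$s_left, track$merge_point)
  cr <- crossing_info(log$t, log$s_right, track$merge_point)

  who <- if (is.na(cl$t) && is.na(cr$t)) {
    NA_character_
  } else if (is.na(cr$t) || (!is.na(cl$t) && cl$t < cr$t)) {
    "left"
  } else if (is.na(cl$t) || cr$t < cl$t) {
    "right"
  } else {
    # exact tie: resolved by position at trial end
    n <- nrow(log)
    if (log$s_left[n] >= log$s_right[n]) "left" else "right"
  }

  gap <- NA_real_
  if (!trial$collision && !is.na(cl$t) && !is.na(cr$t)) {
    t_trail <- max(cl$t, cr$t)
    lead_s <- if (cl$t > cr$t) {
      interp_at(log$t, log$s_right, t_trail)
    } else {
      interp_at(log$t, log$s_left, t_trail)
    }
    gap <- max(0, abs(lead_s - track$merge_point) - track$vehicle_length)
  }

  dev <- function(side) {
    on <- trial$onset[side]
    if (is.na(on)) return(c(max = NA_real_, min = NA_real_))
    vv <- log[[paste0("v_", side)]][log$t >= on]
    v0 <- unname(trial$v_initial[side])
    c(max = max(vv) - v0, min = min(vv) - v0)
  }
  dl <- dev("left"); dr <- dev("right")
  max_dev <- c(left = unname(dl["max"]), right = unname(dr["max"]))
  min_dev <- c(left = unname(dl["min"]), right = unname(dr["min"]))
  list(
    collision = trial$collision,
    who_first = who,
    merge_gap = gap,
    max_dev = max_dev,
    min_dev = min_dev,
    max_abs_dev = pmax(abs(max_dev), abs(min_dev)),
    duration = trial$duration
  )
}

# first (interpolated) time a position trace reaches a line
crossing_info <- function(t, s, line) {
  i <- which(s >= line)[1]
  if (is.na(i)) return(list(t = NA_real_))
  if (i == 1) return(list(t = t[1]))
  frac <- (line - s[i - 1]) / (s[i] - s[i - 1])
  list(t = t[i - 1] + frac * (t[i] - t[i - 1]))
}

interp_at <- function(t, s, t0) {
  stats::approx(t, s, xout = t0, rule = 2)$y
}

#' Merge gap (joint safety margin) of a trial
#'
#' The bumper-to-bumper clearance between the vehicles, evaluated at the
#' (interpolated) instant the trailing vehicle's front bumper crosses the
#' merge point: the distance from the leader's front bumper to the merge
#' point minus one vehicle length. Collision trials carry no gap and are
#' signalled as excluded.
#'
#' @param trial A `cei_trial`.
#' @return Clearance in m (non-negative for non-collision trials).
#' @export
merge_gap <- function(trial) {
  if (trial$collision) {
    rlang::abort("collision trial: excluded from gap analysis",
                 class = "cei_collision_excluded")
  }
  trial$outcome$merge_gap
}

#' Which driver merged first
#'
#' The side whose front bumper crossed the merge point at the earlier
#' interpolated time; an exact tie is resolved by the along-track position at
#' the end of the trial.
#'
#' @param trial A `cei_trial`.
#' @return `"left"` or `"right"` (`NA` if no vehicle reached the merge
#'   point).
#' @export
who_first <- function(trial) trial$outcome$who_first

#' Summarize a batch of trials
#'
#' Group-level summaries of the batch outcome measures. Collision trials are
#' excluded from gap and deviation statistics and counted separately per
#' group.
#'
#' @param batch A `cei_batch` tibble from [run_batch()].
#' @param group_by `"condition"` (default: per-condition means, interquartile
#'   ranges, outcome proportions with exact binomial 95% CIs), `"pair"`
#'   (per-pair summaries), or `"driver"` (per pair x side x condition mean
#'   absolute maximum deviation).
#' @return A tibble.
#' @export
batch_summary <- function(batch, group_by = c("condition", "pair", "driver")) {
  group_by <- match.arg(group_by)
  ok <- dplyr::filter(batch, !.data$collision)
  if (group_by == "driver") {
    long <- tidyr::pivot_longer(
      dplyr::select(ok, "pair", "condition",
                    left = "max_abs_dev_left", right = "max_abs_dev_right"),
      c("left", "right"), names_to = "side", values_to = "max_abs_dev")
    out <- dplyr::summarise(
      dplyr::group_by(long, .data$pair, .data$side, .data$condition),
      n = dplyr::n(),
      mean_abs_max_dev = mean(.data$max_abs_dev),
      .groups = "drop")
    return(out)
  }
  g <- if (group_by == "condition") "condition" else "pair"
  empty <- dplyr::anti_join(dplyr::distinct(batch, .data[[g]]),
                            dplyr::distinct(ok, .data[[g]]), by = g)
  if (nrow(empty) > 0) {
    warning("groups with no non-collision trials omitted: ",
            paste(empty[[g]], collapse = ", "))
  }
  out <- dplyr::summarise(
    dplyr::group_by(ok, .data[[g]]),
    n = dplyr::n(),
    mean_gap = mean(.data$merge_gap, na.rm = TRUE),
    gap_q25 = quantile(.data$merge_gap, 0.25, na.rm = TRUE, names = FALSE),
    gap_q75 = quantile(.data$merge_gap, 0.75, na.rm = TRUE, names = FALSE),
    mean_abs_max_dev = mean((.data$max_abs_dev_left +
                               .data$max_abs_dev_right) / 2),
    n_left_first = sum(.data$who_first == "left", na.rm = TRUE),
    .groups = "drop")
  ci <- purrr::map2(out$n_left_first, out$n,
                    ~binom.test(.x, .y)$conf.int)
  out$p_left_first <- out$n_left_first / out$n
  out$p_left_ci_lo <- purrr::map_dbl(ci, 1)
  out$p_left_ci_hi <- purrr::map_dbl(ci, 2)
  coll <- dplyr::summarise(
    dplyr::group_by(batch, .data[[g]]),
    n_collisions = sum(.data$collision), .groups = "drop")
  dplyr::left_join(out, coll, by = g)
}
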