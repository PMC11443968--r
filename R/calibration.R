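#' Threshold grid for calibration
#'
#' The calibration grid: 25 uniformly spaced upper base thresholds in
#' \[0.3, 0.9\] crossed with 25 lower base thresholds in \[0.01, 0.4\]
#' (625 cells; spacing 0.025 and 0.01625). Cells whose lower threshold does
#' not lie strictly below the upper one cannot describe a valid driver and
#' are flagged.
#'
#' @param n Grid points per axis.
#' @param upper_range,lower_range Axis ranges for the upper and lower base
#'   thresholds.
#' @return A tibble with `theta_l`, `theta_u`, `valid`.
#' @export
#' @examples
#' nrow(build_grid()) # 625
build_grid <- function(n = 25, upper_range = c(0.3, 0.9),
                       lower_range = c(0.01, 0.4)) {
  g <- tidyr::expand_grid(
    theta_l = seq(lower_range[1], lower_range[2], length.out = n),
    theta_u = seq(upper_range[1], upper_range[2], length.out = n)
  )
  g$valid <- g$theta_l < g$theta_u
  g
}

# deviation of a single CEI driver's velocity from its initial velocity,
# probed a fixed time after control onset, against a constant-velocity
# opponent
deviation_probe <- function(cond, theta_l, theta_u, side = "left",
                            params = cei_params(), track = track_geometry(),
                            noisy = FALSE, seed = NULL, probe_at = 1.0) {
  th <- risk_thresholds(theta_l, theta_u, lambda_u = c(0, 0, 0),
                        lambda_l = c(0, 0, 0))
  other <- if (side == "left") "right" else "left"
  tr <- run_trial(cond, thresholds_left = th, thresholds_right = th,
                  seed = seed, params = params, track = track, noisy = noisy,
                  constant_side = other, stop_after_onset = probe_at + 0.1)
  onset <- tr$onset[side]
  v <- interp_at(tr$log$t, tr$log[[paste0("v_", side)]], onset + probe_at)
  unname(v - tr$v_initial[side])
}

#' Grid response lookup for one condition
#'
#' For every valid cell of the calibration grid, simulates one deterministic
#' trial of a single CEI driver (incentive functions disabled, all noise
#' disabled) against a vehicle traveling at constant velocity, and records
#' the driver's signed deviation from the initial velocity 1.0 s after
#' control onset. This captures the driver's immediate response at the
#' tunnel exit before any interaction takes place.
#'
#' @param cond A one-row condition tibble.
#' @param grid A [build_grid()] tibble.
#' @param side Which side the CEI driver occupies (covariates and advantage
#'   signs follow this driver's perspective).
#' @param params,track As in [run_trial()].
#' @return The grid tibble with a `deviation` column (m/s; `NA` for invalid
#'   cells).
#' @export
grid_response_lookup <- function(cond, grid = build_grid(), side = "left",
                                 params = cei_params(),
                                 track = track_geometry()) {
  grid$deviation <- NA_real_
  idx <- which(grid$valid)
  grid$deviation[idx] <- purrr::map_dbl(
    idx, ~deviation_probe(cond, grid$theta_l[.x], grid$theta_u[.x],
                          side = side, params = params, track = track))
  grid
}

#' Match one observed deviation to a grid cell
#'
#' Finds the grid cell whose simulated 1.0 s velocity deviation is closest to
#' an observed one (signed by default; absolute matching optionally). Ties --
#' ubiquitous for zero-deviation observations, which any sufficiently high
#' threshold explains -- are broken towards the most passive cell: largest
#' `theta_u`, then largest `theta_l`.
#'
#' @param observed_deviation Observed deviation from initial velocity at
#'   1.0 s, m/s.
#' @param lookup A [grid_response_lookup()] result for the trial's condition.
#' @param signed Match signed deviations (`TRUE`, default) or absolute
#'   magnitudes?
#' @return A one-row tibble with the matched `theta_l`, `theta_u`.
#' @export
match_trial_thresholds <- function(observed_deviation, lookup,
                                   signed = TRUE) {
  cand <- lookup[lookup$valid & !is.na(lookup$deviation), ]
  err <- if (signed) {
    abs(cand$deviation - observed_deviation)
  } else {
    abs(abs(cand$deviation) - abs(observed_deviation))
  }
  best <- err <= min(err) + 1e-12
  cand <- cand[best, ]
  cand <- cand[order(-cand$theta_u, -cand$theta_l), ]
  cand[1, c("theta_l", "theta_u")]
}

# condition covariates from a driver's own perspective: positive values are
# an advantage for that driver
perspective_covariates <- function(projected_headway, relative_velocity,
                                   side) {
  sgn <- ifelse(side == "left", 1, -1)
  list(dp = sgn * projected_headway, dv = sgn * relative_velocity)
}

#' Generate synthetic participants' trial deviations
#'
#' Stands in for a human dataset in parameter-recovery studies: each
#' synthetic participant is a CEI driver with known true base thresholds
#' (incentive functions disabled), simulated against a constant-velocity
#' opponent for every condition and repetition, recording the velocity
#' deviation 1.0 s after control onset -- the same quantity the grid matching
#' consumes.
#'
#' @param true_thetas A tibble with `participant`, `side`, `theta_l`,
#'   `theta_u`.
#' @param conditions A condition tibble.
#' @param reps Repetitions per condition.
#' @param seed Base seed for the per-trial noise draws.
#' @param noisy Enable the model's perception/execution noise (`FALSE` gives
#'   identical repetitions).
#' @param params,track As in [run_trial()].
#' @return A tibble: `participant`, `side`, `condition`, `rep`,
#'   `deviation` (m/s).
#' @export
synth_participants <- function(true_thetas,
                               conditions = default_conditions(), reps = 10,
                               seed = 1, noisy = TRUE,
                               params = cei_params(),
                               track = track_geometry()) {
  grid_rows <- tidyr::expand_grid(
    p = seq_len(nrow(true_thetas)),
    ci = seq_len(nrow(conditions)),
    rep = seq_len(reps)
  )
  purrr::pmap_dfr(grid_rows, function(p, ci, rep) {
    tt <- true_thetas[p, ]
    cond <- conditions[ci, ]
    dev <- deviation_probe(cond, tt$theta_l, tt$theta_u, side = tt$side,
                           params = params, track = track, noisy = noisy,
                           seed = trial_seed(seed, p, ci, rep))
    tibble::tibble(participant = tt$participant, side = tt$side,
                   condition = cond$label, rep = rep, deviation = dev)
  })
}

#' Match a deviation dataset against per-condition lookups
#'
#' The trial-level stage of the calibration pipeline: every observed
#' deviation is matched to its condition's grid cell, yielding per-trial
#' base-threshold estimates with the condition covariates expressed from the
#' driver's perspective.
#'
#' @param deviations A tibble like the [synth_participants()] output:
#'   `participant`, `side`, `condition`, `rep`, `deviation`.
#' @param lookups A named list of [grid_response_lookup()] tibbles, one per
#'   condition label appearing in `deviations`.
#' @param signed Passed to [match_trial_thresholds()].
#' @return A tibble of trial-level estimates: `participant`, `side`,
#'   `condition`, `rep`, `deviation`, `theta_l`, `theta_u`, `dp`, `dv`.
#' @export
calibrate_trials <- function(deviations, lookups, signed = TRUE) {
  purrr::pmap_dfr(deviations, function(participant, side, condition, rep,
                                       deviation, ...) {
    lk <- lookups[[condition]]
    if (is.null(lk)) stop("no lookup for condition ", condition, call. = FALSE)
    m <- match_trial_thresholds(deviation, lk, signed = signed)
    cond <- ceimerge::condition(condition)
    cov <- perspective_covariates(cond$projected_headway,
                                  cond$relative_velocity, side)
    tibble::tibble(participant = participant, side = side,
                   condition = condition, rep = rep, deviation = deviation,
                   theta_l = m$theta_l, theta_u = m$theta_u,
                   dp = cov$dp, dv = cov$dv)
  })
}

#' Fit incentive coefficients and participant base thresholds
#'
#' The aggregation stage of the calibration pipeline: two linear
#' mixed-effects models (REML, one per threshold) of the trial-level
#' threshold estimates on the condition covariates,
#' `theta ~ dp * dv + (1 | participant)`. The three fixed-effect slopes
#' (position, velocity, interaction) become the population incentive
#' coefficients; the grand intercept plus each participant's random intercept
#' becomes that participant's base threshold.
#'
#' @param estimates A tibble from [calibrate_trials()] (or assembled
#'   directly) with `participant`, `theta_l`, `theta_u`, `dp`, `dv`. At
#'   least two participants and two distinct conditions are required.
#' @return An object of class `cei_incentive_fit`: list with `lambda_u`,
#'   `lambda_l` (named length-3 vectors), `thetas` (tibble `participant`,
#'   `theta_l`, `theta_u`), the two `lme4` fits (`fit_u`, `fit_l`), and
#'   singularity flags. Supports [tidy()] and [glance()].
#' @export
fit_incentive <- function(estimates) {
  if (length(unique(estimates$participant)) < 2) {
    stop("fit_incentive() needs at least two participants", call. = FALSE)
  }
  if (nrow(unique(estimates[, c("dp", "dv")])) < 2) {
    stop("fit_incentive() needs at least two distinct conditions",
         call. = FALSE)
  }
  fit_one <- function(col) {
    d <- data.frame(theta = estimates[[col]],
                    dp = estimates$dp, dv = estimates$dv,
                    participant = factor(estimates$participant))
    suppressMessages(lme4::lmer(theta ~ dp * dv + (1 | participant),
                                data = d, REML = TRUE,
                                control = lme4::lmerControl(
                                  check.conv.singular = "ignore")))
  }
  fit_u <- fit_one("theta_u")
  fit_l <- fit_one("theta_l")
  lam <- function(fit) {
    fe <- lme4::fixef(fit)
    setNames(fe[c("dp", "dv", "dp:dv")], c("position", "velocity",
                                           "interaction"))
  }
  theta_of <- function(fit) {
    re <- lme4::ranef(fit)$participant
    lme4::fixef(fit)[["(Intercept)"]] + setNames(re[["(Intercept)"]],
                                                 rownames(re))
  }
  th_u <- theta_of(fit_u); th_l <- theta_of(fit_l)
  structure(list(
    lambda_u = lam(fit_u), lambda_l = lam(fit_l),
    thetas = tibble::tibble(participant = names(th_u),
                            theta_l = unname(th_l[names(th_u)]),
                            theta_u = unname(th_u)),
    fit_u = fit_u, fit_l = fit_l,
    singular = c(upper = lme4::isSingular(fit_u),
                 lower = lme4::isSingular(fit_l))
  ), class = "cei_incentive_fit")
}

#' @export
print.cei_incentive_fit <- function(x, ...) {
  cat("<cei_incentive_fit>\n")
  cat("  lambda_u:", paste(signif(x$lambda_u, 3), collapse = " "), "\n")
  cat("  lambda_l:", paste(signif(x$lambda_l, 3), collapse = " "), "\n")
  cat("  participants:", nrow(x$thetas), "\n")
  if (any(x$singular)) cat("  note: singular random-effect fit\n")
  invisible(x)
}
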