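test_that("the calibration grid spans the stated ranges uniformly", {
  g <- build_grid()
  expect_equal(nrow(g), 625)
  expect_equal(min(g$theta_l), 0.01)
  expect_equal(max(g$theta_l), 0.4)
  expect_equal(min(g$theta_u), 0.3)
  expect_equal(max(g$theta_u), 0.9)
  expect_equal(diff(sort(unique(g$theta_u))), rep(0.025, 24))
  expect_equal(diff(sort(unique(g$theta_l))), rep(0.01625, 24))
  expect_true(all((g$theta_l < g$theta_u) == g$valid))
  # corners
  expect_true(any(g$theta_l == 0.01 & g$theta_u == 0.3))
  expect_true(any(g$theta_l == 0.4 & g$theta_u == 0.9))
})

test_that("grid responses are deterministic and passive at high theta_u", {
  g <- build_grid(n = 5)
  cond <- condition("0_0")
  lk1 <- grid_response_lookup(cond, g)
  lk2 <- grid_response_lookup(cond, g)
  expect_identical(lk1, lk2)
  expect_true(all(is.na(lk1$deviation[!lk1$valid])))
  # theta_u = 0.9 cells never trigger within 1 s in this condition: their
  # response equals the passive drag-sag shared by all passive cells
  passive <- lk1$deviation[lk1$valid & lk1$theta_u == 0.9]
  expect_true(all(abs(passive) < 0.15))
  expect_equal(length(unique(round(passive, 10))), 1)
})

test_that("deviation magnitude is non-increasing in theta_u along columns", {
  g <- build_grid(n = 7)
  lk <- grid_response_lookup(condition("0_0"), g)
  for (tl in unique(lk$theta_l)) {
    col <- lk[lk$valid & lk$theta_l == tl, ]
    col <- col[order(col$theta_u), ]
    if (nrow(col) > 1) {
      base <- min(abs(col$deviation))
      dev <- abs(col$deviation) - base
      expect_true(all(diff(dev) <= 1e-9),
                  label = paste("theta_l =", tl))
    }
  }
})

test_that("matching picks the nearest cell with a passive tie-break", {
  lookup <- tibble::tibble(
    theta_l = c(0.1, 0.1, 0.2, 0.2),
    theta_u = c(0.4, 0.6, 0.4, 0.6),
    valid = TRUE,
    deviation = c(-2, 0, -1, 0)
  )
  m <- match_trial_thresholds(-1.1, lookup)
  expect_equal(m$theta_u, 0.4)
  expect_equal(m$theta_l, 0.2)
  # zero deviation is explained by every passive cell: most-passive wins
  m <- match_trial_thresholds(0, lookup)
  expect_equal(m$theta_u, 0.6)
  expect_equal(m$theta_l, 0.2)
  # absolute matching option
  m <- match_trial_thresholds(1.05, lookup, signed = FALSE)
  expect_equal(m$theta_u, 0.4)
  expect_equal(m$theta_l, 0.2)
})

test_that("synthetic participants produce the full trial-deviation schema", {
  tt <- tibble::tibble(participant = c("p1", "p2"),
                       side = c("left", "right"),
                       theta_l = c(0.06, 0.2), theta_u = c(0.45, 0.65))
  conds <- default_conditions()[c(3, 5), ]
  d <- synth_participants(tt, conds, reps = 2, seed = 1, noisy = FALSE)
  expect_equal(nrow(d), 2 * 2 * 2)
  expect_named(d, c("participant", "side", "condition", "rep", "deviation"))
  # noise off: repetitions are identical
  wide <- tidyr::pivot_wider(d, names_from = "rep",
                             values_from = "deviation")
  expect_equal(wide$`1`, wide$`2`)
  # with noise, repetitions differ
  dn <- synth_participants(tt[1, ], conds[1, ], reps = 2, seed = 1,
                           noisy = TRUE)
  expect_false(identical(dn$deviation[1], dn$deviation[2]))
})

test_that("fit_incentive recovers flat condition structure as pure intercepts", {
  conds <- default_conditions()
  est <- tidyr::expand_grid(participant = c("a", "b", "c"),
                            condition = conds$label, rep = 1:3)
  est <- dplyr::left_join(est, conds, by = c(condition = "label"))
  est$dp <- est$projected_headway
  est$dv <- est$relative_velocity
  base <- c(a = 0.4, b = 0.5, c = 0.6)
  est$theta_u <- base[est$participant]
  est$theta_l <- base[est$participant] / 4
  # zero residual variance: lme4 grumbles about convergence on this
  # degenerate (noise-free) input, but the estimates are exact
  fit <- suppressWarnings(fit_incentive(est))
  expect_true(all(abs(fit$lambda_u) < 1e-8))
  expect_true(all(abs(fit$lambda_l) < 1e-8))
  expect_equal(fit$thetas$theta_u[order(fit$thetas$participant)],
               unname(base), tolerance = 1e-6)
})

test_that("fit_incentive matches OLS on a balanced two-participant design", {
  conds <- default_conditions()
  est <- tidyr::expand_grid(participant = c("a", "b"), condition = conds$label)
  est <- dplyr::left_join(est, conds, by = c(condition = "label"))
  est$dp <- est$projected_headway
  est$dv <- est$relative_velocity
  set.seed(8)
  est$theta_u <- 0.5 + 0.003 * est$dp + 0.018 * est$dv -
    0.006 * est$dp * est$dv + rnorm(nrow(est), 0, 0.01)
  est$theta_l <- est$theta_u / 3
  fit <- fit_incentive(est)
  ols <- stats::lm(theta_u ~ dp * dv, data = est)
  expect_equal(unname(fit$lambda_u),
               unname(stats::coef(ols)[c("dp", "dv", "dp:dv")]),
               tolerance = 1e-6)
})

test_that("fit_incentive recovers injected incentive slopes within 2 SE", {
  conds <- default_conditions()
  est <- tidyr::expand_grid(participant = paste0("p", 1:18),
                            condition = conds$label, rep = 1:5)
  est <- dplyr::left_join(est, conds, by = c(condition = "label"))
  # alternate driver perspective signs as in a real pair layout
  flip <- as.integer(sub("p", "", est$participant)) %% 2 == 0
  est$dp <- ifelse(flip, -1, 1) * est$projected_headway
  est$dv <- ifelse(flip, -1, 1) * est$relative_velocity
  set.seed(9)
  base <- runif(18, 0.4, 0.7)
  names(base) <- paste0("p", 1:18)
  lam <- c(0.003, 0.018, -0.006)
  est$theta_u <- base[est$participant] + lam[1] * est$dp + lam[2] * est$dv +
    lam[3] * est$dp * est$dv + rnorm(nrow(est), 0, 0.02)
  est$theta_l <- pmax(est$theta_u / 3 + rnorm(nrow(est), 0, 0.01), 0.01)
  fit <- fit_incentive(est)
  td <- tidy(fit)
  up <- td[td$threshold == "upper" & td$term != "(Intercept)", ]
  expect_equal(up$term, c("dp", "dv", "dp:dv"))
  expect_true(all(abs(up$estimate - lam) <= 2 * up$std.error))
  gl <- glance(fit)
  expect_equal(gl$nobs, rep(nrow(est), 2))
  expect_equal(gl$n_participants, rep(18, 2))
})

test_that("the matching pipeline recovers known grid-node thresholds", {
  # participants whose true thresholds are grid nodes, probed without noise,
  # must be matched back to cells explaining their deviation exactly
  g <- build_grid()
  tt <- tibble::tibble(
    participant = c("p1", "p2", "p3"),
    side = "left",
    theta_l = c(0.075, 0.14, 0.205),   # grid nodes of the lower axis
    theta_u = c(0.425, 0.5, 0.575)     # grid nodes of the upper axis
  )
  conds <- default_conditions()[3, ] # 0_0
  lk <- grid_response_lookup(conds, g)
  d <- synth_participants(tt, conds, reps = 1, noisy = FALSE)
  est <- calibrate_trials(d, setNames(list(lk), conds$label))
  cell <- function(tl, tu) {
    which(abs(lk$theta_l - tl) < 1e-9 & abs(lk$theta_u - tu) < 1e-9)
  }
  for (i in 1:3) {
    truth <- lk$deviation[cell(tt$theta_l[i], tt$theta_u[i])]
    obs <- d$deviation[d$participant == tt$participant[i]]
    expect_equal(obs, truth, tolerance = 1e-9)
    matched <- est[est$participant == tt$participant[i], ]
    matched_dev <- lk$deviation[cell(matched$theta_l, matched$theta_u)]
    expect_equal(matched_dev, obs, tolerance = 1e-9)
  }
})
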