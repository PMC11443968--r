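test_that("plan cost matches the closed-form sum without resistance", {
  p <- cei_params(include_resistance_in_rollout = FALSE)
  st <- list(s = 0, v = 10)
  expect_equal(plan_cost(0, st, v_d = 10, params = p), 0)
  # v_k = 10 + k a dt: sum 0.0025 k^2 + n a^2 for a = 1
  expect_equal(plan_cost(1, st, v_d = 10, params = p),
               0.0025 * sum((1:120)^2) + 120, tolerance = 1e-9)
  expect_equal(plan_cost(1, st, v_d = 10, params = p), 1578.05,
               tolerance = 1e-9)
  # away from the stationary optimum the cost is strictly positive
  expect_true(all(plan_cost(c(-1, -0.3, 0.4, 2), st, 10, p) >
                    plan_cost(0, st, 10, p)))
})

test_that("unconstrained optimum holds the desired velocity", {
  p <- cei_params(include_resistance_in_rollout = FALSE)
  far <- tibble::tibble(t_ahead = belief_times_for_test(p),
                        mu = 1e5, sigma = 1, phi = p$phi)
  pl <- optimize_plan(list(s = 0, v = 10, t = 0), far, risk_cap = 1,
                      v_d = 10, params = p)
  expect_equal(pl$a_planned, 0, tolerance = 1e-9)
})

test_that("with resistance on, the optimal input partially compensates drag", {
  p <- cei_params()
  far <- tibble::tibble(t_ahead = belief_times_for_test(p),
                        mu = 1e5, sigma = 1, phi = p$phi)
  pl <- optimize_plan(list(s = 0, v = 10, t = 0), far, risk_cap = 1,
                      v_d = 10, params = p)
  expect_gt(pl$a_planned, 0)
  expect_lt(pl$a_planned, resistance(10))
})

test_that("optimize_plan matches the brute-force grid oracle", {
  p <- cei_params()
  track <- track_geometry()
  set.seed(11)
  n_checked <- 0
  for (i in 1:20) {
    st <- list(s = runif(1, 40, 92), v = runif(1, 7, 13), t = 0)
    bel <- random_belief_instance(p, track)
    cap <- runif(1, 0.02, 0.6)
    impl <- tryCatch(
      optimize_plan(st, bel, cap, v_d = 10, params = p, track = track),
      cei_infeasible = function(e) NULL)
    orc <- oracle_optimize(st, bel, cap, v_d = 10, params = p, track = track)
    if (is.null(impl)) {
      expect_true(is.na(orc$a), label = "oracle agrees on infeasibility")
    } else {
      expect_false(is.na(orc$a))
      expect_lt(abs(impl$a_planned - orc$a), 1e-3 + 1e-9)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 10)
})

test_that("feasible plans respect the risk cap", {
  p <- cei_params()
  track <- track_geometry()
  set.seed(12)
  for (i in 1:20) {
    st <- list(s = runif(1, 40, 92), v = runif(1, 7, 13), t = 0)
    bel <- random_belief_instance(p, track)
    cap <- runif(1, 0.02, 0.6)
    impl <- tryCatch(
      optimize_plan(st, bel, cap, v_d = 10, params = p, track = track),
      cei_infeasible = function(e) NULL)
    if (!is.null(impl)) {
      pos <- plan_positions(impl, st, p)
      r <- perceived_risk(pos, bel, track)$risk
      expect_lte(r, cap + 1e-9)
    }
  }
})

test_that("an adversarial belief on the ego path forces the plan away from 0", {
  p <- cei_params()
  track <- track_geometry()
  st <- list(s = 60, v = 10, t = 0)
  # belief mass concentrated exactly on the ego constant-speed trajectory
  dtk <- belief_times_for_test(p)
  bel <- tibble::tibble(t_ahead = dtk, mu = 60 + 10 * dtk, sigma = 2,
                        phi = p$phi)
  unconstrained <- optimize_plan(st, bel, risk_cap = 1, v_d = 10, params = p,
                                 track = track)
  res <- tryCatch(
    optimize_plan(st, bel, risk_cap = 0.01, v_d = 10, params = p,
                  track = track),
    cei_infeasible = function(e) "infeasible")
  if (is.character(res)) {
    succeed("constraint correctly infeasible")
  } else {
    # the cap forces a clear departure from the unconstrained optimum
    expect_lt(res$a_planned, unconstrained$a_planned - 0.2)
    pos <- plan_positions(res, st, p)
    expect_lte(perceived_risk(pos, bel, track)$risk, 0.01 + 1e-9)
  }
})

test_that("fallback plans brake when behind and floor it when ahead", {
  p <- cei_params()
  expect_equal(fallback_plan(list(s = 60, v = 10), 70, p)$a_planned, -p$a_max)
  expect_equal(fallback_plan(list(s = 70, v = 10), 60, p)$a_planned, p$a_max)
  # tie treated as behind (conservative)
  expect_equal(fallback_plan(list(s = 60, v = 10), 60, p)$a_planned, -p$a_max)
  expect_equal(fallback_plan(list(s = 60, v = 10), 70, p)$origin, "fallback")
})

test_that("execution noise is frozen per plan and has the right scale", {
  p <- cei_params()
  pl <- new_plan_for_test(0.5, list(s = 0, v = 10, t = 0), p)
  expect_equal(perturb_plan(pl, 0)$a_executed, 0.5)
  set.seed(3)
  eps <- replicate(2e4, perturb_plan(pl, 0.14)$a_executed - 0.5)
  expect_equal(sd(eps), 0.14, tolerance = 0.01)
  # a single perturbed plan keeps its draw (the field is fixed, not re-drawn)
  set.seed(4)
  p1 <- perturb_plan(pl, 0.14)
  expect_identical(p1$a_executed, p1$a_executed)
  expect_error(perturb_plan(pl, -1))
})

test_that("execution_noise_sd maps the printed scale parameter", {
  expect_equal(execution_noise_sd(cei_params()), 0.14)
  expect_equal(execution_noise_sd(cei_params(sigma_n = 500)), 0.5)
})

test_that("plan waypoints are monotone with non-negative velocities", {
  p <- cei_params()
  pl <- new_plan_for_test(-2, list(s = 50, v = 3, t = 0), p)
  expect_true(all(pl$velocities >= 0))
  expect_true(all(diff(pl$waypoints) >= 0))
  expect_length(pl$waypoints, 120)
})
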