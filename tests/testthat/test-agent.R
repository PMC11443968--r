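# drive a single agent through a scripted environment: the other vehicle
# follows a fixed constant-velocity trajectory, the ego follows the agent's
# own executed inputs
drive_agent <- function(agent, ego0, other0, v_other, n_steps,
                        params = cei_params()) {
  dt <- params$dt
  s_e <- ego0$s; v_e <- ego0$v
  s_o <- other0
  rows <- vector("list", n_steps)
  for (i in seq_len(n_steps)) {
    t <- (i - 1) * dt
    agent_observe(agent, s_o, v_other, 0)
    res <- agent_step(agent, list(s = s_e, v = v_e, t = t))
    rows[[i]] <- tibble::tibble(t = t, s = s_e, v = v_e, risk = res$risk,
                                rho_l = res$rho_l, rho_u = res$rho_u,
                                event = res$event, input = res$input)
    v_e <- max(0, v_e + (res$input - resistance(v_e)) * dt)
    s_e <- s_e + v_e * dt
    s_o <- s_o + v_other * dt
  }
  dplyr::bind_rows(rows)
}

test_that("upper-threshold replans bring the plan risk under 0.8 rho_l", {
  p <- cei_params()
  track <- track_geometry()
  th <- pair3()$left
  agent <- new_agent("left", th, v_initial = 10, params = p, track = track,
                     noisy = FALSE)
  dt <- p$dt
  s_e <- 55; v_e <- 10; s_o <- 55
  seen_upper <- FALSE
  for (i in 1:200) {
    t <- (i - 1) * dt
    agent_observe(agent, s_o, 10, 0)
    res <- agent_step(agent, list(s = s_e, v = v_e, t = t))
    if (res$event == "upper") {
      seen_upper <- TRUE
      # recompute the new plan's risk against the agent's current belief
      bel <- project_belief(agent$obs$s, agent$vp, agent$mem, p)
      pos <- plan_positions(agent$plan, list(s = s_e, v = v_e), p)
      r <- perceived_risk(pos, bel, track)$risk
      expect_lte(r, 0.8 * res$rho_l + 1e-9)
      expect_gt(res$risk, res$rho_u) # the trigger condition held
    }
    v_e <- max(0, v_e + (res$input - resistance(v_e)) * dt)
    s_e <- s_e + v_e * dt
    s_o <- s_o + 10 * dt
  }
  expect_true(seen_upper)
})

test_that("no replan fires while risk stays strictly between the thresholds", {
  p <- cei_params()
  th <- risk_thresholds(0.0001, 0.9999, lambda_u = c(0, 0, 0),
                        lambda_l = c(0, 0, 0))
  agent <- new_agent("left", th, v_initial = 10, params = p, noisy = FALSE)
  # the other vehicle travels 8 m ahead at the same speed: the perceived
  # risk stays at an intermediate level (a dead-center course would saturate
  # to ~1 once the corridor is within a short lead time)
  log <- drive_agent(agent, list(s = 55, v = 10), other0 = 63, v_other = 10,
                     n_steps = 60, params = p)
  # risk is moderate here: above the tiny rho_l, below the huge rho_u
  expect_true(all(log$risk[-1] > log$rho_l[-1]))
  expect_true(all(log$risk < log$rho_u))
  expect_equal(log$event[1], "initial")
  expect_true(all(log$event[-1] == "none"))
})

test_that("the relaxation replan fires after tau seconds below rho_l", {
  p <- cei_params()
  th <- pair3()$left
  agent <- new_agent("left", th, v_initial = 10, params = p, noisy = FALSE)
  # other vehicle far ahead: risk is ~0 from the start, so the timer starts
  # at the second control step (the first creates the initial plan)
  log <- drive_agent(agent, list(s = 55, v = 10), other0 = 500, v_other = 10,
                     n_steps = 100, params = p)
  relax_t <- log$t[log$event == "relax"][1]
  below_start <- log$t[2] # first risk evaluation of an existing plan
  expect_false(is.na(relax_t))
  expect_lte(abs((relax_t - below_start) - p$tau), p$dt + 1e-9)
})

test_that("the below-threshold timer resets when risk rises above rho_l", {
  p <- cei_params()
  th <- pair3()$left
  agent <- new_agent("left", th, v_initial = 10, params = p, noisy = FALSE)
  agent_observe(agent, 500, 10, 0)
  agent_step(agent, list(s = 55, v = 10, t = 5)) # creates the initial plan
  agent$below_since <- 4.6
  agent_observe(agent, 500.5, 10, 0)
  res <- agent_step(agent, list(s = 55.5, v = 10, t = 5.05))
  # risk ~0 < rho_l and the running timer (0.45 s) is below tau: no relax,
  # and the timer keeps its original start
  expect_equal(res$event, "none")
  expect_equal(agent$below_since, 4.6)
  # now with risk between the thresholds the timer must stay cleared
  agent2 <- new_agent("left", th, v_initial = 10, params = p, noisy = FALSE)
  dt <- p$dt
  s_e <- 55; s_o <- 55
  for (i in 1:40) {
    agent_observe(agent2, s_o, 10, 0)
    res <- agent_step(agent2, list(s = s_e, v = 10, t = (i - 1) * dt))
    if (res$risk >= res$rho_l && res$event == "none") {
      expect_true(is.na(agent2$below_since))
    }
    s_e <- s_e + 10 * dt; s_o <- s_o + 10 * dt
  }
})

test_that("infeasible replans fall back to full braking or acceleration", {
  p <- cei_params()
  track <- track_geometry()
  th <- risk_thresholds(0.0005, 0.002, lambda_u = c(0, 0, 0),
                        lambda_l = c(0, 0, 0))
  # impossibly strict thresholds on a collision course: the upper trigger
  # fires but no input can push risk below 0.8 * 0.0005
  agent <- new_agent("left", th, v_initial = 10, params = p, track = track,
                     noisy = FALSE)
  log <- drive_agent(agent, list(s = 80, v = 10), other0 = 80, v_other = 10,
                     n_steps = 60, params = p)
  fb <- which(log$event == "fallback")
  expect_gt(length(fb), 0)
  # behind or tied with the other vehicle: the fallback brakes
  expect_equal(log$input[fb[1]], -p$a_max)
})
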