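# Independent oracles used across the suite. These deliberately avoid the
# package's own fast paths: brute-force grids, Monte-Carlo sampling, and
# direct numerical integration.

# Brute-force constrained planner: scan constant inputs on a fixed fine grid,
# evaluating cost and risk exactly as defined (independent R rollout).
oracle_rollout_v <- function(v0, a, n, dt, resist) {
  v <- numeric(n)
  for (k in seq_len(n)) {
    drag <- if (resist) 0.5 + 0.005 * v0^2 else 0
    v0 <- max(0, v0 + (a - drag) * dt)
    v[k] <- v0
  }
  v
}

oracle_positions <- function(s0, v0, a, n, dt, stride, resist) {
  v <- oracle_rollout_v(v0, a, n, dt, resist)
  s <- s0 + cumsum(v) * dt
  s[seq_len(n %/% stride) * stride]
}

oracle_mix_prob <- function(mu, sigma, phi, lo, hi) {
  if (sigma <= 0) return(as.numeric(lo <= mu & mu <= hi))
  0.5 * (pnorm(hi, mu, sigma) - pnorm(lo, mu, sigma)) +
    0.5 * (pnorm(hi, mu, sigma * sqrt(phi)) - pnorm(lo, mu, sigma * sqrt(phi)))
}

oracle_risk <- function(pos, bel, phi, track, aggregation = "max") {
  L <- track$vehicle_length
  corridor <- track$merge_point - L
  p <- vapply(seq_along(pos), function(k) {
    e <- pos[k]
    if (e <= corridor) return(0)
    oracle_mix_prob(bel$mu[k], bel$sigma[k], phi,
                    max(e - L, corridor), e + L)
  }, numeric(1))
  if (aggregation == "max") max(p, 0) else min(1, sum(p))
}

# brute-force constrained minimizer over a <- seq(-a_max, a_max, by = step);
# vectorized over candidates in plain R arithmetic, independent of the
# package's compiled kernels
oracle_optimize <- function(state, bel, risk_cap, v_d, params, track,
                            step = 1e-3) {
  n <- round(params$T_horizon / params$dt)
  stride <- round(1 / (params$dt * params$fb))
  a <- seq(-params$a_max, params$a_max, by = step)
  nA <- length(a)
  v <- rep(state$v, nA)
  s <- rep(state$s, nA)
  cost <- numeric(nA)
  pos <- matrix(0, nA, n %/% stride)
  j <- 0
  for (k in seq_len(n)) {
    drag <- if (params$include_resistance_in_rollout) 0.5 + 0.005 * v^2 else 0
    v <- pmax(0, v + (a - drag) * params$dt)
    s <- s + v * params$dt
    cost <- cost + (v - v_d)^2
    if (k %% stride == 0) { j <- j + 1; pos[, j] <- s }
  }
  cost <- cost + n * a^2
  L <- track$vehicle_length
  corridor <- track$merge_point - L
  pmat <- matrix(0, nA, ncol(pos))
  for (kk in seq_len(ncol(pos))) {
    e <- pos[, kk]
    inside <- e > corridor
    if (any(inside) && bel$sigma[kk] > 0) {
      pmat[inside, kk] <- oracle_mix_prob(bel$mu[kk], bel$sigma[kk],
                                          params$phi,
                                          pmax(e[inside] - L, corridor),
                                          e[inside] + L)
    } else if (any(inside)) {
      pmat[inside, kk] <- as.numeric(
        pmax(e[inside] - L, corridor) <= bel$mu[kk] &
          bel$mu[kk] <= e[inside] + L)
    }
  }
  risk <- if (params$risk_aggregation == "max") {
    apply(pmat, 1, max)
  } else {
    pmin(1, rowSums(pmat))
  }
  feasible <- risk <= risk_cap + 1e-12
  if (!any(feasible)) return(list(a = NA_real_, cost = Inf))
  i <- which(feasible)[which.min(cost[feasible])]
  list(a = a[i], cost = cost[i])
}

# random belief around a merging geometry, for oracle comparisons
random_belief_instance <- function(params, track) {
  n_pts <- round(params$T_horizon * params$fb)
  dtk <- seq_len(n_pts) / params$fb
  v_other <- runif(1, 7, 13)
  p_other <- runif(1, 40, 110)
  mu_a <- runif(1, -1, 1)
  sd_a <- runif(1, 0.2, 1.2)
  tibble::tibble(
    t_ahead = dtk,
    mu = p_other + v_other * dtk + 0.5 * dtk^2 * mu_a,
    sigma = 0.5 * dtk^2 * sd_a,
    phi = params$phi
  )
}

belief_times_for_test <- function(params) {
  seq_len(round(params$T_horizon * params$fb)) / params$fb
}

new_plan_for_test <- function(a, state, params) {
  ceimerge:::new_plan(a, state, params, origin = "optimized")
}

pair3 <- function() {
  th <- driver_thresholds()
  list(
    left = risk_thresholds(th$theta_l[th$pair == 3 & th$side == "left"],
                           th$theta_u[th$pair == 3 & th$side == "left"]),
    right = risk_thresholds(th$theta_l[th$pair == 3 & th$side == "right"],
                            th$theta_u[th$pair == 3 & th$side == "right"])
  )
}
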