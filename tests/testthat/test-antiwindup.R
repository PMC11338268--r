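aw_net <- function(topology, enabled = TRUE, mu = 10, Delta = 5, ...) {
  closed_loop_antiwindup(
    gene_expression_process(Delta = Delta), mu = mu, theta = 15, eta = 100,
    k = 8, sats = hill_sats(), topology = topology, v0 = 10, w0 = 20,
    eta_v = 100, eta_w = 100, switches_enabled = enabled, ...)
}

test_that("disabled switches reduce every topology to the base saturated loop", {
  base <- saturated_aif_loop(mu = 10, Delta = 5)
  x0b <- rep(0, 4)
  trb <- simulate_ode(base, x0b, t_max = 60, n_out = 201)
  for (topo in c("I", "II", "III")) {
    net <- aw_net(topo, enabled = FALSE)
    tra <- simulate_ode(net, rep(0, 8), t_max = 60, n_out = 201)
    for (sp in c("X1", "X2", "Z1", "Z2")) {
      expect_equal(tra$states[, sp], trb$states[, sp], tolerance = 1e-7,
                   info = paste("topology", topo, sp))
    }
  }
})

test_that("anti-windup circuitry is dormant in the admissible regime", {
  # switch outputs stay well below the setpoint production rate, and the
  # residual output bias from the finite-rate switch leak shrinks ~1/eta_w
  ss <- find_steady_state(aw_net("I"), rep(0, 8), t_max = 600,
                          tol_rel = 0, tol_abs = 1e-10)
  expect_equal(ss$status, "converged")
  expect_lt(max(ss$state[["V2"]], ss$state[["W2s"]]), 0.01 * 10)
  bias100 <- abs(ss$state[["X2"]] - 10)
  expect_lt(bias100, 0.05)
  ss2 <- find_steady_state(
    closed_loop_antiwindup(gene_expression_process(Delta = 5), mu = 10,
                           theta = 15, eta = 100, k = 8, sats = hill_sats(),
                           topology = "I", v0 = 10, w0 = 20, eta_v = 1000,
                           eta_w = 1000),
    rep(0, 8), t_max = 600, tol_rel = 0, tol_abs = 1e-10)
  bias1000 <- abs(ss2$state[["X2"]] - 10)
  expect_lt(bias1000, bias100 / 5)
})

test_that("topology II degradation propensity grows quadratically past the threshold", {
  # strong-sequestration switch: v2 = max(z1 - v0, 0), so the degradation
  # propensity h1(v2) z1 = alpha1 c (v0 + c) at z1 = v0 + c
  v0 <- 10; alpha1 <- 0.5
  sw <- seq_switch(u0 = v0, eta_v = 1e4)
  for (c0 in c(1, 3, 7)) {
    z1 <- v0 + c0
    ss <- find_steady_state(switch_network(sw, u = z1), c(V1 = 0, V2 = 0),
                            t_max = 100)
    prop_full <- alpha1 * ss$state[["V2"]] * z1
    expect_equal(prop_full, alpha1 * c0 * (v0 + c0), tolerance = 1e-3)
  }
  # below the threshold no anti-windup degradation
  ssb <- find_steady_state(switch_network(sw, u = v0 - 2), c(V1 = 0, V2 = 0),
                           t_max = 100)
  # below the threshold only the finite-rate leak remains, far below the
  # propensity one unit past the threshold
  expect_lt(alpha1 * ssb$state[["V2"]] * (v0 - 2),
            0.01 * alpha1 * 1 * (v0 + 1))
})

test_that("topology III conditions the setpoint rate through Hill repression", {
  h1 <- switch_shape_hill(10, 1)
  expect_equal(h1(0), 10)   # normal mode reproduces mu
  expect_equal(h1(1), 5)    # half-repression at kappa
  # under an inadmissible setpoint demand the conditioned loop stays bounded
  # while the unprotected loop winds up
  ss_base <- find_steady_state(saturated_aif_loop(mu = 12, Delta = 5),
                               rep(0, 4), t_max = 400)
  expect_equal(ss_base$status, "diverged")
  net3 <- aw_net("III", mu = 12)
  tr3 <- simulate_ode(net3, rep(0, 8), t_max = 400, n_out = 401)
  z1_tail <- tr3$states[tr3$times > 300, "Z1"]
  expect_lt(max(tr3$states[, "Z1"]), 100)
  expect_lt(abs(max(z1_tail) - min(z1_tail)), 0.5) # settled, not growing
})

test_that("windup protection bounds the controller species and speeds recovery", {
  sc_on <- scenario_antiwindup(TRUE)
  sc_off <- scenario_antiwindup(FALSE)
  tr_on <- run_scenario(sc_on)
  tr_off <- run_scenario(sc_off)
  win <- sc_on$windows$disturbance
  m_on <- windup_metrics(tr_on, c("Z1", "Z2"), "X2", 10, win, threshold = 20)
  m_off <- windup_metrics(tr_off, c("Z1", "Z2"), "X2", 10, win, threshold = 20)
  expect_lt(max(tr_on$states[, "Z2"]), max(tr_off$states[, "Z2"]) / 4)
  expect_lt(m_on$recovery_time, m_off$recovery_time)
  expect_equal(m_on$time_above_threshold[["Z2"]], 0)
  expect_gt(m_off$time_above_threshold[["Z2"]], 10)
})

test_that("windup metrics vanish for a trajectory pinned at the setpoint", {
  tt <- seq(0, 100, length.out = 101)
  traj <- new_trajectory(tt, cbind(X2 = rep(10, 101), Z1 = 0, Z2 = 0))
  m <- windup_metrics(traj, c("Z1", "Z2"), "X2", 10, c(20, 40), threshold = 1)
  expect_equal(unname(m$peak), c(0, 0))
  expect_equal(unname(m$time_above_threshold), c(0, 0))
  expect_equal(m$recovery_time, 0)
  expect_error(windup_metrics(traj, "Z1", "X2", 10, c(90, 110), 1), "window")
})

test_that("the conditional integrator matches the switch-reduction composition", {
  # reduced topology-I drift: KI e + k alpha1 max(z- - beta1, 0)
  #                              - k alpha2 max(z+ - beta2, 0), v = k z
  p <- reduced_aw_params(KI = 120, k = 8, alpha1 = 0.7, alpha2 = 1.3,
                         beta1 = 10, beta2 = 20, theta = 15, r_in = 2 / 3)
  proc <- gene_expression_process(Delta = 5)
  m <- reduced_conditional_integration(proc, p, hill_sats(), topology = "I")
  rhs <- antiwindup:::model_rhs(m)
  hs <- hill_activation(5)
  set.seed(11)
  for (i in 1:200) {
    s <- c(X1 = runif(1, 0, 20), X2 = runif(1, 0, 20),
           V = runif(1, -300, 300))
    z <- s[["V"]] / p$k
    pn <- positive_negative_parts(z)
    expected <- p$KI * (p$r_in - hs(s[["X2"]])) +
      p$k * (p$alpha1 * max(pn$minus - p$beta1, 0) -
             p$alpha2 * max(pn$plus - p$beta2, 0))
    expect_lt(abs(rhs(0, s)[["V"]] - expected), 1e-8)
  }
})

test_that("inside the safe band the conditional integrator is a pure integrator", {
  proc <- gene_expression_process(Delta = 5)
  p <- reduced_aw_params(KI = 120, k = 8, alpha1 = 1, alpha2 = 1,
                         beta1 = 10, beta2 = 20, theta = 15, r_in = 2 / 3)
  cond <- reduced_conditional_integration(proc, p, hill_sats(), "I")
  pure <- closed_loop_reduced_aif(proc, mu = 10, theta = 15, k = 8,
                                  sats = hill_sats())
  tr_c <- simulate_ode(cond, c(X1 = 0, X2 = 0, V = 0), t_max = 80, n_out = 201)
  tr_p <- simulate_ode(pure, c(X1 = 0, X2 = 0, Z = 0), t_max = 80, n_out = 201)
  # v = k z stays inside [-k beta1, k beta2] on this admissible run
  expect_true(all(tr_c$states[, "V"] > -8 * 10 & tr_c$states[, "V"] < 8 * 20))
  expect_equal(tr_c$states[, "X2"], tr_p$states[, "X2"], tolerance = 1e-7)
  expect_equal(tr_c$states[, "V"], 8 * tr_p$states[, "Z"], tolerance = 1e-6)
})

test_that("the leaky branches settle at the predicted steady-state error", {
  proc <- gene_expression_process(Delta = 5)
  sats <- hill_sats()
  for (r_in in c(0.9, 0.3, 0.8)) {
    p <- reduced_aw_params(KI = 120, k = 8, alpha1 = 1, alpha2 = 1,
                           beta1 = 10, beta2 = 20, theta = 15, r_in = r_in)
    m <- reduced_conditional_integration(proc, p, sats, "I")
    ss <- find_steady_state(m, c(X1 = 0, X2 = 0, V = 0), t_max = 3000,
                            tol_rel = 0, tol_abs = 1e-10)
    expect_equal(ss$status, "converged")
    e_sim <- r_in - sats$hs(ss$state[["X2"]])
    expect_equal(e_sim, steady_state_error(ss$state[["V"]], p, "I"),
                 tolerance = 1e-6)
  }
  # branch continuity and the printed spot values
  p1 <- reduced_aw_params(KI = 120, k = 8, alpha1 = 1, alpha2 = 120,
                          beta1 = 10, beta2 = 20, theta = 15, r_in = 2 / 3)
  expect_equal(steady_state_error(0, p1, "I"), 0)
  expect_equal(steady_state_error(8 * 20 + 1, p1, "I"), 1) # alpha_j = KI
  expect_equal(steady_state_error(8 * 20, p1, "I"), 0)     # continuous edge
})

test_that("conditioning factors scale the reference and sensor as prescribed", {
  p <- reduced_aw_params(KI = 120, k = 8, alpha1 = 2, alpha2 = 3,
                         beta1 = 10, beta2 = 20, theta = 15, r_in = 2 / 3)
  k <- p$k
  inside <- conditioning_factors(0, p)
  expect_equal(inside$rho_reference, 1)
  expect_equal(inside$rho_sensor, 1)
  expect_equal(conditioning_factors(k * p$beta1, p)$rho_reference, 1)
  half_ref <- conditioning_factors(k * p$beta1 + k * p$alpha1, p)
  expect_equal(half_ref$rho_reference, 0.5)
  half_sen <- conditioning_factors(-k * p$beta2 - k * p$alpha2, p)
  expect_equal(half_sen$rho_sensor, 0.5)
  v <- seq(-500, 500, by = 10)
  cf <- conditioning_factors(v, p)
  expect_true(all(cf$rho_reference > 0 & cf$rho_reference <= 1))
  expect_true(all(cf$rho_sensor > 0 & cf$rho_sensor <= 1))
})
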