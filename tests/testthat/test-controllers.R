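test_that("the saturation block clamps exactly at its limits", {
  expect_equal(sat(12, 0, 10), 10)
  expect_equal(sat(-3, 0, 10), 0)
  expect_equal(sat(5, 0, 10), 5)
  expect_equal(hill_activation(5)(5), 0.5) # half-maximum at kappa
})

test_that("the classical integral loop achieves the setpoint when unsaturated", {
  proc <- gene_expression_process(Delta = 5)
  loop <- closed_loop_classical(proc, KI = 1, r = 10)
  ss <- find_steady_state(loop, c(X1 = 0, X2 = 0, V = 0), t_max = 500)
  expect_equal(ss$status, "converged")
  # (u, y) = (inverse map of r, r)
  expect_equal(ss$state[["X2"]], 10, tolerance = 1e-5)
  expect_equal(ss$state[["V"]], 5, tolerance = 1e-4)

  # a setpoint outside the sensor range destroys the fixed point
  loop2 <- closed_loop_classical(proc, KI = 1, r = 10, y_range = c(0, 8))
  ss2 <- find_steady_state(loop2, c(X1 = 0, X2 = 0, V = 0), t_max = 300)
  expect_equal(ss2$status, "diverged")
})

test_that("the antithetic loop adapts perfectly for admissible disturbances", {
  ss <- find_steady_state(basic_aif_loop(Delta = 0), rep(0, 4), t_max = 500)
  expect_equal(ss$status, "converged")
  expect_equal(ss$state[["X2"]], 10, tolerance = 1e-5)

  # RPA: two different admissible disturbances, same output
  y_at <- function(Delta) {
    find_steady_state(saturated_aif_loop(Delta = Delta), rep(0, 4),
                      t_max = 2000, tol_rel = 0, tol_abs = 1e-11)$state[["X2"]]
  }
  expect_lt(abs(y_at(5) - y_at(8)), 1e-6)
})

test_that("the signed controller coordinate integrates the sensed error", {
  # d(z1 - z2)/dt = mu - theta * hs(y) pointwise: sequestration cancels
  net <- saturated_aif_loop()
  rhs <- antiwindup:::model_rhs(net)
  hs <- hill_activation(5)
  tr <- simulate_ode(net, rep(0, 4), t_max = 60, n_out = 301)
  for (i in seq(1, 301, by = 30)) {
    s <- stats::setNames(tr$states[i, ], net$species)
    d <- rhs(tr$times[i], s)
    expect_lt(abs((d[["Z1"]] - d[["Z2"]]) - (10 - 15 * hs(s[["X2"]]))), 1e-6)
  }
})

test_that("the saturated antithetic loop reaches the output setpoint", {
  ss <- find_steady_state(saturated_aif_loop(mu = 10, Delta = 5), rep(0, 4),
                          t_max = 2000, tol_rel = 0, tol_abs = 1e-9)
  expect_equal(ss$status, "converged")
  expect_equal(ss$state[["X2"]], 10, tolerance = 1e-6)
  expect_equal(ss$state[["Z1"]], 25 / 3, tolerance = 1e-6)

  # demanded input setpoint beyond theta * hs(13): Z1 winds up
  ss2 <- find_steady_state(saturated_aif_loop(mu = 12, Delta = 5), rep(0, 4),
                           t_max = 400)
  expect_equal(ss2$status, "diverged")
})

test_that("the reduced controller reproduces the strong-sequestration limit", {
  proc <- gene_expression_process()
  red <- closed_loop_reduced_aif(proc, mu = 10, theta = 1, k = 1)
  ss <- find_steady_state(red, c(X1 = 0, X2 = 0, Z = 0), t_max = 500)
  expect_equal(ss$state[["X2"]], 10, tolerance = 1e-5)
  expect_equal(ss$state[["Z"]], 10, tolerance = 1e-4)

  # below zero the positive-part clamp shuts the actuation off
  rhs <- antiwindup:::model_rhs(red)
  d <- rhs(0, c(X1 = 2, X2 = 3, Z = -5))
  expect_equal(d[["X1"]], -2) # only degradation, no actuation

  # psi_a composition equals the actuation law of the reduced controller
  sats <- hill_sats()
  pa <- psi_a(sats$ha, k = 8)
  for (z in c(-2, 0, 0.5, 3, 10)) {
    expect_equal(pa(8 * z), 8 * sats$ha(max(z, 0)))
  }
})

test_that("input and output setpoints are linked through the sensing function", {
  hs <- hill_activation(5)
  expect_equal(map_setpoints(hs, 2 / 3), 10, tolerance = 1e-8)
  expect_equal(map_setpoints(function(y) y, 7), 7)
  expect_error(map_setpoints(hs, 1.2), "sensor-saturated") # range(hs) = [0, 1)
})

test_that("fixed-point existence follows the algebraic conditions", {
  m0 <- io_map(gene_expression_process())
  rep0 <- fixed_point_exists(m0, r = 10)
  expect_true(rep0$exists)
  expect_equal(rep0$fixed_point[c("y", "u")], list(y = 10, u = 10))

  # output setpoint beyond the admissible interval [5, 13]
  m5 <- io_map(gene_expression_process(Delta = 5))
  rep1 <- fixed_point_exists(m5, r = 14, U = interval(0, 8),
                             sats = hill_sats(), k = 8)
  expect_false(rep1$exists)
  expect_true("setpoint-inadmissible" %in% rep1$failed_conditions)

  # input setpoint outside the sensor range
  rep2 <- fixed_point_exists(m5, r_in = 1.2, U = interval(0, 8),
                             sats = hill_sats(), k = 8)
  expect_false(rep2$exists)
  expect_true("sensor-saturated" %in% rep2$failed_conditions)

  # admissible saturated case: the report matches the simulated loop
  rep3 <- fixed_point_exists(m5, r_in = 2 / 3, U = interval(0, 8),
                             sats = hill_sats(), k = 8)
  expect_true(rep3$exists)
  expect_equal(rep3$fixed_point$y, 10, tolerance = 1e-8)
  expect_equal(rep3$fixed_point$u, 5, tolerance = 1e-8)
  ss <- find_steady_state(saturated_aif_loop(mu = 10, Delta = 5), rep(0, 4),
                          t_max = 2000, tol_rel = 0, tol_abs = 1e-9)
  expect_equal(ss$state[["X2"]], rep3$fixed_point$y, tolerance = 1e-5)
})

test_that("fixed-point verdicts agree with closed-loop simulation across boundaries", {
  # saturated loop, Delta = 5: admissible output setpoints are [5, 13];
  # straddle both boundaries with the input setpoint mu = theta * hs(r_out)
  m5 <- io_map(gene_expression_process(Delta = 5))
  hs <- hill_activation(5)
  for (r_out in c(5.5, 9, 11, 13.5)) {
    verdict <- fixed_point_exists(m5, r = r_out, U = interval(0, 8),
                                  sats = hill_sats(), k = 8)
    mu <- 15 * hs(r_out)
    ss <- find_steady_state(saturated_aif_loop(mu = mu, Delta = 5),
                            rep(0, 4), t_max = 1500)
    expect_equal(verdict$exists, ss$status == "converged", info = r_out)
  }
  # unsaturated loop, r = 10: disturbances straddling the ceiling 10
  m <- function(D) io_map(gene_expression_process(Delta = D))
  for (D in c(9.5, 10.5)) {
    verdict <- fixed_point_exists(m(D), r = 10)
    ss <- find_steady_state(basic_aif_loop(Delta = D), rep(0, 4), t_max = 600)
    expect_equal(verdict$exists, ss$status == "converged", info = D)
  }
})
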