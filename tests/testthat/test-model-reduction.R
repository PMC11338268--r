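test_that("positive/negative parts decompose signed values exactly", {
  expect_equal(positive_negative_parts(3), list(plus = 3, minus = 0))
  expect_equal(positive_negative_parts(-2), list(plus = 0, minus = 2))
  expect_equal(positive_negative_parts(0), list(plus = 0, minus = 0))
  z <- c(-1.5, 0, 2.5)
  pn <- positive_negative_parts(z)
  expect_equal(pn$plus - pn$minus, z)
  expect_true(all(pn$plus * pn$minus == 0))
})

test_that("reduction produces the signed-coordinate drift W1 - W2", {
  # antithetic controller: drift mu - theta * y
  spec <- basic_aif_spec()
  red <- reduce(spec)
  p <- spec$parameters
  x <- c(X1 = 4, X2 = 7)
  expect_equal(red$drift(x, 3, 0, p), 10 - 7)
  expect_equal(red$drift(x, -3, 0, p), 10 - 7) # drift independent of z here

  # W1 = W2: drift identically zero, z frozen at a - b
  sym <- fast_seq_spec(W1 = function(x, z1, z2, t, p) 1 + z1,
                       W2 = function(x, z1, z2, t, p) 1 + z1,
                       eta = 50, a = 2, b = 5)
  rsym <- reduce(sym)
  tr <- simulate_ode(rsym$model, c(Z = sym$a - sym$b), t_max = 10)
  expect_true(all(abs(tr$states[, "Z"] + 3) < 1e-8))

  # sequestration switch: drift u0 - u - delta1 z+ + delta2 z-
  sw <- seq_switch(u0 = 10, eta_v = 1e4, delta1 = 1.5, delta2 = 0.5)
  ssp <- switch_fast_seq_spec(sw, u = 15)
  rsw <- reduce(ssp)
  for (z in c(-4, -0.5, 0, 2, 6)) {
    expect_equal(rsw$drift(numeric(0), z, 0, ssp$parameters),
                 10 - 15 - 1.5 * max(z, 0) + 0.5 * max(-z, 0))
  }
})

test_that("the signed coordinate of the full system obeys d(z1-z2)/dt = W1 - W2", {
  # sequestration cancels exactly in the difference, at any state
  spec <- basic_aif_spec(eta = 100)
  fm <- full_model(spec)
  rhs <- antiwindup:::model_rhs(fm)
  set.seed(7)
  for (i in 1:100) {
    s <- c(X1 = runif(1, 0, 20), X2 = runif(1, 0, 20),
           Z1 = runif(1, 0, 20), Z2 = runif(1, 0, 20))
    d <- rhs(0, s)
    w1 <- spec$W1(s[1:2], s[["Z1"]], s[["Z2"]], 0, spec$parameters)
    w2 <- spec$W2(s[1:2], s[["Z1"]], s[["Z2"]], 0, spec$parameters)
    expect_lt(abs((d[["Z1"]] - d[["Z2"]]) - (w1 - w2)), 1e-6)
  }
})

test_that("discrepancy metrics satisfy their definitional identities", {
  # identical trajectories with (z1, z2) = (z+, z-): both metrics vanish
  tt <- seq(0, 1, length.out = 101)
  full <- new_trajectory(tt, cbind(X = tt, Z1 = tt, Z2 = 0))
  red <- new_trajectory(tt, cbind(X = tt, Z = tt))
  rep0 <- discrepancy(full, red, T = 1)
  expect_equal(rep0$sup_metric, 0)
  expect_equal(rep0$l1_metric, 0)

  # equal signed difference but shifted pair: the sup metric is blind to the
  # common component, the l1 metric is not
  shifted <- new_trajectory(tt, cbind(X = tt, Z1 = tt + 1, Z2 = 1))
  rep_sh <- discrepancy(shifted, red, T = 1)
  expect_equal(rep_sh$sup_metric, 0)
  expect_equal(rep_sh$l1_metric, sqrt(2), tolerance = 1e-6)

  # constant offset c in one coordinate over [0,1]: sup = L1 = c
  c0 <- 0.7
  full2 <- new_trajectory(tt, cbind(X = tt + c0, Z1 = tt, Z2 = 0))
  rep1 <- discrepancy(full2, red, T = 1)
  expect_equal(rep1$sup_metric, c0, tolerance = 1e-10)
  expect_equal(rep1$l1_metric, c0, tolerance = 1e-4)

  # horizon mismatch is rejected
  expect_error(discrepancy(full, red, T = 2), "horizon")
})

test_that("discrepancies shrink with the sequestration rate", {
  tab <- convergence_study(basic_aif_spec(), eta_grid = c(10, 100), T = 10,
                           n_out = 1001)
  expect_lt(tab$sup_metric[2], tab$sup_metric[1])
  expect_lt(tab$l1_metric[2], tab$l1_metric[1])

  # degenerate W1 = W2 spec: full and reduced coincide at every eta
  sym <- fast_seq_spec(W1 = function(x, z1, z2, t, p) 2,
                       W2 = function(x, z1, z2, t, p) 2,
                       eta = 1, a = 1, b = 1)
  tab2 <- convergence_study(sym, eta_grid = c(1, 100), T = 5, n_out = 501)
  expect_true(all(tab2$sup_metric < 1e-5))
})

test_that("reduced trajectories keep z+ . z- = 0 exactly", {
  red <- reduce(basic_aif_spec(Delta = 12)) # crosses z = 0
  tr <- simulate_ode(red$model, c(X1 = 0, X2 = 0, Z = 0), t_max = 50)
  z <- tr$states[, "Z"]
  expect_lt(min(z), 0) # the signed coordinate does go negative here
  pn <- positive_negative_parts(z)
  expect_true(all(pn$plus * pn$minus == 0))
})

test_that("fixed points lift between reduced and full coordinates", {
  red <- reduce(basic_aif_spec())
  expect_equal(unname(lift_fixed_point(red, c(10, 10), 10)[c("Z1", "Z2")]),
               c(10, 0))
  # negative signed coordinate goes to the second species
  sym <- reduce(fast_seq_spec(W1 = function(x, z1, z2, t, p) 2,
                              W2 = function(x, z1, z2, t, p) 2,
                              eta = 1, a = 0, b = 2))
  expect_equal(unname(lift_fixed_point(sym, zbar = -2)[c("Z1", "Z2")]),
               c(0, 2))
  # a non-fixed-point is rejected with its residual
  expect_error(lift_fixed_point(red, c(3, 3), 10), "not a fixed point")
})

test_that("full-system fixed points approach the lifted reduced fixed point", {
  spec <- basic_aif_spec()
  red <- reduce(spec)
  lifted <- lift_fixed_point(red, c(10, 10), 10)
  dist <- function(eta) {
    fp <- full_fixed_point(spec, lifted, eta = eta)
    sqrt(sum((fp[c("Z1", "Z2")] - lifted[c("Z1", "Z2")])^2))
  }
  d3 <- dist(1e3); d4 <- dist(1e4)
  expect_lt(d3, 1e-2)
  expect_lt(d4, d3) # residual shrinks as the rate grows
})
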