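#' Switch readout shapes
#'
#' The two functional forms used by the anti-windup switches:
#' `switch_shape_linear(alpha, beta)` is the threshold-linear map
#' `h(z) = alpha * max(z - beta, 0)` (zero below the threshold, then
#' increasing); `switch_shape_hill(alpha, kappa)` is the repression map
#' `h(v) = alpha / (1 + v / kappa)` (equal to `alpha` at zero, then
#' decreasing). `switch_shape_identity()` is the identity readout.
#'
#' @param alpha slope (linear) or maximal rate (hill).
#' @param beta threshold of the linear shape.
#' @param kappa half-repression constant of the hill shape.
#' @return a function with attribute `kind`.
#' @export
switch_shape_linear <- function(alpha, beta) {
  stopifnot(alpha >= 0, beta >= 0)
  structure(function(z) alpha * pmax(z - beta, 0),
            kind = "linear-above-threshold", alpha = alpha, beta = beta)
}

#' @rdname switch_shape_linear
#' @export
switch_shape_hill <- function(alpha, kappa) {
  stopifnot(alpha > 0, kappa > 0)
  structure(function(v) alpha / (1 + v / kappa),
            kind = "hill-repression", alpha = alpha, kappa = kappa)
}

#' @rdname switch_shape_linear
#' @export
switch_shape_identity <- function() {
  structure(function(z) z, kind = "identity")
}

#' Antithetic closed loop augmented with anti-windup circuitry
#'
#' Builds the full reaction network of the saturated antithetic loop plus one
#' of three anti-windup topologies, each realized by two sequestration
#' switches (species `V1`/`V2` keyed by threshold `v0`, and `W1s`/`W2s` keyed
#' by threshold `w0`):
#'
#' * **Topology I** (conditional integration by cross-production): high `Z2`
#'   drives extra production of `Z1` at rate `h1(v2)` and high `Z1` drives
#'   extra production of `Z2` at rate `h2(w2)`. The `V` switch is fed by
#'   `g1(z2)` and the `W` switch by `g2(z1)`.
#' * **Topology II** (conditional integration by self-degradation): high `Z1`
#'   triggers its own degradation with propensity `h1(v2) * z1` (quadratic
#'   beyond the threshold for linear `h1`), symmetrically for `Z2`; each
#'   switch is fed by its own controller species (`g1(z1)`, `g2(z2)`).
#' * **Topology III** (reference/sensor conditioning): production of `Z1` is
#'   `h1(v2)` with `h1` a decreasing Hill shape pinned to `h1(0) = mu` so the
#'   unswitched regime reproduces the nominal setpoint rate, and sensing is
#'   scaled by the normalized repression `h2(w2) / h2(0)`; switches fed by
#'   `g1(z1)`, `g2(z2)`.
#'
#' With the switch outputs forced to zero (`h1 = h2 = 0` via
#' `switches_enabled = FALSE`) the `Z`/process dynamics coincide exactly with
#' the base saturated loop, plus decoupled switch states.
#'
#' @param proc a `crn_process`.
#' @param mu,theta,eta,k base controller parameters (see
#'   [closed_loop_aif()]).
#' @param sats [make_saturations()] actuation/sensing pair.
#' @param topology `"I"`, `"II"` or `"III"`.
#' @param v0,w0 switch thresholds (production rates of the switch `V1`-type
#'   species).
#' @param eta_v,eta_w switch sequestration rates.
#' @param deltas degradation rates `c(delta_v1, delta_v2, delta_w1,
#'   delta_w2)`.
#' @param g1,g2 monotone switch input maps (default identity).
#' @param h1,h2 switch readouts; default identity for topologies I/II, and
#'   for topology III a Hill repression with `alpha = mu` (for `h1`) and a
#'   unit-normalized Hill repression (for `h2`) with `kappa = kappa_aw`.
#' @param kappa_aw half-repression constant for the topology III defaults.
#' @param switches_enabled set `FALSE` to zero the anti-windup readouts
#'   (diagnostic).
#' @return a [reaction_network()] on
#'   `(x..., Z1, Z2, V1, V2, W1s, W2s)`.
#' @export
closed_loop_antiwindup <- function(proc, mu, theta, eta, k,
                                   sats = make_saturations(),
                                   topology = c("I", "II", "III"),
                                   v0, w0, eta_v, eta_w,
                                   deltas = c(1, 1, 1, 1),
                                   g1 = switch_shape_identity(),
                                   g2 = switch_shape_identity(),
                                   h1 = NULL, h2 = NULL, kappa_aw = 1,
                                   switches_enabled = TRUE) {
  topology <- match.arg(topology)
  stopifnot(inherits(proc, "crn_process"), v0 > 0, w0 > 0, eta_v > 0,
            eta_w > 0, length(deltas) == 4L, all(deltas > 0))
  out <- proc$output_species
  inp <- proc$input_species
  ha <- sats$ha; hs <- sats$hs
  if (is.null(h1)) {
    h1 <- if (topology == "III") switch_shape_hill(mu, kappa_aw)
          else switch_shape_identity()
  }
  if (is.null(h2)) {
    h2 <- if (topology == "III") switch_shape_hill(1, kappa_aw)
          else switch_shape_identity()
  }
  if (!switches_enabled) {
    if (topology == "III") {
      h1 <- structure(function(v) mu + 0 * v, kind = "disabled")
      h2 <- structure(function(v) 1 + 0 * v, kind = "disabled")
    } else {
      h1 <- structure(function(v) 0 * v, kind = "disabled")
      h2 <- structure(function(v) 0 * v, kind = "disabled")
    }
  }

  # switch drive signals per topology
  v_drive <- if (topology == "I") "Z2" else "Z1"
  w_drive <- if (topology == "I") "Z1" else "Z2"

  ctrl <- list(
    # Z1 production: constitutive mu (I, II); repressed by V2 in III
    if (topology == "III") {
      reaction(c(Z1 = 1), function(x, t, p) h1(x[["V2"]]), name = "setpoint (conditioned)")
    } else {
      reaction(c(Z1 = 1), function(x, t, p) p$mu, name = "setpoint")
    },
    # Z2 production: sensing; scaled by the W switch in III
    if (topology == "III") {
      reaction(c(Z2 = 1),
               function(x, t, p) p$theta * hs(x[[out]]) * h2(x[["W2s"]]) / h2(0),
               name = "sensing (conditioned)")
    } else {
      reaction(c(Z2 = 1), function(x, t, p) p$theta * hs(x[[out]]), name = "sensing")
    },
    reaction(c(Z1 = -1, Z2 = -1),
             function(x, t, p) p$eta * x[["Z1"]] * x[["Z2"]], name = "sequestration"),
    reaction(stats::setNames(1, inp),
             function(x, t, p) p$k * ha(x[["Z1"]]), name = "actuation"))

  aw <- switch(topology,
    I = list(
      reaction(c(Z1 = 1), function(x, t, p) h1(x[["V2"]]), name = "anti-windup Z1 production"),
      reaction(c(Z2 = 1), function(x, t, p) h2(x[["W2s"]]), name = "anti-windup Z2 production")),
    II = list(
      reaction(c(Z1 = -1), function(x, t, p) h1(x[["V2"]]) * x[["Z1"]],
               name = "anti-windup Z1 degradation"),
      reaction(c(Z2 = -1), function(x, t, p) h2(x[["W2s"]]) * x[["Z2"]],
               name = "anti-windup Z2 degradation")),
    III = list())

  sw <- list(
    reaction(c(V1 = 1), function(x, t, p) p$v0),
    reaction(c(V2 = 1), function(x, t, p) g1(x[[v_drive]])),
    reaction(c(V1 = -1, V2 = -1),
             function(x, t, p) p$eta_v * x[["V1"]] * x[["V2"]]),
    reaction(c(V1 = -1), function(x, t, p) p$delta_v1 * x[["V1"]]),
    reaction(c(V2 = -1), function(x, t, p) p$delta_v2 * x[["V2"]]),
    reaction(c(W1s = 1), function(x, t, p) p$w0),
    reaction(c(W2s = 1), function(x, t, p) g2(x[[w_drive]])),
    reaction(c(W1s = -1, W2s = -1),
             function(x, t, p) p$eta_w * x[["W1s"]] * x[["W2s"]]),
    reaction(c(W1s = -1), function(x, t, p) p$delta_w1 * x[["W1s"]]),
    reaction(c(W2s = -1), function(x, t, p) p$delta_w2 * x[["W2s"]]))

  reaction_network(
    species = c(proc$species, "Z1", "Z2", "V1", "V2", "W1s", "W2s"),
    reactions = c(proc$reactions, ctrl, aw, sw),
    parameters = c(proc$parameters,
                   list(mu = mu, theta = theta, eta = eta, k = k, v0 = v0,
                        w0 = w0, eta_v = eta_v, eta_w = eta_w,
                        delta_v1 = deltas[1], delta_v2 = deltas[2],
                        delta_w1 = deltas[3], delta_w2 = deltas[4])))
}

#' Reduced conditional-integration parameters
#'
#' @param KI integral gain (`k * theta`).
#' @param k actuation gain.
#' @param alpha1,alpha2 leak slopes of the two switches.
#' @param beta1,beta2 switch thresholds.
#' @param theta sensing gain.
#' @param r_in input setpoint (`mu / theta`).
#' @return list of class `reduced_aw_params`.
#' @export
reduced_aw_params <- function(KI, k, alpha1, alpha2, beta1, beta2, theta,
                              r_in) {
  stopifnot(KI > 0, k > 0, alpha1 >= 0, alpha2 >= 0, beta1 > 0, beta2 > 0,
            theta > 0, r_in > 0)
  structure(list(KI = KI, k = k, alpha1 = alpha1, alpha2 = alpha2,
                 beta1 = beta1, beta2 = beta2, theta = theta, r_in = r_in),
            class = "reduced_aw_params")
}

# branch indices (i, j) of the safe band [-k*beta_i, k*beta_j]
aw_branch_indices <- function(topology) {
  switch(topology, I = c(1L, 2L), II = c(2L, 1L),
         stop("conditional integration applies to topologies I and II"))
}

#' Reduced conditional-integration closed loop
#'
#' Phenomenological limit of anti-windup topologies I and II: the integrator
#' output `v = k (z1 - z2)` integrates the error `e = r_in - hs(y)` inside
#' the safe band `[-k beta_i, k beta_j]` and becomes a leaky integrator
#' outside it:
#' \deqn{\dot v = K_I e - \alpha_i (v + k\beta_i) \ \mathrm{for}\ v < -k\beta_i,
#'  \qquad \dot v = K_I e \ \mathrm{inside}, \qquad
#'  \dot v = K_I e - \alpha_j (v - k\beta_j)\ \mathrm{for}\ v > k\beta_j,}
#' with `(i, j) = (1, 2)` for topology I and `(2, 1)` for topology II.
#' Actuation passes through `psi_a(v) = k ha(max(v, 0)/k)`.
#'
#' @param proc a `crn_process`.
#' @param p a [reduced_aw_params()].
#' @param sats [make_saturations()] pair.
#' @param topology `"I"` or `"II"` (selects the branch assignment).
#' @return an [ode_system()] on `(x..., V)` with `V` signed.
#' @export
reduced_conditional_integration <- function(proc, p,
                                            sats = make_saturations(),
                                            topology = "I") {
  stopifnot(inherits(proc, "crn_process"), inherits(p, "reduced_aw_params"))
  ij <- aw_branch_indices(topology)
  a_i <- c(p$alpha1, p$alpha2)[ij[1]]; b_i <- c(p$beta1, p$beta2)[ij[1]]
  a_j <- c(p$alpha1, p$alpha2)[ij[2]]; b_j <- c(p$beta1, p$beta2)[ij[2]]
  out <- proc$output_species
  pa <- psi_a(sats$ha, p$k)
  hs <- sats$hs
  ode_system(
    species = c(proc$species, "V"),
    rhs = function(t, s, pp) {
      x <- s[proc$species]
      v <- s[["V"]]
      e <- p$r_in - hs(x[[out]])
      leak <- if (v < -p$k * b_i) {
        -a_i * (v + p$k * b_i)
      } else if (v > p$k * b_j) {
        -a_j * (v - p$k * b_j)
      } else 0
      c(process_deriv(proc, x, pa(v), t, pp), p$KI * e + leak)
    },
    parameters = proc$parameters,
    signed_species = "V")
}

#' Steady-state error of the conditional integrator
#'
#' The leaky-integrator branches trade windup protection for a bounded
#' steady-state error proportional to the excursion of the integrator output
#' `v` beyond the safe band:
#' `e = (alpha_i/KI)(v + k beta_i)` below the band, `0` inside,
#' `(alpha_j/KI)(v - k beta_j)` above; continuous at both edges.
#'
#' @param vbar steady-state integrator output.
#' @param p a [reduced_aw_params()].
#' @param topology `"I"` or `"II"`.
#' @return the steady-state error.
#' @export
steady_state_error <- function(vbar, p, topology = "I") {
  stopifnot(inherits(p, "reduced_aw_params"))
  ij <- aw_branch_indices(topology)
  a_i <- c(p$alpha1, p$alpha2)[ij[1]]; b_i <- c(p$beta1, p$beta2)[ij[1]]
  a_j <- c(p$alpha1, p$alpha2)[ij[2]]; b_j <- c(p$beta1, p$beta2)[ij[2]]
  ifelse(vbar < -p$k * b_i, (a_i / p$KI) * (vbar + p$k * b_i),
         ifelse(vbar > p$k * b_j, (a_j / p$KI) * (vbar - p$k * b_j), 0))
}

#' Reference and sensor conditioning factors (topology III)
#'
#' When the integrator output leaves the safe band `[-k beta2, k beta1]`, the
#' reference (for high positive `v`) or the sensed signal (for low negative
#' `v`) is scaled down:
#' `rho_reference = k alpha1 / (k alpha1 + v - k beta1)` for `v > k beta1`,
#' `rho_sensor = k alpha2 / (k alpha2 - v - k beta2)` for `v < -k beta2`,
#' both 1 inside the band and in `(0, 1]` everywhere.
#'
#' @param v integrator output value(s).
#' @param p a [reduced_aw_params()].
#' @return list with numeric components `rho_reference` and `rho_sensor`.
#' @export
conditioning_factors <- function(v, p) {
  stopifnot(inherits(p, "reduced_aw_params"))
  k <- p$k
  rho_ref <- ifelse(v > k * p$beta1,
                    (k * p$alpha1) / (k * p$alpha1 + v - k * p$beta1), 1)
  rho_sen <- ifelse(v < -k * p$beta2,
                    (k * p$alpha2) / (k * p$alpha2 - v - k * p$beta2), 1)
  list(rho_reference = rho_ref, rho_sensor = rho_sen)
}

#' Windup metrics of a closed-loop trajectory
#'
#' Quantifies windup: the peak of each controller species, its time spent
#' above a threshold, and the recovery time — how long after the disturbance
#' window ends the tracking error stays outside 5% of the setpoint (measured
#' as the last time the relative error exceeds 5%, minus the window end).
#'
#' @param traj a trajectory.
#' @param controller_species character vector of controller species columns.
#' @param output output species column.
#' @param setpoint output setpoint used for the error.
#' @param disturbance_window length-2 numeric `(start, end)` of the
#'   disturbance excursion; must lie inside the trajectory horizon.
#' @param threshold level defining `time_above_threshold` for the controller
#'   species.
#' @return list with `peak` (named), `time_above_threshold` (named),
#'   `recovery_time`.
#' @export
windup_metrics <- function(traj, controller_species, output, setpoint,
                           disturbance_window, threshold) {
  stopifnot(inherits(traj, "trajectory"), length(disturbance_window) == 2L)
  if (disturbance_window[2] > max(traj$times) ||
      disturbance_window[1] < min(traj$times)) {
    stop("disturbance window not inside the trajectory horizon")
  }
  dt <- diff(traj$times)
  peak <- vapply(controller_species, function(sp) max(traj$states[, sp]),
                 numeric(1))
  tat <- vapply(controller_species, function(sp) {
    above <- traj$states[, sp] > threshold
    sum(dt[above[-length(above)]])
  }, numeric(1))
  after <- traj$times >= disturbance_window[2]
  rel_err <- abs(traj$states[after, output] - setpoint) / abs(setpoint)
  t_after <- traj$times[after]
  bad <- which(rel_err > 0.05)
  recovery <- if (length(bad)) t_after[max(bad)] - disturbance_window[2] else 0
  list(peak = peak, time_above_threshold = tat, recovery_time = recovery)
}
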