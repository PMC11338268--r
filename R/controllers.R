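#' Saturation function
#'
#' @param z value(s).
#' @param lo,hi saturation bounds (`-Inf`/`Inf` allowed).
#' @return `z` clamped to `[lo, hi]`.
#' @export
sat <- function(z, lo = -Inf, hi = Inf) {
  stopifnot(lo < hi)
  pmin(pmax(z, lo), hi)
}

#' Hill-type (Michaelis-Menten) saturation
#'
#' `h(z) = (z/kappa) / (1 + z/kappa)`: increasing, `h(0) = 0`,
#' `h(kappa) = 1/2`, saturating at 1.
#'
#' @param kappa half-maximum constant (> 0).
#' @return a function of one argument.
#' @export
hill_activation <- function(kappa) {
  stopifnot(kappa > 0)
  function(z) (z / kappa) / (1 + z / kappa)
}

#' Actuation and sensing nonlinearity pair
#'
#' @param ha,hs either `"identity"`, `"hill"`, or a monotonically increasing
#'   function with `h(0) = 0`.
#' @param kappa_a,kappa_s Hill constants (used when the corresponding choice
#'   is `"hill"`).
#' @return list with function components `ha` and `hs` (class `saturations`).
#' @export
make_saturations <- function(ha = "identity", hs = "identity",
                             kappa_a = NULL, kappa_s = NULL) {
  pick <- function(h, kappa, what) {
    if (is.function(h)) return(h)
    switch(h,
           identity = function(z) z,
           hill = {
             if (is.null(kappa)) stop("kappa required for a Hill ", what)
             hill_activation(kappa)
           },
           stop("unknown ", what, " type: ", h))
  }
  structure(list(ha = pick(ha, kappa_a, "actuation"),
                 hs = pick(hs, kappa_s, "sensing")),
            class = "saturations")
}

#' Classical integral feedback loop with saturations
#'
#' Integrator state `v` driven by the error between the setpoint and the
#' (saturated) sensed output, actuating through a saturated channel:
#' `u = sat(v; u_min, u_max)`, `w = sat(y; y_min, y_max)`,
#' `vdot = KI * (r - w)`.
#'
#' @param proc a `crn_process`.
#' @param KI integral gain.
#' @param r setpoint.
#' @param u_range,y_range actuator/sensor ranges, length-2 numeric
#'   (infinite entries allowed).
#' @return an [ode_system()] on `(x..., V)` with `V` signed.
#' @export
closed_loop_classical <- function(proc, KI, r, u_range = c(-Inf, Inf),
                                  y_range = c(-Inf, Inf)) {
  stopifnot(inherits(proc, "crn_process"), u_range[1] < u_range[2],
            y_range[1] < y_range[2])
  out <- proc$output_species
  ode_system(
    species = c(proc$species, "V"),
    rhs = function(t, s, p) {
      x <- s[proc$species]
      u <- sat(s[["V"]], u_range[1], u_range[2])
      w <- sat(x[[out]], y_range[1], y_range[2])
      c(process_deriv(proc, x, u, t, p), KI * (p$r - w))
    },
    parameters = c(proc$parameters, list(KI = KI, r = r)),
    signed_species = "V")
}

#' Antithetic integral feedback closed loop
#'
#' Assembles the process with the two-species antithetic controller as one
#' reaction network. The controller reactions are: constitutive production of
#' `Z1` at rate `mu` (setpoint encoding), catalytic production of `Z2` by the
#' output at rate `theta * hs(y)` (sensing), mutual sequestration
#' `Z1 + Z2 -> 0` at rate `eta * z1 * z2` (comparison), and catalytic
#' production of the process input species at rate `u = k * ha(z1)`
#' (actuation). Identity `ha`/`hs` give the unsaturated controller.
#'
#' @param proc a `crn_process`.
#' @param mu setpoint-encoding production rate.
#' @param theta sensing gain.
#' @param eta sequestration rate.
#' @param k actuation gain.
#' @param sats a [make_saturations()] pair (default identity/identity).
#' @param dilution optional first-order dilution rate of `Z1`, `Z2`
#'   (default 0; slow dilution makes the integral action leaky).
#' @return a [reaction_network()] on `(x..., Z1, Z2)`.
#' @export
closed_loop_aif <- function(proc, mu, theta, eta, k, sats = make_saturations(),
                            dilution = 0) {
  stopifnot(inherits(proc, "crn_process"), mu > 0, theta > 0, eta > 0, k > 0,
            dilution >= 0)
  out <- proc$output_species
  inp <- proc$input_species
  ha <- sats$ha; hs <- sats$hs
  ctrl <- list(
    reaction(stats::setNames(1, "Z1"), function(x, t, p) p$mu, name = "setpoint"),
    reaction(stats::setNames(1, "Z2"),
             function(x, t, p) p$theta * hs(x[[out]]), name = "sensing"),
    reaction(c(Z1 = -1, Z2 = -1),
             function(x, t, p) p$eta * x[["Z1"]] * x[["Z2"]], name = "sequestration"),
    reaction(stats::setNames(1, inp),
             function(x, t, p) p$k * ha(x[["Z1"]]), name = "actuation"))
  if (dilution > 0) {
    ctrl <- c(ctrl, list(
      reaction(c(Z1 = -1), function(x, t, p) p$dilution * x[["Z1"]]),
      reaction(c(Z2 = -1), function(x, t, p) p$dilution * x[["Z2"]])))
  }
  reaction_network(
    species = c(proc$species, "Z1", "Z2"),
    reactions = c(proc$reactions, ctrl),
    parameters = c(proc$parameters,
                   list(mu = mu, theta = theta, eta = eta, k = k,
                        dilution = dilution)))
}

#' Reduced (strong-sequestration) antithetic controller loop
#'
#' The closed loop with the controller replaced by its signed-coordinate
#' limit: `zdot = mu - theta * hs(y)`, `u = k * ha(max(z, 0))`.
#'
#' @inheritParams closed_loop_aif
#' @return an [ode_system()] on `(x..., Z)` with `Z` signed.
#' @export
closed_loop_reduced_aif <- function(proc, mu, theta, k,
                                    sats = make_saturations()) {
  stopifnot(inherits(proc, "crn_process"))
  out <- proc$output_species
  ha <- sats$ha; hs <- sats$hs
  ode_system(
    species = c(proc$species, "Z"),
    rhs = function(t, s, p) {
      x <- s[proc$species]
      u <- p$k * ha(max(s[["Z"]], 0))
      c(process_deriv(proc, x, u, t, p),
        p$mu - p$theta * hs(x[[out]]))
    },
    parameters = c(proc$parameters, list(mu = mu, theta = theta, k = k)),
    signed_species = "Z")
}

#' Fast-sequestration spec of an antithetic closed loop
#'
#' Casts the closed loop into the canonical form with `W1 = mu` and
#' `W2 = theta * hs(y)`, for use with [reduce()], [discrepancy()] and
#' [convergence_study()].
#'
#' @inheritParams closed_loop_aif
#' @param x0 initial process state (default all-zero).
#' @param a,b initial controller species.
#' @param schedules optional schedules (e.g. a `Delta` disturbance).
#' @return a [fast_seq_spec()].
#' @export
aif_fast_seq_spec <- function(proc, mu, theta, eta, k,
                              sats = make_saturations(), x0 = NULL,
                              a = 0, b = 0, schedules = list()) {
  stopifnot(inherits(proc, "crn_process"))
  if (is.null(x0)) {
    x0 <- stats::setNames(numeric(length(proc$species)), proc$species)
  }
  out <- proc$output_species
  ha <- sats$ha; hs <- sats$hs
  fast_seq_spec(
    F = function(x, z1, z2, t, p) process_deriv(proc, x, p$k * ha(z1), t, p),
    W1 = function(x, z1, z2, t, p) p$mu,
    W2 = function(x, z1, z2, t, p) p$theta * hs(x[[out]]),
    eta = eta, x0 = x0, a = a, b = b, x_names = proc$species,
    parameters = c(proc$parameters, list(mu = mu, theta = theta, k = k)),
    schedules = schedules)
}

#' Map the input setpoint to the output setpoint
#'
#' At a stable closed-loop steady state the sensed output equals the input
#' setpoint `r_in = mu / theta`, so the output setpoint solves
#' `hs(r_out) = r_in`. Monotone sensing makes the solution unique.
#'
#' @param hs strictly increasing sensing function.
#' @param r_in input setpoint.
#' @param tol root tolerance.
#' @return `r_out` with `hs(r_out) = r_in` to within `tol`.
#' @export
map_setpoints <- function(hs, r_in, tol = 1e-10) {
  stopifnot(is.function(hs))
  if (abs(hs(r_in) - r_in) < tol) return(r_in) # identity fast path
  hi <- 1
  while (hs(hi) < r_in) {
    hi <- hi * 2
    if (hi > 1e12) {
      stop("sensor-saturated: r_in = ", r_in, " outside range(hs)")
    }
  }
  stats::uniroot(function(y) hs(y) - r_in, c(0, hi), tol = tol)$root
}

#' Effective actuation nonlinearity of the reduced loop
#'
#' The reduced controller actuates through
#' `psi_a(v) = k * ha(max(v, 0) / k)` where `v = k z` is the integrator
#' output; with identity `ha` this is the one-sided saturation `max(v, 0)`.
#'
#' @param ha actuation nonlinearity.
#' @param k actuation gain.
#' @return a function of `v`.
#' @export
psi_a <- function(ha, k) {
  function(v) k * ha(pmax(v, 0) / k)
}

#' Fixed-point existence analysis of the closed loop
#'
#' Checks the three algebraic conditions for a closed-loop fixed point with a
#' feasible supporting input: (1) the (output) setpoint is admissible, (2)
#' the sensor does not saturate at steady state, (3) the actuator does not
#' saturate at steady state. When the conditions hold, the fixed point is
#' `w = r_in`, `y = hs^{-1}(r_in)`, `u = map^{-1}(y)`,
#' `v = psi_a^{-1}(u)`. With no sensing/actuation nonlinearities
#' (`sats = NULL`, finite `u_range`/`y_range`) the classical saturation-block
#' conditions are checked instead. Conditions holding exactly at a range
#' boundary are reported as existing with a `boundary` note.
#'
#' @param map an [affine_io_map()] (or monotone function) of the process.
#' @param r desired output setpoint (alternatively give `r_in`).
#' @param r_in desired input setpoint (`mu/theta` for the antithetic
#'   controller); the output setpoint is then recovered through the sensing
#'   function, and failure to invert is a sensor saturation.
#' @param U feasible-input [interval()].
#' @param sats optional [make_saturations()] pair; when supplied, `k` must be
#'   given and the conditions of the saturated loop are used.
#' @param k actuation gain (with `sats`).
#' @param u_range,y_range classical saturation ranges (without `sats`).
#' @return object of class `fixed_point_report`: list with `exists`,
#'   `failed_conditions` (subset of `"setpoint-inadmissible"`,
#'   `"sensor-saturated"`, `"actuator-saturated"`), `fixed_point`
#'   (`y`, `u`, `v`, `w` when it exists) and `boundary` flag.
#' @export
fixed_point_exists <- function(map, r = NULL, r_in = NULL,
                               U = interval(0, Inf), sats = NULL,
                               k = NULL, u_range = c(-Inf, Inf),
                               y_range = c(-Inf, Inf)) {
  failed <- character(0)
  boundary <- FALSE
  if (is.null(sats)) {
    stopifnot(!is.null(r))
    ubar <- tryCatch(supporting_input(map, r, U = U),
                     error = function(e) NA_real_)
    if (is.na(ubar)) failed <- c(failed, "setpoint-inadmissible")
    w <- r; y <- r
    if (!(r >= y_range[1] && r <= y_range[2])) {
      failed <- c(failed, "sensor-saturated")
    } else if (r %in% y_range) boundary <- TRUE
    if (!is.na(ubar)) {
      if (!(ubar >= u_range[1] && ubar <= u_range[2])) {
        failed <- c(failed, "actuator-saturated")
      } else if (ubar %in% u_range) boundary <- TRUE
    }
    v <- ubar
  } else {
    stopifnot(!is.null(k))
    hs <- sats$hs; ha <- sats$ha
    # sensor condition: the input setpoint must be reachable by the sensed
    # signal, i.e. r_in in range(psi_s) = range(hs)
    if (is.null(r)) {
      stopifnot(!is.null(r_in))
      r <- tryCatch(map_setpoints(hs, r_in), error = function(e) NA_real_)
      if (is.na(r)) failed <- c(failed, "sensor-saturated")
    } else {
      r_in <- hs(r)
    }
    y <- r; w <- r_in
    ubar <- NA_real_
    v <- NA_real_
    if (!is.na(r)) {
      ubar <- tryCatch(supporting_input(map, r, U = U),
                       error = function(e) NA_real_)
      if (is.na(ubar)) failed <- c(failed, "setpoint-inadmissible")
    }
    if (!is.na(ubar)) {
      pa <- psi_a(ha, k)
      pa_sup <- pa(1e12 * max(1, k))
      if (!(ubar >= 0 && ubar < pa_sup)) {
        failed <- c(failed, "actuator-saturated")
      } else if (ubar > 0) {
        vhi <- max(1, k)
        while (pa(vhi) < ubar) vhi <- vhi * 2
        v <- stats::uniroot(function(v) pa(v) - ubar, c(0, vhi),
                            tol = 1e-12)$root
      } else v <- 0
    }
  }
  failed <- unique(failed)
  exists <- length(failed) == 0L
  structure(list(
    exists = exists, failed_conditions = failed, boundary = boundary,
    fixed_point = if (exists) list(y = y, u = ubar, v = v, w = w) else NULL),
    class = "fixed_point_report")
}

#' @export
print.fixed_point_report <- function(x, ...) {
  if (x$exists) {
    cat("<fixed_point_report> exists",
        if (x$boundary) "(at a saturation boundary)", "\n")
    fp <- x$fixed_point
    cat(sprintf("  y = %.6g  u = %.6g  v = %.6g  w = %.6g\n",
                fp$y, fp$u, fp$v, fp$w))
  } else {
    cat("<fixed_point_report> no fixed point; failed:",
        paste(x$failed_conditions, collapse = ", "), "\n")
  }
  invisible(x)
}
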