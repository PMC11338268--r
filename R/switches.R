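#' Sequestration-based biomolecular switch
#'
#' Two species `V1`, `V2` sequester each other at rate `eta_v` while
#' degrading separately:
#' \deqn{\dot v_1 = u_0 - \eta_v v_1 v_2 - \delta_1 v_1, \quad
#'       \dot v_2 = u - \eta_v v_1 v_2 - \delta_2 v_2.}
#' The input `u` is the production rate of `V2` and the constitutive
#' production rate `u0` of `V1` sets the threshold: in the
#' strong-sequestration limit the steady-state response is the
#' threshold-linear map `v2 = max(u - u0, 0) / delta2`. `V2` is read out
#' through a monotone function `h` — increasing for an activator switch,
#' decreasing (e.g. a Hill repressor) for a repressor switch.
#'
#' @param u0 threshold production rate of `V1` (> 0).
#' @param eta_v sequestration rate (> 0).
#' @param delta1,delta2 degradation rates (> 0); smaller `delta2` steepens the
#'   post-threshold slope (`1/delta2`).
#' @param mode `"activator"` or `"repressor"`.
#' @param h output readout applied to `v2` (default identity); must be
#'   nondecreasing for activator mode and nonincreasing for repressor mode.
#' @return object of class `seq_switch`.
#' @export
seq_switch <- function(u0, eta_v, delta1 = 1, delta2 = 1,
                       mode = c("activator", "repressor"), h = NULL) {
  mode <- match.arg(mode)
  stopifnot(u0 > 0, eta_v > 0, delta1 > 0, delta2 > 0)
  if (is.null(h)) {
    if (mode == "repressor") {
      stop("repressor mode requires an explicit decreasing readout h")
    }
    h <- function(v2) v2
  }
  probe <- seq(0, 10 * u0 / delta2, length.out = 33L)
  dh <- diff(vapply(probe, h, numeric(1)))
  if (mode == "activator" && any(dh < -1e-12)) {
    stop("activator readout h must be nondecreasing")
  }
  if (mode == "repressor" && any(dh > 1e-12)) {
    stop("repressor readout h must be nonincreasing")
  }
  structure(list(u0 = u0, eta_v = eta_v, delta1 = delta1, delta2 = delta2,
                 mode = mode, h = h),
            class = "seq_switch")
}

#' Reaction network of a standalone switch
#'
#' @param sw a [seq_switch()].
#' @param u input production rate of `V2` (scalar); attach a schedule named
#'   `"u"` to the returned network to vary it.
#' @return a [reaction_network()] on `(V1, V2)`.
#' @export
switch_network <- function(sw, u) {
  stopifnot(inherits(sw, "seq_switch"), u >= 0)
  reaction_network(
    species = c("V1", "V2"),
    reactions = list(
      reaction(c(V1 = 1), function(x, t, p) p$u0, name = "threshold production"),
      reaction(c(V2 = 1), function(x, t, p) p$u, name = "input production"),
      reaction(c(V1 = -1, V2 = -1),
               function(x, t, p) p$eta_v * x[["V1"]] * x[["V2"]],
               name = "sequestration"),
      reaction(c(V1 = -1), function(x, t, p) p$delta1 * x[["V1"]]),
      reaction(c(V2 = -1), function(x, t, p) p$delta2 * x[["V2"]])),
    parameters = list(u0 = sw$u0, u = u, eta_v = sw$eta_v,
                      delta1 = sw$delta1, delta2 = sw$delta2))
}

#' Signed-coordinate reduction of a standalone switch
#'
#' The strong-sequestration limit of the switch as a jump/ODE system on the
#' signed coordinate `z = v1 - v2`: birth at rate `u0 + delta2 * max(-z, 0)`
#' and death at rate `u + delta1 * max(z, 0)`, whose deterministic drift is
#' `u0 - u - delta1 z+ + delta2 z-`.
#'
#' @inheritParams switch_network
#' @return a [reaction_network()] on the signed species `Z`.
#' @export
switch_reduced_network <- function(sw, u) {
  stopifnot(inherits(sw, "seq_switch"), u >= 0)
  reaction_network(
    species = "Z",
    reactions = list(
      reaction(c(Z = 1), function(x, t, p) p$u0),
      reaction(c(Z = -1), function(x, t, p) p$u),
      reaction(c(Z = -1), function(x, t, p) p$delta1 * max(x[["Z"]], 0)),
      reaction(c(Z = 1), function(x, t, p) p$delta2 * max(-x[["Z"]], 0))),
    parameters = list(u0 = sw$u0, u = u, delta1 = sw$delta1,
                      delta2 = sw$delta2),
    signed_species = "Z")
}

#' Fast-sequestration spec of a standalone switch
#'
#' @inheritParams switch_network
#' @param a,b initial values of `V1`, `V2`.
#' @return a [fast_seq_spec()] with `W1 = u0 - delta1 * v1` and
#'   `W2 = u - delta2 * v2` (aggregate non-sequestration fluxes).
#' @export
switch_fast_seq_spec <- function(sw, u, a = 0, b = 0) {
  stopifnot(inherits(sw, "seq_switch"))
  fast_seq_spec(
    W1 = function(x, z1, z2, t, p) p$u0 - p$delta1 * z1,
    W2 = function(x, z1, z2, t, p) p$u - p$delta2 * z2,
    eta = sw$eta_v, a = a, b = b,
    parameters = list(u0 = sw$u0, u = u, delta1 = sw$delta1,
                      delta2 = sw$delta2))
}

#' Closed-form strong-sequestration steady state of the switch
#'
#' `v2 = max(u - u0, 0) / delta2`: zero below the threshold `u0`,
#' linear with slope `1/delta2` above it. Composing with the readout `h`
#' gives the switch output.
#'
#' @param u input production rate(s).
#' @param u0 threshold production rate.
#' @param delta2 degradation rate of `V2`.
#' @return steady-state `v2` value(s).
#' @export
switch_steady_state_closed_form <- function(u, u0, delta2 = 1) {
  stopifnot(u0 > 0, delta2 > 0)
  pmax(u - u0, 0) / delta2
}

#' Steady-state response curve of a switch
#'
#' Sweeps the input over a grid, solving the full two-species ODE to steady
#' state at each point and comparing with the strong-sequestration closed
#' form.
#'
#' @param sw a [seq_switch()].
#' @param u_grid nonnegative input grid.
#' @param t_max steady-state time budget per point.
#' @param ... passed to [find_steady_state()].
#' @return data.frame `(u, v2_full, v2_closed)` with attributes `max_gap`
#'   (largest absolute difference) and `nonconverged` (inputs whose
#'   steady-state search did not converge, flagged `NA`).
#' @export
sweep_response <- function(sw, u_grid, t_max = 200, ...) {
  stopifnot(inherits(sw, "seq_switch"), length(u_grid) >= 1L, all(u_grid >= 0))
  v2_full <- vapply(u_grid, function(u) {
    net <- switch_network(sw, u)
    ss <- find_steady_state(net, c(V1 = 0, V2 = 0), t_max = t_max, ...)
    if (ss$status == "converged") ss$state[["V2"]] else NA_real_
  }, numeric(1))
  v2_closed <- switch_steady_state_closed_form(u_grid, sw$u0, sw$delta2)
  out <- data.frame(u = u_grid, v2_full = v2_full, v2_closed = v2_closed)
  attr(out, "max_gap") <- max(abs(v2_full - v2_closed), na.rm = TRUE)
  attr(out, "nonconverged") <- u_grid[is.na(v2_full)]
  out
}
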