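#' Scenario fixtures
#'
#' Prebuilt closed-loop simulations carrying the package's canonical
#' parameter sets, each with machine-checkable expected outcomes. Available
#' scenarios:
#'
#' * `"aif-windup"` — unsaturated antithetic loop around unit-rate gene
#'   expression (`mu = 10`, `eta = 100`, `k = theta = k1 = gamma1 = gamma2 =
#'   1`, setpoint 10). The basal-transcription disturbance is stepped
#'   `0 -> 5 -> 12 -> 5`; the admissible-disturbance set is `[0, 10]`, so the
#'   12 plateau triggers windup of `Z2` and a slow recovery.
#' * `"sat-tracking"` — saturated loop (`k1 = gamma1 = gamma2 = 1`,
#'   `eta = 100`, `theta = 15`, `k = 8`, Hill actuation/sensing with
#'   `kappa_a = kappa_s = 5`), disturbance fixed at 5 while `mu` is stepped
#'   `10 -> 9 -> 12 -> 10` across the admissible band
#'   `theta * hs([5, 13]) = [7.5, 10.8333]`; the 12 plateau winds up `Z1`.
#' * `"sat-rejection"` — same loop with `mu = 10` fixed and the disturbance
#'   stepped `5 -> 12 -> 5 -> 0 -> 5` across the admissible band `[2, 10]`;
#'   the 12 plateau winds up `Z2` and the 0 plateau winds up `Z1`.
#' * `"antiwindup"` — the `sat-rejection` loop at `mu = 10` equipped with
#'   anti-windup topology I (`eta_v = eta_w = 100`, `v0 = 10`, `w0 = 20`,
#'   unit switch degradations, identity switch maps), with a 60-time-unit
#'   disturbance pulse to 15 (50% beyond the admissible ceiling).
#'
#' @param name scenario name.
#' @return a `scenario` object: list with `name`, `description`, `model`,
#'   `x0`, `t_max`, `n_out`, `output`, `setpoint`, `windows` and
#'   `expected_outcomes`.
#' @export
get_scenario <- function(name) {
  builders <- list(
    "aif-windup" = scenario_aif_windup,
    "sat-tracking" = scenario_saturated_tracking,
    "sat-rejection" = scenario_saturated_rejection,
    "antiwindup" = scenario_antiwindup)
  if (!name %in% names(builders)) {
    stop("unknown scenario '", name, "'; available: ",
         paste(names(builders), collapse = ", "))
  }
  builders[[name]]()
}

#' @rdname get_scenario
#' @export
list_scenarios <- function() {
  c("aif-windup", "sat-tracking", "sat-rejection", "antiwindup")
}

new_scenario <- function(name, description, model, x0, t_max, output,
                         setpoint, windows = list(), expected_outcomes = list(),
                         n_out = 1501L) {
  structure(list(name = name, description = description, model = model,
                 x0 = x0, t_max = t_max, n_out = n_out, output = output,
                 setpoint = setpoint, windows = windows,
                 expected_outcomes = expected_outcomes),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario>", x$name, "\n", x$description, "\n")
  cat("horizon:", x$t_max, " output:", x$output, " setpoint:", x$setpoint, "\n")
  invisible(x)
}

# mean of an output over the tail of a time window
window_level <- function(traj, species, t_from, t_to) {
  sel <- traj$times >= t_from & traj$times <= t_to
  mean(traj$states[sel, species])
}

outcome <- function(check, pass, measured, expected) {
  list(check = check, pass = isTRUE(pass), measured = measured,
       expected = expected)
}

#' @rdname get_scenario
#' @export
scenario_aif_windup <- function() {
  proc <- gene_expression_process(k1 = 1, gamma1 = 1, gamma2 = 1, Delta = 0)
  net <- closed_loop_aif(proc, mu = 10, theta = 1, eta = 100, k = 1)
  net$schedules <- list(Delta = schedule(c(0, 60, 120, 180), c(0, 5, 12, 5)))
  x0 <- stats::setNames(numeric(length(net$species)), net$species)
  expected <- list(
    function(traj, sc) {
      y <- window_level(traj, "X2", 110, 120)
      outcome("output settles at the setpoint on the admissible plateau",
              abs(y - 10) < 0.1, y, 10)
    },
    function(traj, sc) {
      sel <- traj$times >= 130 & traj$times <= 175
      z2 <- traj$states[sel, "Z2"]
      outcome("Z2 grows monotonically under the inadmissible disturbance",
              all(diff(z2) > 0), max(z2), "monotone growth")
    },
    function(traj, sc) {
      y <- window_level(traj, "X2", 290, 300)
      outcome("output re-settles at the setpoint after the disturbance reverts",
              abs(y - 10) < 0.1, y, 10)
    })
  new_scenario(
    "aif-windup",
    "Windup of the unsaturated antithetic loop driven past its admissible disturbances",
    net, x0, t_max = 300, output = "X2", setpoint = 10,
    windows = list(disturbance = c(120, 180)),
    expected_outcomes = expected)
}

saturated_loop <- function(mu = 10, Delta = 5) {
  proc <- gene_expression_process(k1 = 1, gamma1 = 1, gamma2 = 1, Delta = Delta)
  sats <- make_saturations("hill", "hill", kappa_a = 5, kappa_s = 5)
  closed_loop_aif(proc, mu = mu, theta = 15, eta = 100, k = 8, sats = sats)
}

#' @rdname get_scenario
#' @export
scenario_saturated_tracking <- function() {
  net <- saturated_loop(mu = 10, Delta = 5)
  net$schedules <- list(mu = schedule(c(0, 60, 120, 180), c(10, 9, 12, 10)))
  x0 <- stats::setNames(numeric(length(net$species)), net$species)
  expected <- list(
    function(traj, sc) {
      y <- window_level(traj, "X2", 50, 60)
      outcome("output tracks the nominal setpoint", abs(y - 10) < 0.1, y, 10)
    },
    function(traj, sc) {
      y <- window_level(traj, "X2", 110, 120)
      outcome("output tracks the stepped-down admissible setpoint",
              abs(y - 7.5) < 0.1, y, 7.5)
    },
    function(traj, sc) {
      sel <- traj$times >= 130 & traj$times <= 175
      z1 <- traj$states[sel, "Z1"]
      outcome("Z1 winds up when the demanded setpoint is inadmissible",
              all(diff(z1) > 0), max(z1), "monotone growth")
    })
  new_scenario(
    "sat-tracking",
    "Setpoint tracking of the saturated antithetic loop across the admissible input-setpoint band",
    net, x0, t_max = 300, output = "X2", setpoint = 10,
    windows = list(disturbance = c(120, 180)),
    expected_outcomes = expected)
}

#' @rdname get_scenario
#' @export
scenario_saturated_rejection <- function() {
  net <- saturated_loop(mu = 10, Delta = 5)
  net$schedules <- list(
    Delta = schedule(c(0, 60, 120, 180, 240), c(5, 12, 5, 0, 5)))
  x0 <- stats::setNames(numeric(length(net$species)), net$species)
  expected <- list(
    function(traj, sc) {
      y <- window_level(traj, "X2", 50, 60)
      outcome("output holds the setpoint under the admissible disturbance",
              abs(y - 10) < 0.1, y, 10)
    },
    function(traj, sc) {
      sel <- traj$times >= 70 & traj$times <= 115
      z2 <- traj$states[sel, "Z2"]
      outcome("Z2 accumulates when the disturbance exceeds the admissible ceiling",
              all(diff(z2) > 0), max(z2), "monotone growth")
    },
    function(traj, sc) {
      sel <- traj$times >= 190 & traj$times <= 235
      z1 <- traj$states[sel, "Z1"]
      outcome("Z1 accumulates when the disturbance falls below the admissible floor",
              all(diff(z1) > 0), max(z1), "monotone growth")
    })
  new_scenario(
    "sat-rejection",
    "Disturbance rejection of the saturated antithetic loop across the admissible disturbance band",
    net, x0, t_max = 320, output = "X2", setpoint = 10,
    windows = list(disturbance = c(60, 120)),
    expected_outcomes = expected)
}

#' @rdname get_scenario
#' @export
scenario_antiwindup <- function(antiwindup = TRUE) {
  proc <- gene_expression_process(k1 = 1, gamma1 = 1, gamma2 = 1, Delta = 5)
  sats <- make_saturations("hill", "hill", kappa_a = 5, kappa_s = 5)
  net <- closed_loop_antiwindup(
    proc, mu = 10, theta = 15, eta = 100, k = 8, sats = sats,
    topology = "I", v0 = 10, w0 = 20, eta_v = 100, eta_w = 100,
    deltas = c(1, 1, 1, 1), switches_enabled = antiwindup)
  net$schedules <- list(Delta = schedule(c(0, 60, 120), c(5, 15, 5)))
  x0 <- stats::setNames(numeric(length(net$species)), net$species)
  expected <- if (antiwindup) list(
    function(traj, sc) {
      sel <- traj$times >= 40 & traj$times <= 60
      act <- max(traj$states[sel, "V2"], traj$states[sel, "W2s"])
      outcome("anti-windup species stay dormant in the admissible phase",
              act < 0.01 * 10, act, "< 1% of mu")
    },
    function(traj, sc) {
      y <- window_level(traj, "X2", 50, 60)
      outcome("output holds the setpoint before the pulse",
              abs(y - 10) < 0.15, y, 10)
    },
    function(traj, sc) {
      m <- windup_metrics(traj, c("Z1", "Z2"), "X2", 10, c(60, 120),
                          threshold = 20)
      outcome("tracking error recovers within 40 time units of the pulse end",
              m$recovery_time < 40, m$recovery_time, "< 40")
    })
  else list(
    function(traj, sc) {
      sel <- traj$times >= 70 & traj$times <= 118
      z2 <- traj$states[sel, "Z2"]
      outcome("without protection Z2 winds up during the pulse",
              all(diff(z2) > 0), max(z2), "monotone growth")
    })
  new_scenario(
    if (antiwindup) "antiwindup" else "antiwindup-off",
    paste("Saturated antithetic loop with topology-I anti-windup circuitry",
          if (!antiwindup) "(switches disabled)" else "",
          "under an inadmissible disturbance pulse"),
    net, x0, t_max = 300, output = "X2", setpoint = 10,
    windows = list(disturbance = c(60, 120)),
    expected_outcomes = expected)
}

#' Run a scenario
#'
#' @param sc a `scenario` (or its name).
#' @param ... solver options passed to [simulate_ode()].
#' @return a trajectory.
#' @export
run_scenario <- function(sc, ...) {
  if (is.character(sc)) sc <- get_scenario(sc)
  stopifnot(inherits(sc, "scenario"))
  simulate_ode(sc$model, sc$x0, t_max = sc$t_max, n_out = sc$n_out, ...)
}

#' Evaluate a scenario's expected outcomes
#'
#' @param sc a `scenario` (or its name).
#' @param traj optional precomputed trajectory (defaults to running the
#'   scenario).
#' @param ... solver options for [run_scenario()].
#' @return data.frame with one row per outcome (`check`, `pass`, `measured`,
#'   `expected`); attribute `"pass"` is the conjunction.
#' @export
check_scenario <- function(sc, traj = NULL, ...) {
  if (is.character(sc)) sc <- get_scenario(sc)
  stopifnot(inherits(sc, "scenario"))
  if (is.null(traj)) traj <- run_scenario(sc, ...)
  rows <- lapply(sc$expected_outcomes, function(f) {
    o <- f(traj, sc)
    data.frame(check = o$check, pass = o$pass,
               measured = paste(signif(unlist(o$measured), 6), collapse = ", "),
               expected = paste(o$expected, collapse = ", "))
  })
  out <- do.call(rbind, rows)
  attr(out, "pass") <- all(out$pass)
  out
}
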