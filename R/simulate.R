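#' Trajectory container
#'
#' @param times numeric vector of increasing times.
#' @param states matrix (time x species) of concentrations or copy numbers.
#' @param meta list of metadata (solver, tolerances, seed, ...).
#' @return object of class `trajectory`.
#' @export
new_trajectory <- function(times, states, meta = list()) {
  states <- as.matrix(states)
  stopifnot(length(times) == nrow(states))
  structure(list(times = as.numeric(times), states = states, meta = meta),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$times), " time points over [",
      signif(min(x$times), 4), ", ", signif(max(x$times), 4), "], species: ",
      paste(colnames(x$states), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}

#' Final state of a trajectory
#' @param traj a [new_trajectory()].
#' @return named numeric vector.
#' @export
final_state <- function(traj) {
  stats::setNames(traj$states[nrow(traj$states), ], colnames(traj$states))
}

#' Interpolate a trajectory column onto a grid
#' @param traj a trajectory.
#' @param species column name.
#' @param times grid to interpolate onto (default: the stored grid).
#' @return numeric vector.
#' @export
traj_interp <- function(traj, species, times = traj$times) {
  stats::approx(traj$times, traj$states[, species], xout = times, rule = 2)$y
}

#' Deterministic simulation of a model
#'
#' Integrates the mass-action (or user-supplied) vector field with a
#' stiff-capable solver. The integration is restarted at every schedule
#' breakpoint so that piecewise-constant disturbances are resolved exactly
#' rather than smoothed over by the step-size controller. States that
#' round-off slightly negative (within `10 * atol` of zero) are clipped to
#' zero; larger negative excursions are left visible since they indicate a
#' modeling error.
#'
#' @param model a [reaction_network()] or [ode_system()].
#' @param x0 initial state (named or in species order); nonnegative for the
#'   non-signed species.
#' @param t_max end of the (finite) horizon; integration starts at `t0`.
#' @param t0 start time (default 0).
#' @param n_out number of equally spaced output points (ignored when `times`
#'   is given).
#' @param times explicit output grid.
#' @param rtol,atol relative/absolute solver tolerances. Sequestration rates
#'   of order 1e4 make these systems stiff, hence the tight defaults and the
#'   implicit-capable `lsoda` method.
#' @param method deSolve method name.
#' @return a [new_trajectory()].
#' @examples
#' bd <- reaction_network(c("X"),
#'   list(reaction(c(X = 1), "lambda"), reaction(c(X = -1), "gamma * X")),
#'   parameters = list(lambda = 2, gamma = 1))
#' traj <- simulate_ode(bd, c(X = 0), t_max = 5)
#' final_state(traj) # ~ 2 * (1 - exp(-5))
#' @export
simulate_ode <- function(model, x0, t_max, t0 = 0, n_out = 501, times = NULL,
                         rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  stopifnot(inherits(model, "crn_model"), is.finite(t_max), t_max >= t0)
  x0 <- named_state(model, x0)
  neg0 <- setdiff(names(x0)[x0 < 0], model$signed_species)
  if (length(neg0)) stop("negative initial condition for: ", paste(neg0, collapse = ", "))
  if (is.null(times)) {
    times <- seq(t0, t_max, length.out = max(2L, n_out))
  }
  stopifnot(times[1] == t0, !is.unsorted(times))
  if (t_max == t0) {
    return(new_trajectory(t0, matrix(x0, nrow = 1,
                                     dimnames = list(NULL, model$species)),
                          meta = list(solver = method, rtol = rtol, atol = atol)))
  }
  rhs <- model_rhs(model)
  dfun <- function(t, y, parms) list(rhs(t, y))

  breaks <- schedule_breaks(model$schedules, t0, t_max)
  seg_edges <- unique(c(t0, breaks, t_max))
  # snap output times onto segment edges so that restarts never leave two
  # output points separated by a sub-tolerance gap (lsoda rejects those)
  snap <- vapply(times, function(tt) {
    j <- which(abs(seg_edges - tt) < 1e-9 * max(1, abs(tt)))
    if (length(j)) seg_edges[j[1]] else tt
  }, numeric(1))
  out_times <- unique(sort(c(snap, seg_edges)))

  all_t <- numeric(0)
  all_x <- NULL
  cur <- x0
  for (i in seq_len(length(seg_edges) - 1L)) {
    a <- seg_edges[i]; b <- seg_edges[i + 1L]
    seg_times <- unique(c(a, out_times[out_times > a & out_times <= b], b))
    out <- tryCatch(
      deSolve::ode(y = cur, times = seg_times, func = dfun, parms = NULL,
                   method = method, rtol = rtol, atol = atol, maxsteps = 1e5),
      warning = function(w) stop("ODE solver failed near t=", signif(a, 6),
                                 ": ", conditionMessage(w), call. = FALSE)
    )
    if (nrow(out) < length(seg_times) || any(!is.finite(out))) {
      bad <- if (nrow(out)) out[nrow(out), 1] else a
      stop("ODE solver failed near t=", signif(bad, 6),
           " (stiffness or step underflow)")
    }
    st <- out[, -1, drop = FALSE]
    # clip round-off negatives
    clip <- st < 0 & st > -10 * atol
    st[clip] <- 0
    all_t <- c(all_t, out[, 1])
    all_x <- rbind(all_x, st)
    cur <- stats::setNames(st[nrow(st), ], model$species)
  }
  keep <- !duplicated(all_t)
  sel <- all_t[keep] %in% snap | all_t[keep] %in% seg_edges
  new_trajectory(all_t[keep][sel], all_x[keep, , drop = FALSE][sel, , drop = FALSE],
                 meta = list(solver = method, rtol = rtol, atol = atol))
}

#' Exact stochastic simulation (Gillespie direct method)
#'
#' One realization of the jump process whose intensities are the network
#' propensities evaluated at integer copy numbers. Schedules are honored by
#' restarting the chain at each breakpoint (propensities are re-evaluated
#' after every event, so only explicit time dependence between events would
#' be missed; piecewise-constant parameters have none).
#'
#' @param network a [reaction_network()].
#' @param x0 nonnegative integer initial copy numbers.
#' @param t_max horizon.
#' @param seed integer RNG seed; the event sequence is reproducible given the
#'   seed.
#' @param times recording grid (default 201 equally spaced points); the state
#'   recorded at a grid time is the state just after the last event at or
#'   before it.
#' @param max_events safety cap on the number of jumps.
#' @return a [new_trajectory()] with `meta$seed`.
#' @export
simulate_ssa <- function(network, x0, t_max, seed = NULL, times = NULL,
                         max_events = 1e7) {
  stopifnot(inherits(network, "reaction_network"))
  x0 <- named_state(network, x0)
  if (any(x0 != round(x0))) stop("SSA initial state must be integer copy numbers")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(times)) times <- seq(0, t_max, length.out = 201L)
  stopifnot(!is.unsorted(times), times[1] >= 0, max(times) <= t_max)

  S <- stoich_matrix(network)
  nr <- ncol(S)
  rec <- matrix(NA_real_, nrow = length(times), ncol = nrow(S),
                dimnames = list(NULL, network$species))
  x <- x0
  t <- 0
  ri <- 1L
  n_ev <- 0L
  seg_edges <- c(0, schedule_breaks(network$schedules, 0, t_max), t_max)
  for (si in seq_len(length(seg_edges) - 1L)) {
    seg_end <- seg_edges[si + 1L]
    p <- params_at(network, seg_edges[si])
    repeat {
      a <- vapply(network$reactions, function(r) r$rate(x, t, p), numeric(1))
      if (any(a < -1e-12)) stop("negative propensity at t=", signif(t, 6))
      a[a < 0] <- 0
      a0 <- sum(a)
      t_next <- if (a0 > 0) t + stats::rexp(1, a0) else Inf
      if (t_next > seg_end) {
        while (ri <= length(times) && times[ri] <= seg_end) {
          rec[ri, ] <- x; ri <- ri + 1L
        }
        t <- seg_end
        break
      }
      while (ri <= length(times) && times[ri] < t_next) {
        rec[ri, ] <- x; ri <- ri + 1L
      }
      j <- sample.int(nr, 1L, prob = a)
      x <- x + S[, j]
      t <- t_next
      n_ev <- n_ev + 1L
      if (n_ev >= max_events) stop("SSA exceeded max_events = ", max_events)
    }
  }
  while (ri <= length(times)) { rec[ri, ] <- x; ri <- ri + 1L }
  new_trajectory(times, rec,
                 meta = list(solver = "ssa-direct", seed = seed, events = n_ev))
}

#' Steady-state search by integration
#'
#' Integrates the model in chunks until the vector field is small
#' (`converged`), a divergence criterion fires (`diverged`), or the time
#' budget is exhausted (`max_time`). Convergence requires
#' `||f(x)|| < tol_rel * ||x|| + tol_abs` at a time past the last schedule
#' breakpoint. Divergence is declared when any state exceeds `div_threshold`,
#' or when, at the horizon, some state is still growing essentially linearly
#' or faster: over the last 20% of the horizon the state must have increased
#' monotonically by a non-trivial amount with a late-window slope at least
#' half the early-window slope (a saturating approach to equilibrium has a
#' decaying slope and is reported as `max_time` instead).
#'
#' @param model a `crn_model`.
#' @param x0 initial state.
#' @param t_max time budget.
#' @param tol_rel,tol_abs convergence tolerances on the vector-field norm.
#' @param div_threshold state magnitude that triggers `diverged`.
#' @param n_chunks number of integration chunks.
#' @param ... passed to [simulate_ode()] (tolerances, method).
#' @return object of class `steady_state_result`: list with `state`,
#'   `residual` (l2 norm of the vector field), `status`, `t`.
#' @export
find_steady_state <- function(model, x0, t_max = 1000, tol_rel = 1e-6,
                              tol_abs = 1e-8, div_threshold = 1e9,
                              n_chunks = 25L, ...) {
  stopifnot(inherits(model, "crn_model"))
  x0 <- named_state(model, x0)
  rhs <- model_rhs(model)
  settle <- schedule_settle_time(model$schedules)
  res0 <- l2norm(rhs(0, x0))
  if (res0 < tol_rel * l2norm(x0) + tol_abs && settle <= 0) {
    return(structure(list(state = x0, residual = res0, status = "converged",
                          t = 0), class = "steady_state_result"))
  }
  edges <- seq(0, t_max, length.out = n_chunks + 1L)
  cur <- x0
  n_keep <- max(1L, ceiling(0.2 * n_chunks))
  window_chunks <- list()
  for (i in seq_len(n_chunks)) {
    tr <- simulate_ode(model, cur, t_max = edges[i + 1L], t0 = edges[i],
                       n_out = 41L, ...)
    cur <- final_state(tr)
    window_chunks[[length(window_chunks) + 1L]] <- tr
    if (length(window_chunks) > n_keep) window_chunks[[1]] <- NULL
    t_now <- edges[i + 1L]
    if (any(abs(cur) > div_threshold)) {
      return(structure(list(state = cur, residual = NA_real_,
                            status = "diverged", t = t_now),
                       class = "steady_state_result"))
    }
    res <- l2norm(rhs(t_now, cur))
    if (t_now > settle && res < tol_rel * l2norm(cur) + tol_abs) {
      return(structure(list(state = cur, residual = res, status = "converged",
                            t = t_now), class = "steady_state_result"))
    }
  }
  # horizon exhausted: windowed slope test over the last 20% of the horizon
  wt <- unlist(lapply(window_chunks, function(tr) tr$times))
  wx <- do.call(rbind, lapply(window_chunks, function(tr) tr$states))
  keep <- !duplicated(wt)
  wt <- wt[keep]; wx <- wx[keep, , drop = FALSE]
  growing <- vapply(seq_along(model$species), function(j) {
    v <- wx[, j]
    n <- length(v)
    inc <- v[n] - v[1]
    scale_ref <- max(abs(v[n]), 1)
    if (inc <= 1e-3 * scale_ref) return(FALSE)
    if (any(diff(v) < -1e-9 * scale_ref)) return(FALSE)
    half <- max(2L, floor(n / 2))
    slope_early <- (v[half] - v[1]) / (wt[half] - wt[1])
    slope_late <- (v[n] - v[half]) / (wt[n] - wt[half])
    slope_late >= 0.5 * slope_early
  }, logical(1))
  res <- l2norm(rhs(t_max, cur))
  status <- if (any(growing)) "diverged" else "max_time"
  structure(list(state = cur, residual = res, status = status, t = t_max),
            class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat("<steady_state_result> status:", x$status, " t:", signif(x$t, 5), "\n")
  if (!is.na(x$residual)) cat("residual:", signif(x$residual, 4), "\n")
  print(signif(x$state, 6))
  invisible(x)
}
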