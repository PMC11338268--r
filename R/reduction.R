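#' Positive and negative parts of a signed scalar or signal
#'
#' `z = z_plus - z_minus` with `z_plus * z_minus = 0` exactly. In the
#' strong-sequestration limit the two sequestering species become the
#' positive and negative parts of a single signed coordinate.
#'
#' @param z numeric scalar or vector.
#' @return list with components `plus` and `minus`.
#' @export
positive_negative_parts <- function(z) {
  list(plus = pmax(z, 0), minus = pmax(-z, 0))
}

#' Specification of a system with one fast sequestration pair
#'
#' Describes the full system: an arbitrary subnetwork `x` with vector field
#' `F(x, z1, z2, t, p)`, and a sequestering pair with aggregate
#' production/removal maps `W1`, `W2` and sequestration rate `eta`:
#' \deqn{\dot z_1 = W_1(x, z_1, z_2) - \eta z_1 z_2, \quad
#'       \dot z_2 = W_2(x, z_1, z_2) - \eta z_1 z_2.}
#'
#' @param F function `(x, z1, z2, t, p)` returning the derivative of `x`; may
#'   be `NULL` when there is no x-subsystem (a standalone switch).
#' @param W1,W2 functions `(x, z1, z2, t, p)` returning nonnegative scalars.
#' @param eta sequestration rate (> 0).
#' @param x0 initial x (possibly length 0).
#' @param a,b nonnegative initial values of the sequestering pair.
#' @param x_names names for the x states.
#' @param parameters,schedules as in [reaction_network()].
#' @return object of class `fast_seq_spec`.
#' @export
fast_seq_spec <- function(F = NULL, W1, W2, eta, x0 = numeric(0), a = 0, b = 0,
                          x_names = names(x0) %||% character(0),
                          parameters = list(), schedules = list()) {
  stopifnot(is.function(W1), is.function(W2), eta > 0, a >= 0, b >= 0,
            length(x0) == length(x_names))
  if (length(x0) > 0) stopifnot(is.function(F))
  structure(list(F = F, W1 = W1, W2 = W2, eta = eta,
                 x0 = stats::setNames(as.numeric(x0), x_names), a = a, b = b,
                 x_names = x_names, parameters = parameters,
                 schedules = schedules),
            class = "fast_seq_spec")
}

#' Full model of a fast-sequestration spec as a simulatable system
#' @param spec a [fast_seq_spec()].
#' @param eta optional override of the sequestration rate.
#' @return an [ode_system()] on `(x..., Z1, Z2)`.
#' @export
full_model <- function(spec, eta = spec$eta) {
  stopifnot(inherits(spec, "fast_seq_spec"))
  xs <- spec$x_names
  ode_system(
    species = c(xs, "Z1", "Z2"),
    rhs = function(t, s, p) {
      x <- s[xs]; z1 <- s[["Z1"]]; z2 <- s[["Z2"]]
      seq_flux <- eta * z1 * z2
      dx <- if (length(xs)) spec$F(x, z1, z2, t, p) else numeric(0)
      c(dx,
        spec$W1(x, z1, z2, t, p) - seq_flux,
        spec$W2(x, z1, z2, t, p) - seq_flux)
    },
    parameters = spec$parameters, schedules = spec$schedules,
    signed_species = character(0))
}

#' Reduce a fast-sequestration system to its signed-coordinate limit
#'
#' In the limit of infinitely fast sequestration the pair `(Z1, Z2)`
#' collapses onto the positive and negative parts of a single signed
#' coordinate `z` with drift `W1 - W2` evaluated at
#' `(x, max(z, 0), max(-z, 0))` and initial condition `a - b`.
#'
#' @param spec a [fast_seq_spec()].
#' @return object of class `reduced_spec`; its `$model` is an [ode_system()]
#'   on `(x..., Z)` with `Z` signed, and `$drift(x, z, t, p)` exposes the
#'   reduced drift directly.
#' @examples
#' # constant production vs proportional sensing: drift mu - theta * xL
#' sp <- fast_seq_spec(
#'   F = function(x, z1, z2, t, p) p$k * z1 - p$g * x,
#'   W1 = function(x, z1, z2, t, p) p$mu,
#'   W2 = function(x, z1, z2, t, p) p$theta * x,
#'   eta = 100, x0 = c(X = 0), a = 0, b = 0,
#'   parameters = list(mu = 10, theta = 1, k = 1, g = 1))
#' red <- reduce(sp)
#' red$drift(c(X = 3), 0, 0, sp$parameters) # 10 - 3
#' @export
reduce <- function(spec) {
  stopifnot(inherits(spec, "fast_seq_spec"))
  xs <- spec$x_names
  drift <- function(x, z, t, p) {
    pn <- positive_negative_parts(z)
    spec$W1(x, pn$plus, pn$minus, t, p) - spec$W2(x, pn$plus, pn$minus, t, p)
  }
  model <- ode_system(
    species = c(xs, "Z"),
    rhs = function(t, s, p) {
      x <- s[xs]; z <- s[["Z"]]
      pn <- positive_negative_parts(z)
      dx <- if (length(xs)) spec$F(x, pn$plus, pn$minus, t, p) else numeric(0)
      c(dx, drift(x, z, t, p))
    },
    parameters = spec$parameters, schedules = spec$schedules,
    signed_species = "Z")
  structure(list(spec = spec, model = model, drift = drift,
                 z0 = spec$a - spec$b),
            class = "reduced_spec")
}

#' Simulate the full and reduced systems of a spec
#' @param spec a [fast_seq_spec()].
#' @param t_max horizon.
#' @param eta optional sequestration-rate override for the full system.
#' @param n_out output grid size.
#' @param ... solver options for [simulate_ode()].
#' @return list with trajectories `full` and `reduced`.
#' @export
simulate_pair <- function(spec, t_max, eta = spec$eta, n_out = 2001L, ...) {
  fm <- full_model(spec, eta = eta)
  rm_ <- reduce(spec)
  full <- simulate_ode(fm, c(spec$x0, Z1 = spec$a, Z2 = spec$b),
                       t_max = t_max, n_out = n_out, ...)
  reduced <- simulate_ode(rm_$model, c(spec$x0, Z = spec$a - spec$b),
                          t_max = t_max, n_out = n_out, ...)
  list(full = full, reduced = reduced)
}

#' Discrepancy between full and reduced trajectories
#'
#' Two convergence metrics: the sup over `[0, T]` of the l2 distance between
#' `(x, z1 - z2)` and `(x, z)`, and the time integral (trapezoidal) of the l2
#' distance between `(x, z1, z2)` and `(x, z+, z-)`. Both tend to 0 as the
#' sequestration rate grows.
#'
#' @param full trajectory of the full system (columns `..., Z1, Z2`).
#' @param reduced trajectory of the reduced system (columns `..., Z`).
#' @param T horizon; both trajectories must cover `[0, T]`.
#' @param n_grid size of the common interpolation grid (>= 2000 by default so
#'   the integral metric is stable under refinement).
#' @return object of class `discrepancy_report`: list with `sup_metric`,
#'   `l1_metric`, `T`, `n_grid`.
#' @export
discrepancy <- function(full, reduced, T, n_grid = 2001L) {
  stopifnot(inherits(full, "trajectory"), inherits(reduced, "trajectory"))
  if (max(full$times) < T || max(reduced$times) < T) {
    stop("trajectories do not cover the requested horizon T=", T)
  }
  xs <- setdiff(colnames(full$states), c("Z1", "Z2"))
  if (!all(c("Z1", "Z2") %in% colnames(full$states)) ||
      !("Z" %in% colnames(reduced$states)) ||
      !all(xs %in% colnames(reduced$states))) {
    stop("species mismatch between full (needs Z1, Z2) and reduced (needs Z)")
  }
  grid <- seq(0, T, length.out = n_grid)
  interp_all <- function(traj, cols) {
    vapply(cols, function(cn) traj_interp(traj, cn, grid), numeric(length(grid)))
  }
  xf <- interp_all(full, xs); xr <- interp_all(reduced, xs)
  z1 <- traj_interp(full, "Z1", grid); z2 <- traj_interp(full, "Z2", grid)
  z <- traj_interp(reduced, "Z", grid)
  pn <- positive_negative_parts(z)
  dx2 <- if (length(xs)) rowSums((xf - xr)^2) else 0
  sup_metric <- max(sqrt(dx2 + ((z1 - z2) - z)^2))
  integrand <- sqrt(dx2 + (z1 - pn$plus)^2 + (z2 - pn$minus)^2)
  l1_metric <- pracma::trapz(grid, integrand)
  structure(list(sup_metric = sup_metric, l1_metric = l1_metric, T = T,
                 n_grid = n_grid, grid_spacing = grid[2] - grid[1]),
            class = "discrepancy_report")
}

#' @export
print.discrepancy_report <- function(x, ...) {
  cat("<discrepancy_report> T =", x$T, "\n  sup:", signif(x$sup_metric, 5),
      "  L1:", signif(x$l1_metric, 5), "\n")
  invisible(x)
}

#' Lift a reduced fixed point to the full-system coordinates
#'
#' A fixed point `(x, z)` of the reduced system corresponds, in the limit of
#' fast sequestration, to the full-system fixed point `(x, z+, z-)`; this is
#' the unique limit point of nonnegative full-system fixed points. If the
#' reduced system has no fixed point, neither does the full system for large
#' sequestration rates.
#'
#' @param reduced a [reduce()]d spec.
#' @param xbar fixed-point x coordinates (named or in `x_names` order).
#' @param zbar signed fixed-point coordinate.
#' @param tol residual tolerance for validating the input fixed point.
#' @param t time at which schedules are evaluated (default: past all
#'   breakpoints).
#' @return named vector `(x..., Z1, Z2)`.
#' @export
lift_fixed_point <- function(reduced, xbar = numeric(0), zbar, tol = 1e-6,
                             t = NULL) {
  stopifnot(inherits(reduced, "reduced_spec"))
  md <- reduced$model
  if (is.null(t)) t <- max(0, schedule_settle_time(md$schedules)) + 1
  s <- c(stats::setNames(as.numeric(xbar), reduced$spec$x_names), Z = zbar)
  resid <- l2norm(model_rhs(md)(t, s))
  if (resid > tol) {
    stop("input is not a fixed point of the reduced system (residual = ",
         signif(resid, 4), " > ", tol, ")")
  }
  pn <- positive_negative_parts(zbar)
  c(stats::setNames(as.numeric(xbar), reduced$spec$x_names),
    Z1 = pn$plus, Z2 = pn$minus)
}

#' Fixed point of the full system by root-finding
#'
#' Solves the full algebraic system with a Newton-type method started from a
#' given point, typically the lifted reduced fixed point (the unique limit
#' point for fast sequestration, which makes it the natural starting guess).
#'
#' @param spec a [fast_seq_spec()].
#' @param start starting point `(x..., Z1, Z2)`.
#' @param eta optional sequestration-rate override.
#' @param t time at which schedules are evaluated.
#' @param tol residual tolerance demanded of the root.
#' @return named fixed-point vector, or an error if no root is found.
#' @export
full_fixed_point <- function(spec, start, eta = spec$eta, t = NULL, tol = 1e-8) {
  md <- full_model(spec, eta = eta)
  if (is.null(t)) t <- max(0, schedule_settle_time(md$schedules)) + 1
  rhs <- model_rhs(md)
  f <- function(v) rhs(t, stats::setNames(v, md$species))
  sol <- tryCatch(pracma::fsolve(f, as.numeric(named_state(md, start)),
                                 tol = 1e-12),
                  error = function(e) NULL)
  if (is.null(sol) || l2norm(f(sol$x)) > tol) {
    stop("no fixed point found for the full system at eta=", eta)
  }
  stats::setNames(sol$x, md$species)
}

#' Convergence study across sequestration rates
#'
#' Runs the full system at each rate in `eta_grid` against the single reduced
#' system and tabulates the discrepancy metrics, all at identical horizons and
#' solver settings. The metrics shrink to zero as the rate grows.
#'
#' @param spec a [fast_seq_spec()].
#' @param eta_grid increasing positive rates.
#' @param T horizon.
#' @param n_out trajectory grid size.
#' @param ... solver options.
#' @return data.frame with columns `eta`, `sup_metric`, `l1_metric`.
#' @export
convergence_study <- function(spec, eta_grid, T, n_out = 2001L, ...) {
  stopifnot(length(eta_grid) >= 1L, all(eta_grid > 0),
            !is.unsorted(eta_grid))
  rm_ <- reduce(spec)
  reduced <- simulate_ode(rm_$model, c(spec$x0, Z = spec$a - spec$b),
                          t_max = T, n_out = n_out, ...)
  rows <- lapply(eta_grid, function(eta) {
    fm <- full_model(spec, eta = eta)
    full <- simulate_ode(fm, c(spec$x0, Z1 = spec$a, Z2 = spec$b),
                         t_max = T, n_out = n_out, ...)
    rep <- discrepancy(full, reduced, T = T, n_grid = n_out)
    data.frame(eta = eta, sup_metric = rep$sup_metric,
               l1_metric = rep$l1_metric)
  })
  do.call(rbind, rows)
}
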