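#' Gene expression process
#'
#' Two-species open-loop process: mRNA `X1` produced at rate `u + Delta`
#' (induced plus basal transcription) and degraded at rate `gamma1 * x1`;
#' protein `X2` translated at `k1 * x1` and degraded at `gamma2 * x2`. The
#' output is the protein concentration `y = x2`. The steady-state
#' input/output map is affine: `y = (k1 / (gamma1 * gamma2)) * (u + Delta)`.
#'
#' @param k1 translation rate (> 0).
#' @param gamma1,gamma2 degradation rates (> 0).
#' @param Delta basal transcription rate (>= 0), a scalar; attach a
#'   [schedule()] named `"Delta"` to a closed-loop network to vary it.
#' @return object of class `c("gene_expression_process", "crn_process")`.
#' @export
gene_expression_process <- function(k1 = 1, gamma1 = 1, gamma2 = 1, Delta = 0) {
  stopifnot(k1 > 0, gamma1 > 0, gamma2 > 0, Delta >= 0)
  structure(list(
    species = c("X1", "X2"),
    input_species = "X1",
    output_species = "X2",
    parameters = list(k1 = k1, gamma1 = gamma1, gamma2 = gamma2, Delta = Delta),
    reactions = list(
      reaction(c(X1 = 1), function(x, t, p) p$Delta, name = "basal transcription"),
      reaction(c(X1 = -1), function(x, t, p) p$gamma1 * x[["X1"]], name = "mRNA degradation"),
      reaction(c(X2 = 1), function(x, t, p) p$k1 * x[["X1"]], name = "translation"),
      reaction(c(X2 = -1), function(x, t, p) p$gamma2 * x[["X2"]], name = "protein degradation")
    )),
    class = c("gene_expression_process", "crn_process"))
}

#' Stable unimolecular process
#'
#' General unimolecular network of `L` species with affine propensities
#' `lambda(x) = W x + b`, actuated by production of species 1 and read out at
#' species `L`: `xdot = S W x + S b + e1 u`, `y = x_L`.
#'
#' @param S stoichiometry matrix, `L` species x `K` reactions.
#' @param W nonnegative `K x L` coefficient matrix.
#' @param b nonnegative length-`K` basal vector.
#' @param species optional species names (default `X1..XL`).
#' @return object of class `c("unimolecular_process", "crn_process")`.
#' @export
unimolecular_process <- function(S, W, b = rep(0, nrow(W)), species = NULL) {
  S <- as.matrix(S); W <- as.matrix(W)
  L <- nrow(S); K <- ncol(S)
  stopifnot(nrow(W) == K, ncol(W) == L, length(b) == K,
            all(W >= 0), all(b >= 0), all(S == round(S)))
  if (is.null(species)) species <- paste0("X", seq_len(L))
  reactions <- lapply(seq_len(K), function(j) {
    st <- stats::setNames(S[, j], species)
    st <- st[st != 0]
    if (!length(st)) st <- stats::setNames(0, species[1])
    force(j)
    reaction(st, function(x, t, p) sum(W[j, ] * x[species]) + b[j])
  })
  structure(list(
    species = species,
    input_species = species[1],
    output_species = species[L],
    parameters = list(),
    S = S, W = W, b = b,
    reactions = reactions),
    class = c("unimolecular_process", "crn_process"))
}

# Derivative of the process states for a given actuation u (production of the
# input species). Shared by all closed-loop builders.
process_deriv <- function(proc, x, u, t, p) {
  d <- stats::setNames(numeric(length(proc$species)), proc$species)
  for (r in proc$reactions) {
    a <- r$rate(x, t, p)
    d[names(r$stoich)] <- d[names(r$stoich)] + r$stoich * a
  }
  d[proc$input_species] <- d[proc$input_species] + u
  d
}

#' Hurwitz / Metzler verdict for a square matrix
#'
#' @param M square numeric matrix.
#' @return list with logical flags `hurwitz` (all eigenvalue real parts < 0)
#'   and `metzler` (all off-diagonal entries >= 0), plus `max_re`.
#' @export
hurwitz_metzler_check <- function(M) {
  M <- as.matrix(M)
  stopifnot(nrow(M) == ncol(M))
  max_re <- max(Re(eigen(M, only.values = TRUE)$values))
  off <- M; diag(off) <- 0
  list(hurwitz = max_re < 0, metzler = all(off >= 0), max_re = max_re)
}

#' Affine steady-state input/output map
#'
#' @param alpha steady-state gain (>= 0).
#' @param beta basal offset (>= 0): the output sustained with zero input.
#' @return object of class `affine_io_map`.
#' @export
affine_io_map <- function(alpha, beta) {
  stopifnot(alpha >= 0, beta >= 0)
  structure(list(alpha = alpha, beta = beta), class = "affine_io_map")
}

#' @export
print.affine_io_map <- function(x, ...) {
  cat("<affine_io_map> y = ", signif(x$alpha, 6), " * u + ",
      signif(x$beta, 6), "\n", sep = "")
  invisible(x)
}

#' Evaluate a steady-state map
#' @param map an [affine_io_map()] or a monotone function.
#' @param u input value(s).
#' @return steady-state output(s).
#' @export
io_eval <- function(map, u) {
  if (inherits(map, "affine_io_map")) map$alpha * u + map$beta else map(u)
}

#' Steady-state input/output map of a process
#'
#' For a stable unimolecular process, `alpha = -eL' (SW)^{-1} e1` and
#' `beta = -eL' (SW)^{-1} S b`; Metzler + Hurwitz structure guarantees both
#' are nonnegative. For the gene expression process the map is
#' `alpha = k1/(gamma1 gamma2)`, `beta = k1 Delta/(gamma1 gamma2)`.
#'
#' @param proc a `crn_process`.
#' @param Delta optional disturbance override (gene expression only).
#' @return an [affine_io_map()].
#' @export
io_map <- function(proc, Delta = NULL) {
  UseMethod("io_map")
}

#' @export
io_map.gene_expression_process <- function(proc, Delta = NULL) {
  p <- proc$parameters
  if (is.null(Delta)) Delta <- p$Delta
  affine_io_map(alpha = p$k1 / (p$gamma1 * p$gamma2),
                beta = p$k1 * Delta / (p$gamma1 * p$gamma2))
}

#' @export
io_map.unimolecular_process <- function(proc, Delta = NULL) {
  A <- proc$S %*% proc$W
  chk <- hurwitz_metzler_check(A)
  if (!chk$hurwitz) {
    stop("S %*% W is not Hurwitz (max Re eigenvalue = ", signif(chk$max_re, 4),
         "); the steady-state map is undefined")
  }
  L <- nrow(A)
  eL <- numeric(L); eL[L] <- 1
  e1 <- numeric(L); e1[1] <- 1
  alpha <- -drop(eL %*% solve(A, e1))
  beta <- -drop(eL %*% solve(A, proc$S %*% proc$b))
  affine_io_map(alpha = alpha, beta = max(beta, 0))
}

#' Supporting input for a setpoint
#'
#' The constant input whose open-loop steady-state output equals the desired
#' setpoint. Affine maps are inverted analytically; monotone callable maps by
#' bracketed root-finding (the bracket is grown by doubling until the map
#' exceeds the setpoint, up to a cap of 1e12). Strict monotonicity is
#' required so the supporting input is unique.
#'
#' @param map an [affine_io_map()] or strictly increasing function.
#' @param r desired setpoint.
#' @param U feasible-input [interval()] (default nonnegative reals).
#' @param tol relative tolerance of the root.
#' @return the supporting input value.
#' @export
supporting_input <- function(map, r, U = interval(0, Inf), tol = 1e-10) {
  if (inherits(map, "affine_io_map")) {
    if (map$alpha == 0) {
      if (r == map$beta) return(U$lo)
      stop("no supporting input: constant map cannot reach r = ", r)
    }
    u <- (r - map$beta) / map$alpha
  } else {
    stopifnot(is.function(map))
    lo <- max(U$lo, if (is.finite(U$lo)) U$lo else 0)
    f_lo <- map(lo) - r
    if (f_lo > tol * max(1, abs(r))) {
      stop("no supporting input: setpoint r = ", r, " below the map range")
    }
    hi <- max(1, lo * 2)
    while (map(hi) < r) {
      hi <- hi * 2
      if (hi > 1e12) stop("no supporting input: setpoint r = ", r,
                          " not reached below the 1e12 input cap")
    }
    # reject non-monotone maps rather than silently returning one root
    probe <- seq(lo, hi, length.out = 64L)
    if (any(diff(vapply(probe, map, numeric(1))) < 0)) {
      stop("map is not monotonically increasing on the bracketing interval")
    }
    u <- stats::uniroot(function(u) map(u) - r, c(lo, hi),
                        tol = tol * max(1, abs(r)))$root
  }
  if (!in_interval(u, U)) {
    stop("no feasible supporting input: u = ", signif(u, 6),
         " outside U = ", format(U))
  }
  u
}

#' Set of admissible setpoints
#'
#' Image of the feasible-input set under the steady-state map: the setpoints
#' for which a feasible supporting input exists. For an affine map with gain
#' `alpha` and offset `beta` over inputs `[u_lo, u_hi]` this is
#' `[alpha * u_lo + beta, alpha * u_hi + beta]`.
#'
#' @param map an [affine_io_map()] (or strictly increasing function, in which
#'   case `U` must have finite endpoints).
#' @param U feasible-input [interval()].
#' @return an [interval()] of admissible setpoints.
#' @export
admissible_setpoints <- function(map, U = interval(0, Inf)) {
  stopifnot(inherits(U, "ss_interval"), !U$empty)
  if (inherits(map, "affine_io_map")) {
    lo <- if (is.finite(U$lo)) map$alpha * U$lo + map$beta else -Inf
    hi <- if (is.finite(U$hi)) map$alpha * U$hi + map$beta else Inf
    if (map$alpha == 0) return(interval(map$beta, map$beta, TRUE, TRUE))
    interval(lo, hi, U$lo_closed, U$hi_closed)
  } else {
    stopifnot(is.function(map), is.finite(U$lo), is.finite(U$hi))
    interval(map(U$lo), map(U$hi), U$lo_closed, U$hi_closed)
  }
}

#' Set of admissible disturbances for a setpoint
#'
#' The disturbances that preserve the feasibility of the supporting input:
#' all `Delta` in `D` for which `supporting_input(family(Delta), r)` lies in
#' `U`. The disturbance family must be monotone (the supporting input is
#' monotone in `Delta`), which holds for all affine processes where the
#' disturbance enters as a basal production.
#'
#' @param family function `Delta -> affine_io_map` (or any map accepted by
#'   [supporting_input()]).
#' @param r admissible setpoint.
#' @param U feasible-input [interval()].
#' @param D feasible-disturbance [interval()].
#' @param tol bisection tolerance on the boundary location.
#' @return an [interval()] of admissible disturbances (possibly empty).
#' @export
admissible_disturbances <- function(family, r, U = interval(0, Inf),
                                    D = interval(0, Inf), tol = 1e-9) {
  stopifnot(is.function(family), inherits(U, "ss_interval"),
            inherits(D, "ss_interval"), !D$empty)
  u_of <- function(Delta) {
    m <- family(Delta)
    if (inherits(m, "affine_io_map")) {
      if (m$alpha == 0) return(if (r == m$beta) U$lo else NA_real_)
      (r - m$beta) / m$alpha
    } else {
      tryCatch(supporting_input(m, r, U = interval(-Inf, Inf)),
               error = function(e) NA_real_)
    }
  }
  feasible <- function(Delta) {
    u <- u_of(Delta)
    !is.na(u) && in_interval(u, U)
  }
  lo_cap <- if (is.finite(D$lo)) D$lo else -1e9
  hi_cap <- if (is.finite(D$hi)) D$hi else 1e9
  u_a <- u_of(lo_cap); u_b <- u_of(hi_cap)
  if (is.na(u_a) || is.na(u_b)) {
    # supporting input undefined at a cap: fall back to a grid scan
    grid <- seq(lo_cap, hi_cap, length.out = 513L)
    ok <- vapply(grid, feasible, logical(1))
    if (!any(ok)) return(empty_interval())
    lo <- grid[which(ok)[1]]; hi <- grid[rev(which(ok))[1]]
    return(interval(lo, hi))
  }
  # the supporting input is monotone in Delta: the feasible set is the
  # preimage of [U$lo, U$hi], located by bisection on each crossing
  crossing <- function(target) {
    g <- function(Delta) u_of(Delta) - target
    ga <- g(lo_cap); gb <- g(hi_cap)
    if (!is.finite(target) || ga * gb > 0) return(NULL)
    stats::uniroot(g, c(lo_cap, hi_cap), tol = tol)$root
  }
  edges <- c(lo_cap, hi_cap,
             unlist(lapply(c(U$lo, U$hi), crossing)))
  edges <- sort(edges)
  # keep the sub-intervals on which the input is feasible
  lo <- NA_real_; hi <- NA_real_
  for (i in seq_len(length(edges) - 1L)) {
    mid <- (edges[i] + edges[i + 1L]) / 2
    if (feasible(mid)) {
      if (is.na(lo)) lo <- edges[i]
      hi <- edges[i + 1L]
    }
  }
  if (is.na(lo)) return(empty_interval())
  if (lo == lo_cap) lo <- D$lo
  if (hi == hi_cap) hi <- D$hi
  interval(lo, hi,
           lo_closed = is.finite(lo) && feasible(lo),
           hi_closed = is.finite(hi) && feasible(hi))
}

#' Map an output-setpoint set through a sensing function
#'
#' Admissible input setpoints are the image of the admissible output
#' setpoints under the (strictly increasing) sensing nonlinearity.
#'
#' @param out_set [interval()] of admissible output setpoints.
#' @param hs strictly increasing sensing function.
#' @return [interval()] of admissible input setpoints.
#' @export
admissible_input_setpoints <- function(out_set, hs) {
  stopifnot(inherits(out_set, "ss_interval"), is.function(hs))
  if (out_set$empty) return(empty_interval())
  lo_ref <- if (is.finite(out_set$lo)) out_set$lo else 0
  hi_ref <- if (is.finite(out_set$hi)) out_set$hi else lo_ref + 100
  if (hi_ref > lo_ref) { # degenerate single-point sets need no probe
    probe <- seq(lo_ref, hi_ref, length.out = 64L)
    if (any(diff(vapply(probe, hs, numeric(1))) <= 0)) {
      stop("sensing function is not strictly increasing on the setpoint set")
    }
  }
  lo <- if (is.finite(out_set$lo)) hs(out_set$lo) else -Inf
  hi <- if (is.finite(out_set$hi)) hs(out_set$hi) else Inf
  interval(lo, hi, out_set$lo_closed, out_set$hi_closed)
}
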