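#' Define a single reaction
#'
#' @param stoich named numeric vector of integer stoichiometric changes, e.g.
#'   `c(Z1 = -1, Z2 = -1)` for a sequestration event. Species not named are
#'   unchanged.
#' @param rate propensity: either a function `f(x, t, p)` of the named state
#'   vector `x`, time `t` and parameter list `p`, returning a nonnegative
#'   scalar, or a character string with an R expression in the species names,
#'   parameter names and `t` (e.g. `"eta * Z1 * Z2"`).
#' @param name optional reaction label (used in error messages).
#' @return an object of class `reaction`.
#' @export
reaction <- function(stoich, rate, name = NULL) {
  stopifnot(is.numeric(stoich), !is.null(names(stoich)))
  if (any(stoich != round(stoich))) {
    stop("stoichiometry entries must be integers")
  }
  if (is.character(rate)) {
    expr <- parse(text = rate)[[1]]
    rate_str <- rate
    rate <- function(x, t, p) {
      eval(expr, envir = c(as.list(x), p, list(t = t)))
    }
    attr(rate, "source") <- rate_str
  }
  stopifnot(is.function(rate))
  structure(list(stoich = stoich, rate = rate, name = name),
            class = "reaction")
}

#' Reaction network
#'
#' The universal simulation substrate: an ordered species list, a set of
#' reactions (integer stoichiometries plus propensity functions), a parameter
#' table and optional piecewise-constant [schedule()]s that override
#' parameters over time. The same object drives both the deterministic ODEs
#' (via [simulate_ode()]) and the stochastic jump process (via
#' [simulate_ssa()]).
#'
#' @param species character vector of species names (state ordering).
#' @param reactions list of [reaction()]s.
#' @param parameters named list of numeric parameter values.
#' @param schedules named list of [schedule()]s keyed by parameter name.
#' @param signed_species character vector of species allowed to take negative
#'   values (used by reduced models whose signed coordinate is a difference of
#'   two concentrations); all other species are checked for nonnegativity.
#' @return an object of class `reaction_network` (also `crn_model`).
#' @export
reaction_network <- function(species, reactions, parameters = list(),
                             schedules = list(), signed_species = character(0)) {
  stopifnot(is.character(species), length(species) >= 1L,
            !anyDuplicated(species), is.list(reactions))
  for (r in reactions) {
    if (!inherits(r, "reaction")) stop("reactions must be built with reaction()")
    unknown <- setdiff(names(r$stoich), species)
    if (length(unknown)) {
      stop("reaction changes unknown species: ", paste(unknown, collapse = ", "))
    }
  }
  if (length(schedules)) {
    stopifnot(!is.null(names(schedules)))
    for (s in schedules) stopifnot(inherits(s, "schedule"))
  }
  structure(list(species = species, reactions = reactions,
                 parameters = parameters, schedules = schedules,
                 signed_species = signed_species),
            class = c("reaction_network", "crn_model"))
}

#' Dynamical system given directly as a vector field
#'
#' Some models (reduced controllers, classical integral loops with signed
#' integrator states) are not mass-action reaction lists; they are supplied
#' directly as ODE right-hand sides and share the simulation machinery with
#' [reaction_network()]s.
#'
#' @param species character vector of state names.
#' @param rhs function `f(t, x, p)` returning the named derivative vector.
#' @param parameters named list of parameters.
#' @param schedules named list of [schedule()]s.
#' @param signed_species states allowed to be negative (default: all of them,
#'   since generic ODE states carry no positivity constraint).
#' @return an object of class `ode_system` (also `crn_model`).
#' @export
ode_system <- function(species, rhs, parameters = list(), schedules = list(),
                       signed_species = species) {
  stopifnot(is.character(species), is.function(rhs))
  structure(list(species = species, rhs = rhs, parameters = parameters,
                 schedules = schedules, signed_species = signed_species),
            class = c("ode_system", "crn_model"))
}

# Parameters with schedule overrides applied at time t
params_at <- function(model, t) {
  p <- model$parameters
  for (nm in names(model$schedules)) {
    p[[nm]] <- schedule_value(model$schedules[[nm]], t)
  }
  p
}

#' Evaluate all propensities of a reaction network
#'
#' @param network a [reaction_network()].
#' @param x named (or ordered) nonnegative state vector.
#' @param t time at which schedules are evaluated.
#' @return numeric vector of reaction rates.
#' @export
propensities <- function(network, x, t = 0) {
  stopifnot(inherits(network, "reaction_network"))
  x <- named_state(network, x)
  p <- params_at(network, t)
  vapply(network$reactions, function(r) {
    a <- r$rate(x, t, p)
    if (!is.finite(a)) {
      stop("non-finite propensity", if (!is.null(r$name)) paste0(" in '", r$name, "'"),
           " at t=", signif(t, 6))
    }
    a
  }, numeric(1))
}

named_state <- function(model, x) {
  if (is.null(names(x))) {
    stopifnot(length(x) == length(model$species))
    names(x) <- model$species
  }
  x[model$species]
}

# Stoichiometry matrix (species x reactions)
stoich_matrix <- function(network) {
  S <- matrix(0, nrow = length(network$species),
              ncol = length(network$reactions),
              dimnames = list(network$species, NULL))
  for (j in seq_along(network$reactions)) {
    st <- network$reactions[[j]]$stoich
    S[names(st), j] <- st
  }
  S
}

# Deterministic vector field of any crn_model, as f(t, x_named) -> named vector
model_rhs <- function(model) {
  if (inherits(model, "ode_system")) {
    function(t, x) {
      d <- model$rhs(t, named_state(model, x), params_at(model, t))
      stats::setNames(as.numeric(d), model$species)
    }
  } else {
    S <- stoich_matrix(model)
    function(t, x) {
      x <- named_state(model, x)
      p <- params_at(model, t)
      a <- vapply(model$reactions, function(r) r$rate(x, t, p), numeric(1))
      if (any(a < -1e-12)) {
        j <- which.min(a)
        stop("negative propensity (", signif(a[j], 4), ") in reaction ", j,
             " at t=", signif(t, 6))
      }
      drop(S %*% pmax(a, 0))
    }
  }
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", length(x$species), " species, ",
      length(x$reactions), " reactions\n", sep = "")
  cat("species:", paste(x$species, collapse = ", "), "\n")
  if (length(x$schedules)) {
    cat("scheduled parameters:", paste(names(x$schedules), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.ode_system <- function(x, ...) {
  cat("<ode_system> states:", paste(x$species, collapse = ", "), "\n")
  invisible(x)
}
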