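#' Read a reaction-network config
#'
#' Loads a YAML (or JSON) description of a network and simulation settings.
#' Schema (all rates are R expressions in the species names, parameter names
#' and `t`):
#'
#' ```yaml
#' species: [X1, X2, Z1, Z2]
#' signed_species: []          # optional
#' parameters: {k1: 1, gamma1: 1, gamma2: 1, Delta: 0,
#'              mu: 10, theta: 1, eta: 100, k: 1}
#' reactions:
#'   - {stoich: {X1: 1},  rate: "Delta + k * Z1"}
#'   - {stoich: {X1: -1}, rate: "gamma1 * X1"}
#'   - {stoich: {X2: 1},  rate: "k1 * X1"}
#'   - {stoich: {X2: -1}, rate: "gamma2 * X2"}
#'   - {stoich: {Z1: 1},  rate: "mu"}
#'   - {stoich: {Z2: 1},  rate: "theta * X2"}
#'   - {stoich: {Z1: -1, Z2: -1}, rate: "eta * Z1 * Z2"}
#' schedules:
#'   Delta: {breakpoints: [0, 60, 120], values: [0, 5, 12]}
#' simulation:
#'   t_max: 300
#'   x0: {X1: 0, X2: 0, Z1: 0, Z2: 0}   # optional, default all zero
#'   rtol: 1.0e-8
#'   atol: 1.0e-10
#'   n_out: 1001
#'   seed: 1                            # used by the SSA only
#' ```
#'
#' @param path file path (`.yaml`/`.yml`/`.json`).
#' @return list with `network` (a [reaction_network()]) and `simulation`
#'   (list of settings, possibly empty).
#' @export
read_network_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- tryCatch(
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    },
    error = function(e) stop("cannot parse config '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  for (key in c("species", "reactions")) {
    if (is.null(cfg[[key]])) stop("config '", path, "': missing key '", key, "'")
  }
  reactions <- lapply(seq_along(cfg$reactions), function(i) {
    r <- cfg$reactions[[i]]
    if (is.null(r$stoich) || is.null(r$rate)) {
      stop("config '", path, "': reaction ", i, " needs 'stoich' and 'rate'")
    }
    reaction(unlist(r$stoich), r$rate, name = r$name %||% paste0("r", i))
  })
  schedules <- lapply(cfg$schedules %||% list(), function(s) {
    schedule(unlist(s$breakpoints), unlist(s$values))
  })
  net <- reaction_network(
    species = unlist(cfg$species),
    reactions = reactions,
    parameters = as.list(cfg$parameters %||% list()),
    schedules = schedules,
    signed_species = unlist(cfg$signed_species %||% character(0)))
  list(network = net, simulation = cfg$simulation %||% list())
}

#' Write a trajectory as CSV plus JSON metadata sidecar
#'
#' @param traj a trajectory.
#' @param prefix output path prefix; writes `<prefix>.csv` (columns `time`,
#'   one per species) and `<prefix>.json` (solver metadata).
#' @return invisibly, the CSV path.
#' @export
write_trajectory <- function(traj, prefix) {
  stopifnot(inherits(traj, "trajectory"))
  csv <- paste0(prefix, ".csv")
  utils::write.csv(as.data.frame(traj), csv, row.names = FALSE)
  meta <- c(traj$meta, list(n_times = length(traj$times),
                            t_max = max(traj$times),
                            species = colnames(traj$states)))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(csv)
}

#' Read an admissibility config
#'
#' Schema:
#' ```yaml
#' process: {type: gene_expression, k1: 1, gamma1: 1, gamma2: 1, Delta: 5}
#' inputs: {lo: 0, hi: 8}          # feasible-input interval U
#' disturbances: {lo: 0, hi: .inf} # feasible-disturbance interval D
#' setpoint: 10
#' sensing: {type: hill, kappa: 5, theta: 15}  # optional
#' ```
#' @param path file path.
#' @return list with `process`, `U`, `D`, `setpoint`, `hs` (or NULL),
#'   `theta` (or NULL).
#' @keywords internal
read_admissibility_config <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("cannot parse config '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  pc <- cfg$process
  if (is.null(pc) || is.null(pc$type)) stop("config needs process: {type: ...}")
  proc <- switch(pc$type,
    gene_expression = gene_expression_process(
      k1 = pc$k1 %||% 1, gamma1 = pc$gamma1 %||% 1,
      gamma2 = pc$gamma2 %||% 1, Delta = pc$Delta %||% 0),
    stop("unknown process type: ", pc$type))
  as_iv <- function(x, default) {
    if (is.null(x)) default
    else interval(x$lo %||% 0, x$hi %||% Inf)
  }
  hs <- NULL; theta <- NULL
  if (!is.null(cfg$sensing)) {
    stopifnot(cfg$sensing$type %in% c("hill", "identity"))
    hs <- if (cfg$sensing$type == "hill") {
      hill_activation(cfg$sensing$kappa)
    } else function(y) y
    theta <- cfg$sensing$theta %||% 1
  }
  list(process = proc, U = as_iv(cfg$inputs, interval(0, Inf)),
       D = as_iv(cfg$disturbances, interval(0, Inf)),
       setpoint = cfg$setpoint, hs = hs, theta = theta)
}

#' Read a fast-sequestration spec config (for the reduce command)
#'
#' Schema (rates are expressions in `x` species names, `z1`, `z2`,
#' parameters and `t`):
#' ```yaml
#' x_species: [X]            # may be empty
#' x0: {X: 0}
#' a: 0
#' b: 0
#' eta: 100
#' parameters: {mu: 10, theta: 1, k: 1, gamma: 1}
#' F: {X: "k * z1 - gamma * X"}
#' W1: "mu"
#' W2: "theta * X"
#' ```
#' @param path file path.
#' @return a [fast_seq_spec()].
#' @keywords internal
read_fast_seq_config <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("cannot parse config '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  for (key in c("eta", "W1", "W2")) {
    if (is.null(cfg[[key]])) stop("config '", path, "': missing key '", key, "'")
  }
  xs <- unlist(cfg$x_species %||% character(0))
  pars <- as.list(cfg$parameters %||% list())
  mk_scalar <- function(src) {
    expr <- parse(text = src)[[1]]
    function(x, z1, z2, t, p) {
      eval(expr, envir = c(as.list(x), p, list(z1 = z1, z2 = z2, t = t)))
    }
  }
  Ffun <- NULL
  if (length(xs)) {
    exprs <- lapply(xs, function(nm) {
      src <- cfg$F[[nm]]
      if (is.null(src)) stop("config '", path, "': F missing for species ", nm)
      parse(text = src)[[1]]
    })
    Ffun <- function(x, z1, z2, t, p) {
      env <- c(as.list(x), p, list(z1 = z1, z2 = z2, t = t))
      vapply(exprs, eval, numeric(1), envir = env)
    }
  }
  x0 <- stats::setNames(numeric(length(xs)), xs)
  if (!is.null(cfg$x0)) x0[names(cfg$x0)] <- unlist(cfg$x0)
  fast_seq_spec(F = Ffun, W1 = mk_scalar(cfg$W1), W2 = mk_scalar(cfg$W2),
                eta = cfg$eta, x0 = x0, a = cfg$a %||% 0, b = cfg$b %||% 0,
                x_names = xs, parameters = pars)
}
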