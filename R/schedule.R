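#' Piecewise-constant parameter schedule
#'
#' A schedule binds a time-varying value to a model parameter, typically a
#' disturbance that is stepped between plateaus. Evaluation is
#' right-continuous: on each half-open interval `[breakpoints[i],
#' breakpoints[i+1])` the schedule takes `values[i]`; before the first
#' breakpoint it takes `values[1]` as well (i.e. `breakpoints[1]` is the start
#' of the first plateau and is usually the simulation start).
#'
#' @param breakpoints strictly increasing numeric vector of switch times; the
#'   first entry marks the start of the first plateau.
#' @param values numeric vector, one value per breakpoint.
#' @return an object of class `schedule`.
#' @examples
#' s <- schedule(c(0, 50, 100), c(0, 5, 12))
#' schedule_value(s, 49.9) # 0
#' schedule_value(s, 50)   # 5 (right-continuous)
#' @export
schedule <- function(breakpoints, values) {
  stopifnot(is.numeric(breakpoints), is.numeric(values),
            length(breakpoints) == length(values),
            length(breakpoints) >= 1L)
  if (any(diff(breakpoints) <= 0)) {
    stop("schedule breakpoints must be strictly increasing")
  }
  structure(list(breakpoints = as.numeric(breakpoints),
                 values = as.numeric(values)),
            class = "schedule")
}

#' Evaluate a schedule at time t
#'
#' @param s a [schedule()].
#' @param t numeric vector of times.
#' @return numeric vector of schedule values, right-continuous in `t`.
#' @export
schedule_value <- function(s, t) {
  stopifnot(inherits(s, "schedule"))
  idx <- findInterval(t, s$breakpoints, left.open = FALSE)
  idx[idx < 1L] <- 1L
  s$values[idx]
}

#' @export
print.schedule <- function(x, ...) {
  cat("<schedule>", length(x$breakpoints), "plateaus\n")
  print(data.frame(from = x$breakpoints, value = x$values))
  invisible(x)
}

# Breakpoints of all schedules attached to a model, restricted to a horizon.
# The ODE solver is restarted at each of these to avoid stepping over a
# discontinuity.
schedule_breaks <- function(schedules, t0, t1) {
  if (length(schedules) == 0) return(numeric(0))
  b <- sort(unique(unlist(lapply(schedules, function(s) s$breakpoints))))
  b[b > t0 & b < t1]
}

# Time beyond which all schedules are constant
schedule_settle_time <- function(schedules) {
  if (length(schedules) == 0) return(-Inf)
  max(vapply(schedules, function(s) max(s$breakpoints), numeric(1)))
}
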