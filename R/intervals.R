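#' Intervals of the extended real line
#'
#' Admissibility sets (setpoints, disturbances, input setpoints) are
#' intervals, possibly unbounded. Finite endpoints attained by a feasible
#' input are closed by default; infinite endpoints are always open.
#'
#' @param lo,hi endpoints (`-Inf`/`Inf` allowed).
#' @param lo_closed,hi_closed endpoint closure flags (forced open at infinite
#'   endpoints).
#' @return object of class `ss_interval`.
#' @export
interval <- function(lo, hi, lo_closed = is.finite(lo), hi_closed = is.finite(hi)) {
  if (lo > hi) stop("interval endpoints out of order: lo > hi")
  if (!is.finite(lo)) lo_closed <- FALSE
  if (!is.finite(hi)) hi_closed <- FALSE
  structure(list(lo = lo, hi = hi, lo_closed = lo_closed,
                 hi_closed = hi_closed, empty = FALSE),
            class = "ss_interval")
}

#' The empty interval
#' @return an empty `ss_interval`.
#' @export
empty_interval <- function() {
  structure(list(lo = NA_real_, hi = NA_real_, lo_closed = FALSE,
                 hi_closed = FALSE, empty = TRUE),
            class = "ss_interval")
}

#' Membership test for an interval
#' @param x numeric vector.
#' @param I an [interval()].
#' @return logical vector.
#' @export
in_interval <- function(x, I) {
  stopifnot(inherits(I, "ss_interval"))
  if (I$empty) return(rep(FALSE, length(x)))
  lo_ok <- if (I$lo_closed) x >= I$lo else x > I$lo
  hi_ok <- if (I$hi_closed) x <= I$hi else x < I$hi
  lo_ok & hi_ok
}

#' Intersection of two intervals
#' @param a,b [interval()]s.
#' @return an `ss_interval` (possibly empty).
#' @export
interval_intersect <- function(a, b) {
  stopifnot(inherits(a, "ss_interval"), inherits(b, "ss_interval"))
  if (a$empty || b$empty) return(empty_interval())
  lo <- max(a$lo, b$lo); hi <- min(a$hi, b$hi)
  if (lo > hi) return(empty_interval())
  lo_closed <- (if (a$lo == lo) a$lo_closed else TRUE) &&
               (if (b$lo == lo) b$lo_closed else TRUE)
  hi_closed <- (if (a$hi == hi) a$hi_closed else TRUE) &&
               (if (b$hi == hi) b$hi_closed else TRUE)
  if (lo == hi && !(lo_closed && hi_closed)) return(empty_interval())
  interval(lo, hi, lo_closed, hi_closed)
}

#' @export
print.ss_interval <- function(x, ...) {
  if (x$empty) {
    cat("<interval> (empty)\n")
  } else {
    cat("<interval> ", if (x$lo_closed) "[" else "(", x$lo, ", ", x$hi,
        if (x$hi_closed) "]" else ")", "\n", sep = "")
  }
  invisible(x)
}

#' @export
format.ss_interval <- function(x, ...) {
  if (x$empty) return("(empty)")
  paste0(if (x$lo_closed) "[" else "(", x$lo, ", ", x$hi,
         if (x$hi_closed) "]" else ")")
}
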