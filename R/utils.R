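#' Wrap values onto a periodic interval
#'
#' Maps `x` onto `[lo, lo + L)` by subtracting integer multiples of the wrap
#' length `L`.  Used everywhere a stimulus leaves its feasible range: the
#' population codes tile their space periodically, so an angle of
#' `lo + L + eps` is encoded identically to `lo + eps`.
#'
#' @param x numeric vector.
#' @param lo lower edge of the interval.
#' @param L period (interval length), `L > 0`.
#' @return numeric vector in `[lo, lo + L)`.
#' @export
wrap_to_range <- function(x, lo, L) {
  stopifnot(is.finite(L), L > 0)
  lo + ((x - lo) %% L)
}

#' Wrapped (circular) difference
#'
#' Signed difference between two points on a circle of circumference `L`,
#' mapped to `(-L/2, L/2]`.  This is the error measure used for all angle
#' and torque statistics: an estimate one full period away from the truth is
#' a zero error.
#'
#' @param d raw difference (or vector of differences).
#' @param L period.
#' @return wrapped differences in `(-L/2, L/2]`.
#' @export
wrap_diff <- function(d, L) {
  e <- ((d + L / 2) %% L) - L / 2
  e[e == -L / 2] <- L / 2
  e
}

# Derived per-trajectory seed: trajectory i of an experiment with root seed s
# always uses the same stream, regardless of how many trajectories are drawn,
# so enlarging n_traj never reshuffles earlier trajectories.
traj_seed <- function(root, i) {
  as.integer((as.numeric(root) * 48271 + i) %% 2147483646) + 1L
}

logistic <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
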