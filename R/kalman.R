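#' Scalar Kalman smoother state
#'
#' State of the simple one-dimensional Kalman filter used to clean barometric
#' altitude and CO traces. The filter has no dynamics model: each step blends
#' the running estimate with the new measurement by the gain
#' `K = p / (p + r)`, and inflates the uncertainty by a term proportional to
#' how much the estimate just moved (`|x - x'| * q`), a signal-dependent
#' process noise that lets the filter re-open when the signal genuinely moves.
#'
#' @param x Current state estimate (same unit as the measurements).
#' @param p Current estimation uncertainty (unit^2), `>= 0`.
#' @param r Measurement uncertainty (unit^2), `> 0`.
#' @param q Process-noise scale (dimensionless), `>= 0`.
#' @return A `kalman_state` object.
#' @export
kalman_state <- function(x = 0, p = 1, r = 1, q = 0.01) {
  if (!is.finite(p) || p < 0) stop("`p` must be >= 0", call. = FALSE)
  if (!is.finite(r) || r <= 0) stop("`r` must be > 0", call. = FALSE)
  if (!is.finite(q) || q < 0) stop("`q` must be >= 0", call. = FALSE)
  structure(list(x = as.numeric(x), p = as.numeric(p),
                 r = as.numeric(r), q = as.numeric(q)),
            class = "kalman_state")
}

#' @export
print.kalman_state <- function(x, ...) {
  cat(sprintf("<kalman_state> x = %.4g, p = %.4g, r = %.4g, q = %.4g (K = %.4g)\n",
              x$x, x$p, x$r, x$q, x$p / (x$p + x$r)))
  invisible(x)
}

#' One scalar Kalman update
#'
#' Computes `K = p/(p+r)`, `x' = x*(1-K) + K*z`,
#' `p' = (1-K)*p + |x - x'| * q`. The gain lies in `[0, 1)`, so the updated
#' estimate is always a convex combination of the previous estimate and the
#' measurement.
#'
#' @param state A `kalman_state`.
#' @param z Measurement.
#' @return The updated `kalman_state`.
#' @examples
#' s <- kalman_state(x = 0, p = 1, r = 1)
#' kalman_step(s, 2)$x # gain 0.5 -> estimate 1
#' @export
kalman_step <- function(state, z) {
  stopifnot(inherits(state, "kalman_state"))
  k <- state$p / (state$p + state$r)
  x_new <- state$x + k * (z - state$x)   # == x*(1-K) + K*z, exact when z == x
  p_new <- (1 - k) * state$p + abs(state$x - x_new) * state$q
  state$x <- x_new
  state$p <- p_new
  state
}

#' Smooth a measurement trace with the scalar Kalman filter
#'
#' Sequentially applies [kalman_step()] along `z`. Unless an explicit `init`
#' state is given, the filter is seeded with `x = z[1]` so a constant trace is
#' reproduced bit-exactly.
#'
#' @param z Numeric measurement vector (non-empty).
#' @param init Optional initial `kalman_state`; its `x` seeds the estimate.
#' @param r,q,p_init Filter parameters used when `init` is `NULL`.
#' @return Numeric vector of filtered values, same length as `z`.
#' @export
kalman_smooth <- function(z, init = NULL, r = 1, q = 0.01, p_init = 1) {
  if (length(z) < 1L) stop("`z` must be non-empty", call. = FALSE)
  st <- init %||% kalman_state(x = z[1], p = p_init, r = r, q = q)
  stopifnot(inherits(st, "kalman_state"))
  n <- length(z)
  out <- numeric(n)
  x <- st$x; p <- st$p; rr <- st$r; qq <- st$q
  for (i in seq_len(n)) {
    k <- p / (p + rr)
    x_new <- x + k * (z[i] - x)
    p <- (1 - k) * p + abs(x - x_new) * qq
    x <- x_new
    out[i] <- x
  }
  out
}
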