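#' Convert barometric pressure to altitude
#'
#' Barometric formula `H = 44330 * (1 - (P/P0)^(1/5.225))`, metres above the
#' reference pressure level. The exponent denominator defaults to 5.225 (the
#' device's calibration); the common standard-atmosphere value 5.255 can be
#' configured and differs by millimetres over indoor ranges.
#'
#' @param pressure Pressure in hPa (strictly positive; vectorised).
#' @param p0 Reference sea-level pressure in hPa (default 1013.25).
#' @param exponent_denominator Denominator D of the exponent 1/D.
#' @return Altitude(s) in metres.
#' @examples
#' pressure_to_altitude(1013.25)              # 0 at the reference
#' abs(pressure_to_altitude(890.0651) -
#'     pressure_to_altitude(890.0402))        # ~0.23 m floor-height change
#' @export
pressure_to_altitude <- function(pressure, p0 = 1013.25,
                                 exponent_denominator = 5.225) {
  if (any(!is.finite(pressure)) || any(pressure <= 0))
    stop("`pressure` must be strictly positive (hPa)", call. = FALSE)
  check_positive_scalar(p0, "p0")
  check_positive_scalar(exponent_denominator, "exponent_denominator")
  44330 * (1 - (pressure / p0)^(1 / exponent_denominator))
}

#' Inverse barometric formula
#'
#' Pressure at a given altitude; exact inverse of [pressure_to_altitude()].
#' Used by the scenario simulator to synthesise pressure channels.
#'
#' @param altitude Altitude in metres (vectorised, `< 44330`).
#' @inheritParams pressure_to_altitude
#' @return Pressure(s) in hPa.
#' @export
altitude_to_pressure <- function(altitude, p0 = 1013.25,
                                 exponent_denominator = 5.225) {
  if (any(altitude >= 44330))
    stop("`altitude` must be below 44330 m", call. = FALSE)
  p0 * (1 - altitude / 44330)^exponent_denominator
}

#' Altitude trace from a barometric channel
#'
#' Converts a frame's pressure channel to altitude and smooths it with the
#' scalar Kalman filter (seeded at the first raw altitude).
#'
#' @param frame A `sensor_frame` with a pressure channel, or a numeric vector
#'   of pressures in hPa (then `fs` must be given).
#' @param p0 Reference pressure, hPa.
#' @param exponent_denominator See [pressure_to_altitude()].
#' @param kalman_r,kalman_q,kalman_p_init Scalar Kalman parameters (m^2,
#'   dimensionless, m^2).
#' @param fs Sampling rate, only needed when `frame` is a bare vector.
#' @return An `altitude_trace`: list with `h_raw`, `h_filtered` (m), `p0`, `fs`.
#' @export
altitude_trace <- function(frame, p0 = 1013.25, exponent_denominator = 5.225,
                           kalman_r = 1, kalman_q = 0.01, kalman_p_init = 1,
                           fs = NULL) {
  if (inherits(frame, "sensor_frame")) {
    if (is.null(frame$pressure))
      stop("frame has no pressure channel", call. = FALSE)
    pressure <- frame$pressure
    fs <- frame$fs
  } else {
    pressure <- frame
    if (is.null(fs)) stop("`fs` is required with a bare pressure vector",
                          call. = FALSE)
  }
  if (length(pressure) < 1L) stop("empty pressure trace", call. = FALSE)
  h_raw <- pressure_to_altitude(pressure, p0, exponent_denominator)
  h_f <- kalman_smooth(h_raw, r = kalman_r, q = kalman_q, p_init = kalman_p_init)
  structure(list(h_raw = h_raw, h_filtered = h_f, p0 = p0, fs = fs),
            class = "altitude_trace")
}

#' Re-smooth an altitude trace
#'
#' Recomputes `h_filtered` from `h_raw` with a caller-supplied initial Kalman
#' state (seeded at the first raw altitude when `init` is `NULL`).
#'
#' @param trace An `altitude_trace`.
#' @param init Optional initial `kalman_state`.
#' @return The trace with `h_filtered` replaced.
#' @export
smooth_altitude <- function(trace, init = NULL) {
  stopifnot(inherits(trace, "altitude_trace"))
  if (length(trace$h_raw) < 1L) stop("empty altitude trace", call. = FALSE)
  trace$h_filtered <- kalman_smooth(trace$h_raw, init = init)
  trace
}

#' @export
print.altitude_trace <- function(x, ...) {
  cat(sprintf("<altitude_trace> %d samples @ %g Hz, filtered range [%.2f, %.2f] m (p0 = %g hPa)\n",
              length(x$h_raw), x$fs, min(x$h_filtered), max(x$h_filtered), x$p0))
  invisible(x)
}
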