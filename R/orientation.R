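# Quaternions are numeric length-4, scalar-first: c(w, x, y, z).
# Convention: q rotates the sensor frame into the earth frame; the gravity
# direction seen by the sensor is then the third column of R(q)^T,
#   u(q) = c(2(xz - wy), 2(yz + wx), w^2 - x^2 - y^2 + z^2),
# which equals c(0, 0, 1) for the identity (device upright, az = +1 g).

q_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

q_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

q_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n == 0) stop("cannot normalise a zero quaternion", call. = FALSE)
  q / n
}

q_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n == 0) return(c(1, 0, 0, 0))
  c(cos(angle / 2), sin(angle / 2) * axis / n)
}

# gravity direction in the sensor frame predicted by q
q_gravity <- function(q) {
  c(2 * (q[2] * q[4] - q[1] * q[3]),
    2 * (q[3] * q[4] + q[1] * q[2]),
    q[1]^2 - q[2]^2 - q[3]^2 + q[4]^2)
}

# spherical linear interpolation between unit quaternions, f in [0, 1]
q_slerp <- function(qa, qb, f) {
  d <- sum(qa * qb)
  if (d < 0) { qb <- -qb; d <- -d }
  if (d > 1 - 1e-10) return(q_normalize(qa + f * (qb - qa)))
  th <- acos(min(1, d))
  (sin((1 - f) * th) * qa + sin(f * th) * qb) / sin(th)
}

#' Tilt angle of the device's vertical axis from gravity
#'
#' `theta = acos(az / ||a||)` in degrees: 0 when the device is upright
#' (az parallel to gravity), 90 when horizontal. Scale-invariant, so raw
#' accelerometer readings can be used in any unit.
#'
#' @param ax,ay,az Acceleration components (vectorised, equal length).
#' @return Tilt angle(s) in degrees, in `[0, 180]`.
#' @examples
#' theta_angle(0, 0, 1) # 0: upright
#' theta_angle(1, 0, 0) # 90: lying horizontal
#' @export
theta_angle <- function(ax, ay, az) {
  mag <- sqrt(ax^2 + ay^2 + az^2)
  if (any(mag == 0))
    stop("orientation undefined for a zero acceleration vector", call. = FALSE)
  acos(pmin(1, pmax(-1, az / mag))) * 180 / pi
}

#' One Madgwick orientation filter update
#'
#' Gradient-descent fusion of gyroscope integration with an accelerometer
#' (and optionally magnetometer) correction. With `mag` supplied the MARG
#' variant is used; otherwise the IMU variant. A zero accelerometer vector
#' skips the corrective term for that step. With `beta = 0` the update reduces
#' to pure gyroscope quaternion integration.
#'
#' @param q Unit quaternion, scalar-first `c(w, x, y, z)`.
#' @param gyro Angular rate `c(gx, gy, gz)` in rad/s.
#' @param acc Acceleration `c(ax, ay, az)`, any unit (normalised internally).
#' @param mag Optional magnetic field `c(mx, my, mz)`, any consistent unit.
#' @param dt Time step in seconds (`> 0`).
#' @param beta Filter gain (default 0.1).
#' @return The updated unit quaternion.
#' @export
madgwick_update <- function(q, gyro, acc, mag = NULL, dt, beta = 0.1) {
  stopifnot(length(q) == 4L, length(gyro) == 3L, length(acc) == 3L)
  check_positive_scalar(dt, "dt")
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  # gyro term: qdot = 0.5 * q * (0, omega)
  qdot <- 0.5 * q_multiply(q, c(0, gyro))
  an <- sqrt(sum(acc^2))
  if (an > 0 && beta > 0) {
    a <- acc / an
    # gravity objective and its Jacobian-transpose product
    f1 <- 2 * (x * z - w * y) - a[1]
    f2 <- 2 * (w * x + y * z) - a[2]
    f3 <- 2 * (0.5 - x^2 - y^2) - a[3]
    s <- c(-2 * y * f1 + 2 * x * f2,
            2 * z * f1 + 2 * w * f2 - 4 * x * f3,
           -2 * w * f1 + 2 * z * f2 - 4 * y * f3,
            2 * x * f1 + 2 * y * f2)
    mn <- if (is.null(mag)) 0 else sqrt(sum(mag^2))
    if (mn > 0) {
      m <- mag / mn
      # earth-frame field from the current estimate; reference b = (bx, 0, bz)
      h1 <- (w^2 + x^2 - y^2 - z^2) * m[1] + 2 * (x * y - w * z) * m[2] +
        2 * (x * z + w * y) * m[3]
      h2 <- 2 * (x * y + w * z) * m[1] + (w^2 - x^2 + y^2 - z^2) * m[2] +
        2 * (y * z - w * x) * m[3]
      h3 <- 2 * (x * z - w * y) * m[1] + 2 * (y * z + w * x) * m[2] +
        (w^2 - x^2 - y^2 + z^2) * m[3]
      bx <- sqrt(h1^2 + h2^2); bz <- h3
      # field objective: rotate b back into the sensor frame, compare to m
      g1 <- (w^2 + x^2 - y^2 - z^2) * bx + 2 * (x * z - w * y) * bz - m[1]
      g2 <- 2 * (x * y - w * z) * bx + 2 * (y * z + w * x) * bz - m[2]
      g3 <- 2 * (x * z + w * y) * bx + (w^2 - x^2 - y^2 + z^2) * bz - m[3]
      # columns of dM/dq_k %*% c(bx, 0, bz)
      s <- s + 2 * c(
        ( w * bx - y * bz) * g1 + (-z * bx + x * bz) * g2 + ( y * bx + w * bz) * g3,
        ( x * bx + z * bz) * g1 + ( y * bx + w * bz) * g2 + ( z * bx - x * bz) * g3,
        (-y * bx - w * bz) * g1 + ( x * bx + z * bz) * g2 + ( w * bx - y * bz) * g3,
        (-z * bx + x * bz) * g1 + (-w * bx + y * bz) * g2 + ( x * bx + z * bz) * g3)
    }
    sn <- sqrt(sum(s^2))
    if (sn > 0) qdot <- qdot - beta * s / sn
  }
  q_normalize(q + qdot * dt)
}

# quaternion aligning the predicted gravity direction with a measured
# acceleration direction; used to warm-start the filter
q_from_accel <- function(acc) {
  an <- sqrt(sum(acc^2))
  if (an == 0) return(c(1, 0, 0, 0))
  a <- acc / an
  axis <- c(a[2], -a[1], 0)            # a x e_z
  ang <- acos(min(1, max(-1, a[3])))
  if (sqrt(sum(axis^2)) < 1e-12) {
    if (a[3] > 0) return(c(1, 0, 0, 0)) else return(c(0, 1, 0, 0))
  }
  q_axis_angle(axis, ang)
}

#' Run the Madgwick filter along a sensor frame
#'
#' @param frame A `sensor_frame` with gyroscope channels.
#' @param beta Filter gain.
#' @param q0 Initial quaternion; default warm-starts from the accelerometer
#'   tilt of the first sample.
#' @param use_mag Use the magnetometer (MARG variant) when present. Default
#'   `FALSE`: the posture decision only needs pitch and roll, which the IMU
#'   variant supplies, and magnetic field readings inside steel-framed
#'   buildings are unreliable.
#' @return An n x 4 matrix of unit quaternions (scalar-first rows).
#' @export
madgwick_filter <- function(frame, beta = 0.1, q0 = NULL, use_mag = FALSE) {
  validate_sensor_frame(frame)
  if (is.null(frame$gx))
    stop("frame has no gyroscope channels", call. = FALSE)
  n <- length(frame$ax)
  dt <- 1 / frame$fs
  q <- q0 %||% q_from_accel(c(frame$ax[1], frame$ay[1], frame$az[1]))
  q <- q_normalize(q)
  out <- matrix(NA_real_, n, 4L)
  has_mag <- use_mag && !is.null(frame$mx)
  for (i in seq_len(n)) {
    mag <- if (has_mag) c(frame$mx[i], frame$my[i], frame$mz[i]) else NULL
    q <- madgwick_update(q, c(frame$gx[i], frame$gy[i], frame$gz[i]),
                         c(frame$ax[i], frame$ay[i], frame$az[i]),
                         mag = mag, dt = dt, beta = beta)
    out[i, ] <- q
  }
  colnames(out) <- c("w", "x", "y", "z")
  out
}

#' Euler angles from a quaternion
#'
#' Yaw/pitch/roll in degrees under the device's convention:
#' `Y = atan2(2 q2 q3 - 2 q1 q4, 2 q1^2 + 2 q2^2 - 1)`,
#' `P = -asin(2 q2 q4 + 2 q1 q3)`,
#' `R = atan2(2 q3 q4 - 2 q1 q2, 2 q1^2 + 2 q4^2 - 1)`
#' with scalar-first components `q1..q4`. [quaternion_from_euler()] is the
#' exact inverse under the same convention. Near gimbal lock the asin argument
#' is clamped with a warning.
#'
#' @param q Unit quaternion (length 4) or an n x 4 matrix of them.
#' @return Named vector `c(yaw, pitch, roll)` in degrees, or a data.frame for
#'   matrix input.
#' @export
euler_from_quaternion <- function(q) {
  if (is.matrix(q)) {
    w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  } else {
    stopifnot(length(q) == 4L)
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  }
  sp <- 2 * x * z + 2 * w * y
  if (any(abs(sp) > 1 - 1e-9)) {
    warning("pitch at gimbal proximity; asin argument clamped", call. = FALSE)
    sp <- pmin(1, pmax(-1, sp))
  }
  yaw <- atan2(2 * x * y - 2 * w * z, 2 * w^2 + 2 * x^2 - 1) * 180 / pi
  pitch <- -asin(sp) * 180 / pi
  roll <- atan2(2 * y * z - 2 * w * x, 2 * w^2 + 2 * z^2 - 1) * 180 / pi
  if (is.matrix(q)) data.frame(yaw = yaw, pitch = pitch, roll = roll)
  else c(yaw = yaw, pitch = pitch, roll = roll)
}

#' Quaternion from Euler angles
#'
#' Inverse of [euler_from_quaternion()] under the same convention (the
#' conjugate of the standard yaw-pitch-roll composition).
#'
#' @param yaw,pitch,roll Angles in degrees.
#' @return A unit quaternion, scalar-first.
#' @export
quaternion_from_euler <- function(yaw, pitch, roll) {
  y <- unname(yaw) * pi / 180
  p <- unname(pitch) * pi / 180
  r <- unname(roll) * pi / 180
  qz <- c(cos(y / 2), 0, 0, sin(y / 2))
  qy <- c(cos(p / 2), 0, sin(p / 2), 0)
  qx <- c(cos(r / 2), sin(r / 2), 0, 0)
  q_conjugate(q_multiply(q_multiply(qz, qy), qx))
}

#' Per-sample posture angles for a sensor frame
#'
#' Computes the tilt angle theta from the accelerometer and pitch/roll (and
#' yaw, unused by the decision) from the Madgwick filter.
#'
#' @param frame A `sensor_frame` with gyroscope channels.
#' @param beta Madgwick gain.
#' @param theta_from `"raw"` (default): theta from the raw accelerometer
#'   components; `"filtered"`: from the filter's predicted gravity direction.
#' @param use_mag See [madgwick_filter()].
#' @param q0 Optional initial quaternion.
#' @return A `posture_trace`: data.frame with columns `theta`, `pitch`,
#'   `roll`, `yaw` (degrees) and attribute `fs`.
#' @export
estimate_posture <- function(frame, beta = 0.1,
                             theta_from = c("raw", "filtered"),
                             use_mag = FALSE, q0 = NULL) {
  theta_from <- match.arg(theta_from)
  qs <- madgwick_filter(frame, beta = beta, q0 = q0, use_mag = use_mag)
  eul <- euler_from_quaternion(qs)
  theta <- if (theta_from == "raw") {
    theta_angle(frame$ax, frame$ay, frame$az)
  } else {
    gz <- qs[, 1]^2 - qs[, 2]^2 - qs[, 3]^2 + qs[, 4]^2
    acos(pmin(1, pmax(-1, gz))) * 180 / pi
  }
  out <- data.frame(theta = theta, pitch = eul$pitch, roll = eul$roll,
                    yaw = eul$yaw)
  attr(out, "fs") <- frame$fs
  class(out) <- c("posture_trace", "data.frame")
  out
}

#' Posture-recognition decision, double-checked 0.5 s apart
#'
#' Declares a fall posture when the tilt angle exceeds `theta_th` AND the
#' absolute pitch exceeds `pitch_th` AND the absolute roll exceeds `roll_th`
#' at BOTH checks (strict inequalities). Absolute values are compared because
#' falls in opposite directions produce opposite signs.
#'
#' @param first,second Angle sets at the two checks: numeric vectors
#'   `c(theta, pitch, roll)` (extra elements such as yaw are ignored), or
#'   single rows of a [estimate_posture()] trace.
#' @param theta_th,pitch_th,roll_th Thresholds in degrees (defaults 25, 30, 30).
#' @return `TRUE` for fall posture at both checks, else `FALSE`.
#' @examples
#' posture_decision(c(30, 35, 35), c(30, 35, 35)) # TRUE
#' posture_decision(c(30, 35, 35), c(10, 35, 35)) # FALSE: second check fails
#' posture_decision(c(25, 30, 30), c(25, 30, 30)) # FALSE: strict inequality
#' @export
posture_decision <- function(first, second,
                             theta_th = 25, pitch_th = 30, roll_th = 30) {
  pick <- function(a) {
    if (is.data.frame(a)) a <- unlist(a[1, c("theta", "pitch", "roll")])
    as.numeric(a[1:3])
  }
  f <- pick(first); s <- pick(second)
  ok <- function(v) v[1] > theta_th && abs(v[2]) > pitch_th && abs(v[3]) > roll_th
  ok(f) && ok(s)
}
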