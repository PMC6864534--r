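#' Construct a synchronized multi-channel sensor frame
#'
#' A `sensor_frame` holds the time-aligned channels recorded by the body-worn
#' unit: tri-axial acceleration (mandatory), and optionally tri-axial angular
#' rate, tri-axial magnetic field, barometric pressure and CO concentration,
#' all on one uniform time grid at sampling rate `fs`.
#'
#' Acceleration is stored internally in m/s^2; inputs declared in g are
#' multiplied by 9.81 at ingest. Missing optional channels simply disable the
#' detectors that need them downstream.
#'
#' @param fs Sampling rate in Hz.
#' @param ax,ay,az Acceleration per axis. Units per `acc_units`.
#' @param gx,gy,gz Optional angular rate per axis, rad/s.
#' @param mx,my,mz Optional magnetic field per axis, any consistent unit.
#' @param pressure Optional barometric pressure, hPa (strictly positive).
#' @param co Optional CO concentration, ppm (non-negative).
#' @param t Optional time stamps in seconds. Must be a uniform grid with step
#'   `1/fs` within 1e-6 s; non-uniform stamps are rejected rather than
#'   resampled (see [resample_frame()] for rate conversion).
#' @param acc_units Either `"ms2"` (default) or `"g"`.
#' @param prefilter Optional function applied to the completed frame before it
#'   is returned (a hook for device-specific calibration/denoising; default
#'   identity).
#' @return An object of class `sensor_frame`.
#' @examples
#' fr <- sensor_frame(fs = 100, ax = rep(0, 50), ay = rep(0, 50),
#'                    az = rep(9.81, 50))
#' rms_acceleration(fr)$acc[1] # 1 g at rest
#' @export
sensor_frame <- function(fs, ax, ay, az,
                         gx = NULL, gy = NULL, gz = NULL,
                         mx = NULL, my = NULL, mz = NULL,
                         pressure = NULL, co = NULL, t = NULL,
                         acc_units = c("ms2", "g"), prefilter = NULL) {
  acc_units <- match.arg(acc_units)
  check_positive_scalar(fs, "fs")
  if (is.null(ax) || is.null(ay) || is.null(az))
    stop("accelerometer channels ax, ay, az are required", call. = FALSE)
  if (acc_units == "g") {
    ax <- ax * GRAVITY_MS2; ay <- ay * GRAVITY_MS2; az <- az * GRAVITY_MS2
  }
  n <- length(ax)
  if (n < 1L) stop("channels must have length >= 1", call. = FALSE)
  if (is.null(t)) t <- (seq_len(n) - 1L) / fs
  fr <- structure(
    list(t = as.numeric(t), fs = as.numeric(fs),
         ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az),
         gx = gx, gy = gy, gz = gz, mx = mx, my = my, mz = mz,
         pressure = pressure, co = co),
    class = "sensor_frame")
  validate_sensor_frame(fr)
  if (!is.null(prefilter)) {
    stopifnot(is.function(prefilter))
    fr <- prefilter(fr)
    validate_sensor_frame(fr)
  }
  fr
}

#' Validate a sensor frame's invariants
#'
#' Checks equal channel lengths, positive sampling rate, a uniform time grid
#' (step `1/fs` within 1e-6 s), strictly positive pressure and non-negative CO.
#'
#' @param frame A `sensor_frame`.
#' @return The frame, invisibly; errors on violation.
#' @export
validate_sensor_frame <- function(frame) {
  stopifnot(inherits(frame, "sensor_frame"))
  n <- length(frame$ax)
  chans <- c("t", "ax", "ay", "az", "gx", "gy", "gz",
             "mx", "my", "mz", "pressure", "co")
  for (ch in chans) {
    v <- frame[[ch]]
    if (!is.null(v) && length(v) != n)
      stop(sprintf("channel `%s` has length %d, expected %d", ch, length(v), n),
           call. = FALSE)
  }
  if (frame$fs <= 0) stop("`fs` must be > 0", call. = FALSE)
  if (n > 1L) {
    dt <- diff(frame$t)
    if (any(abs(dt - 1 / frame$fs) > 1e-6))
      stop("time stamps are not a uniform 1/fs grid (tolerance 1e-6 s); ",
           "use resample_frame() for rate conversion", call. = FALSE)
  }
  if (!is.null(frame$pressure) && any(frame$pressure <= 0))
    stop("`pressure` must be strictly positive (hPa)", call. = FALSE)
  if (!is.null(frame$co) && any(frame$co < 0))
    stop("`co` must be non-negative (ppm)", call. = FALSE)
  invisible(frame)
}

#' @export
print.sensor_frame <- function(x, ...) {
  opt <- c("gx", "mx", "pressure", "co")
  have <- c(gyro = !is.null(x$gx), mag = !is.null(x$mx),
            baro = !is.null(x$pressure), co = !is.null(x$co))
  cat(sprintf("<sensor_frame> %d samples @ %g Hz (%.2f s)\n",
              length(x$ax), x$fs, length(x$ax) / x$fs))
  cat("  channels: acc", names(have)[have], "\n")
  invisible(x)
}

#' Number of samples in a sensor frame
#' @param x A `sensor_frame`.
#' @export
length.sensor_frame <- function(x) length(x$ax)

#' Read a sensor log from CSV
#'
#' Expected header: `time,ax,ay,az[,gx,gy,gz][,mx,my,mz][,pressure][,co]`.
#' Acceleration units are declared by the caller (or a config), not guessed.
#'
#' @param path CSV file path.
#' @param fs Sampling rate in Hz; if `NULL`, inferred from the median time
#'   step (the grid must still be uniform).
#' @param acc_units `"ms2"` or `"g"`.
#' @param prefilter Optional pre-filter hook, see [sensor_frame()].
#' @return A `sensor_frame`.
#' @export
read_sensor_csv <- function(path, fs = NULL, acc_units = c("ms2", "g"),
                            prefilter = NULL) {
  acc_units <- match.arg(acc_units)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time", "ax", "ay", "az")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!stats::complete.cases(df[need]))
  if (length(bad))
    stop(sprintf("malformed CSV row(s) at line(s) %s (1 = first data row)",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  if (is.null(fs)) {
    if (nrow(df) < 2L)
      stop("cannot infer `fs` from a single row; pass it explicitly",
           call. = FALSE)
    fs <- 1 / stats::median(diff(df$time))
    # snap to a round rate when within tolerance (e.g. 99.9999 -> 100)
    if (abs(fs - round(fs)) < 1e-3) fs <- round(fs)
  }
  grab <- function(nm) if (nm %in% names(df)) df[[nm]] else NULL
  sensor_frame(fs = fs, ax = df$ax, ay = df$ay, az = df$az,
               gx = grab("gx"), gy = grab("gy"), gz = grab("gz"),
               mx = grab("mx"), my = grab("my"), mz = grab("mz"),
               pressure = grab("pressure"), co = grab("co"),
               t = df$time - df$time[1], acc_units = acc_units,
               prefilter = prefilter)
}

#' Write a sensor frame to CSV
#'
#' Inverse of [read_sensor_csv()]; acceleration is written in m/s^2.
#'
#' @param frame A `sensor_frame`.
#' @param path Output path.
#' @export
write_sensor_csv <- function(frame, path) {
  validate_sensor_frame(frame)
  cols <- list(time = frame$t, ax = frame$ax, ay = frame$ay, az = frame$az)
  for (nm in c("gx", "gy", "gz", "mx", "my", "mz", "pressure", "co"))
    if (!is.null(frame[[nm]])) cols[[nm]] <- frame[[nm]]
  utils::write.csv(as.data.frame(cols), path, row.names = FALSE)
  invisible(path)
}

#' Linearly resample a frame to a target rate
#'
#' Utility for bringing 25 Hz public-style logs onto another grid. Detectors
#' themselves never resample: thresholds are stated in seconds and converted
#' with [seconds_to_samples()], so resampling is rarely needed.
#'
#' @param frame A `sensor_frame`.
#' @param fs_target Target sampling rate in Hz.
#' @return A new `sensor_frame` at `fs_target`.
#' @export
resample_frame <- function(frame, fs_target) {
  validate_sensor_frame(frame)
  check_positive_scalar(fs_target, "fs_target")
  t_new <- seq(0, frame$t[length(frame$t)], by = 1 / fs_target)
  interp <- function(v) if (is.null(v)) NULL else
    stats::approx(frame$t, v, xout = t_new, rule = 2)$y
  sensor_frame(fs = fs_target,
               ax = interp(frame$ax), ay = interp(frame$ay), az = interp(frame$az),
               gx = interp(frame$gx), gy = interp(frame$gy), gz = interp(frame$gz),
               mx = interp(frame$mx), my = interp(frame$my), mz = interp(frame$mz),
               pressure = interp(frame$pressure), co = interp(frame$co),
               t = t_new)
}

#' RMS acceleration magnitude in g
#'
#' Per-sample vector magnitude of the three acceleration axes, normalised to
#' g = 9.81 m/s^2: `sqrt(ax^2 + ay^2 + az^2) / 9.81`. (The field calls this
#' the RMS of acceleration; no averaging over time is involved.)
#'
#' @param frame A `sensor_frame`.
#' @return An `acc_magnitude` object: list with `acc` (g) and `fs` (Hz).
#' @examples
#' fr <- sensor_frame(fs = 100, ax = 3, ay = 4, az = 0)
#' rms_acceleration(fr)$acc # 5 / 9.81
#' @export
rms_acceleration <- function(frame) {
  if (!inherits(frame, "sensor_frame"))
    stop("`frame` must be a sensor_frame", call. = FALSE)
  validate_sensor_frame(frame)
  acc <- sqrt(frame$ax^2 + frame$ay^2 + frame$az^2) / GRAVITY_MS2
  structure(list(acc = acc, fs = frame$fs), class = "acc_magnitude")
}

#' @export
print.acc_magnitude <- function(x, ...) {
  cat(sprintf("<acc_magnitude> %d samples @ %g Hz, range [%.3f, %.3f] g\n",
              length(x$acc), x$fs, min(x$acc), max(x$acc)))
  invisible(x)
}
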