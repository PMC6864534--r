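#' Activity labels covered by the scenario simulator
#'
#' The four fall directions, the quiescence accidents (crawl-then-fall,
#' stuck in a narrow path), elevator rides in both directions, the ambulatory
#' on-duty activities, quiet standing, and a CO exposure scenario.
#'
#' @return Character vector of the 17 scenario labels.
#' @export
scenario_labels <- function() {
  c("stand", "walk", "run", "jog", "jump", "crawl",
    "stairs_up", "stairs_down", "elevator_up", "elevator_down",
    "fall_forward", "fall_backward", "fall_left", "fall_right",
    "crawl_then_fall", "stuck_narrow_path", "co_exposure")
}

SCENARIO_DURATIONS <- c(
  stand = 10, walk = 10, run = 12, jog = 12, jump = 12, crawl = 12,
  stairs_up = 14, stairs_down = 14, elevator_up = 16, elevator_down = 16,
  fall_forward = 12, fall_backward = 12, fall_left = 12, fall_right = 12,
  crawl_then_fall = 16, stuck_narrow_path = 14, co_exposure = 20)

# tilt-axis direction (degrees in the horizontal plane) per fall direction
FALL_AXIS_DEG <- c(fall_forward = 45, fall_backward = 225,
                   fall_left = 135, fall_right = 315)

#' Specify a synthetic activity scenario
#'
#' @param label One of [scenario_labels()].
#' @param duration Trace length in seconds; default is a per-label length
#'   long enough for the detectors' evaluation windows.
#' @param fs Sampling rate in Hz (default 100, the device rate).
#' @param noise_sd_acc Per-axis accelerometer noise, g (default 0.02).
#' @param noise_sd_pressure Barometer noise, hPa (default 0.01).
#' @param seed Integer seed; a spec maps deterministically to one trace.
#' @param recovery_s For fall labels only: start time (s) of a 0.5 s recovery
#'   rotation back to upright, producing a stand-up-after-fall trace whose
#'   ground truth is non-fall. `NULL` (default) for a committed fall.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(label, duration = NULL, fs = 100,
                          noise_sd_acc = 0.02, noise_sd_pressure = 0.01,
                          seed = 1, recovery_s = NULL) {
  label <- match.arg(label, scenario_labels())
  duration <- duration %||% unname(SCENARIO_DURATIONS[label])
  check_positive_scalar(duration, "duration")
  check_positive_scalar(fs, "fs")
  if (!is.null(recovery_s) && !startsWith(label, "fall_"))
    stop("`recovery_s` only applies to fall labels", call. = FALSE)
  structure(list(label = label, duration = duration, fs = fs,
                 noise_sd_acc = noise_sd_acc,
                 noise_sd_pressure = noise_sd_pressure,
                 seed = as.integer(seed), recovery_s = recovery_s),
            class = "scenario_spec")
}

# smoothstep ramp 0 -> 1 over [t0, t1]
smoothstep <- function(t, t0, t1) {
  f <- pmin(1, pmax(0, (t - t0) / (t1 - t0)))
  f * f * (3 - 2 * f)
}

# half-sine burst of given peak amplitude over [t0, t1]
burst <- function(t, t0, t1, peak) {
  inside <- t >= t0 & t < t1
  out <- numeric(length(t))
  out[inside] <- peak * sin(pi * (t[inside] - t0) / (t1 - t0))
  out
}

#' Generate a synthetic sensor trace with ground truth
#'
#' Produces a deterministic (given the seed) `sensor_frame` emulating the
#' labelled activity, together with the ground-truth events implied by its
#' construction. Fall traces contain a quiet stance, a sub-1 g free-fall dip,
#' an impact spike above 2.5 g, a damped ripple and a tilted rest posture;
#' elevator traces pair near-1 g quiescence with an altitude ramp; the
#' quiescence accidents pair it with flat altitude; ambulatory traces
#' oscillate in label-specific bands. Ground-truth indices are derived from
#' the clean profiles, before noise is added.
#'
#' @param spec A [scenario_spec()] (or a label, for defaults).
#' @return A `scenario` list: `frame` (sensor_frame), `truth` (data.frame
#'   `kind,index,time`), `spec`, and `clean` (noise-free magnitude/altitude/CO
#'   profiles, for reference).
#' @export
generate_scenario <- function(spec) {
  if (is.character(spec)) spec <- scenario_spec(spec)
  stopifnot(inherits(spec, "scenario_spec"))
  # localise RNG state
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  fs <- spec$fs
  n <- seconds_to_samples(spec$duration, fs)
  t <- (seq_len(n) - 1L) / fs
  lab <- spec$label
  base_alt <- 20                      # metres: a few storeys up
  alt <- rep(base_alt, n)
  co <- NULL
  tilt_axis_deg <- 90                 # pitch-forward axis default
  tilt <- numeric(n)                  # tilt angle profile, degrees
  truth_kind <- character()
  truth_idx <- integer()

  osc <- function(amp, freq) 1 + amp * sin(2 * pi * freq * t)

  mag <- switch(lab,
    stand = rep(1, n),
    walk = osc(0.40, 2.0),
    jog  = osc(0.55, 2.5),
    run  = osc(0.90, 3.0),
    jump = {
      m <- rep(1, n)
      for (tb in seq(2, spec$duration - 1, by = 2))
        m <- m + burst(t, tb, tb + 0.3, 1.5)
      m
    },
    crawl = osc(0.30, 1.2),
    stairs_up = , stairs_down = {
      ramp <- 3 * smoothstep(t, 2, spec$duration - 2)
      alt <- base_alt + if (lab == "stairs_up") ramp else -ramp
      osc(0.45, 2.0)
    },
    elevator_up = , elevator_down = {
      m <- rep(1, n)
      pre <- t < 2.5; post <- t >= spec$duration - 2.5
      m[pre] <- 1 + 0.35 * sin(2 * pi * 2 * t[pre])
      m[post] <- 1 + 0.35 * sin(2 * pi * 2 * (t[post] - (spec$duration - 2.5)))
      # constant-velocity travel spanning the whole quiescent ride, so every
      # 4 s quiescence window sees the full altitude rate (0.3 m/s)
      travel <- 0.3 * pmin(spec$duration - 5, pmax(0, t - 2.5))
      alt <- base_alt + if (lab == "elevator_up") travel else -travel
      m
    },
    fall_forward = , fall_backward = , fall_left = , fall_right = {
      tilt_axis_deg <- FALL_AXIS_DEG[[lab]]
      tilt <- 75 * smoothstep(t, 3.3, 3.9)
      if (!is.null(spec$recovery_s))
        tilt <- tilt * (1 - smoothstep(t, spec$recovery_s, spec$recovery_s + 0.5))
      m <- rep(1, n)
      m[t >= 3.0 & t < 3.3] <- 0.3                      # flight of fall
      m <- m + burst(t, 3.3, 3.45, 2.0)                 # impact, peak 3 g
      rip <- t >= 3.45 & t < 4.8
      m[rip] <- 1 + 0.45 * exp(-2 * (t[rip] - 3.45)) *
        sin(2 * pi * 6 * (t[rip] - 3.45))               # damped settling
      m
    },
    crawl_then_fall = {
      m <- osc(0.30, 1.2)
      m[t >= 6] <- 1
      m <- m + burst(t, 6, 6.2, 0.5)                    # sub-threshold collapse
      tilt_axis_deg <- 90
      tilt <- 70 * smoothstep(t, 0.5, 1.5)              # crawling posture
      m
    },
    stuck_narrow_path = {
      m <- osc(0.30, 1.2)
      m[t >= 4] <- 1
      tilt_axis_deg <- 90
      tilt <- 70 * smoothstep(t, 0.5, 1.5)
      m
    },
    co_exposure = {
      co <- rep(7, n)
      ramp <- t >= 6 & t < 9
      co[ramp] <- 7 + (40 - 7) * (t[ramp] - 6) / 3
      plat <- t >= 9
      co[plat] <- 40 + 2 * sin(2 * pi * 0.2 * (t[plat] - 9))
      osc(0.40, 1.5)
    })

  # ground truth from the clean profiles
  if (startsWith(lab, "fall_") && is.null(spec$recovery_s)) {
    truth_kind <- "fall"
    truth_idx <- which(mag > 1.8)[1] - 1L
  } else if (lab %in% c("crawl_then_fall", "stuck_narrow_path",
                        "elevator_up", "elevator_down")) {
    clean_acc <- structure(list(acc = mag, fs = fs), class = "acc_magnitude")
    runs <- quiescence_windows(clean_acc, lopp_config())
    if (nrow(runs)) {
      truth_kind <- if (startsWith(lab, "elevator"))
        sub("elevator", "moving", lab) else "lopp"
      truth_idx <- runs$start[1]
    }
  } else if (lab == "co_exposure") {
    truth_kind <- "co_alert"
    truth_idx <- which(co >= 33)[1] - 1L
  }

  # orientation: tilt about a fixed horizontal axis
  arad <- tilt_axis_deg * pi / 180
  u <- c(cos(arad), sin(arad), 0)
  phi <- tilt * pi / 180
  s <- sin(phi); cph <- cos(phi)
  gdir <- cbind(-u[2] * s, u[1] * s, cph)     # gravity direction, sensor frame
  # exact angular rate for a fixed-axis rotation
  dphi <- c(diff(phi), 0) * fs
  gyro <- outer(dphi, u)

  sd_a <- spec$noise_sd_acc * GRAVITY_MS2
  acc <- gdir * mag * GRAVITY_MS2 + matrix(stats::rnorm(3 * n, 0, sd_a), n, 3)
  gyro <- gyro + matrix(stats::rnorm(3 * n, 0, 0.005), n, 3)
  # earth magnetic field rotated into the sensor frame (Rodrigues about u)
  m_e <- c(0.43, 0, -0.50)
  uxm <- c(u[2] * m_e[3], -u[1] * m_e[3], u[1] * m_e[2] - u[2] * m_e[1])
  udm <- sum(u * m_e)
  magf <- cbind(m_e[1] * cph, m_e[2] * cph, m_e[3] * cph) -
    cbind(uxm[1] * s, uxm[2] * s, uxm[3] * s) +
    outer(1 - cph, u * udm)
  magf <- magf + matrix(stats::rnorm(3 * n, 0, 0.01), n, 3)
  pressure <- altitude_to_pressure(alt) +
    stats::rnorm(n, 0, spec$noise_sd_pressure)
  if (!is.null(co)) co_noisy <- co + stats::rnorm(n, 0, 0.3)

  frame <- sensor_frame(
    fs = fs, ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
    gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3],
    mx = magf[, 1], my = magf[, 2], mz = magf[, 3],
    pressure = pressure, co = if (is.null(co)) NULL else pmax(0, co_noisy))

  truth <- data.frame(kind = truth_kind, index = truth_idx,
                      time = truth_idx / fs, stringsAsFactors = FALSE)
  structure(list(frame = frame, truth = truth, spec = spec,
                 clean = list(mag = mag, alt = alt, co = co)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s, %g s @ %g Hz, seed %d; truth: %s\n",
              x$spec$label, x$spec$duration, x$spec$fs, x$spec$seed,
              if (nrow(x$truth)) paste(x$truth$kind, "@", round(x$truth$time, 2),
                                       "s", collapse = ", ") else "none"))
  invisible(x)
}

#' Generate a deterministic suite of scenarios over all activity classes
#'
#' @param n_per_class Traces per label (`>= 1`).
#' @param seed Master seed; per-trace seeds are derived from it, so identical
#'   seeds give bit-identical suites and different seeds change only the
#'   noise realisations, never the truth structure.
#' @param labels Labels to include (default all of [scenario_labels()]).
#' @param ... Passed to [scenario_spec()] (e.g. noise levels).
#' @return List of `scenario` objects, length `n_per_class * length(labels)`.
#' @export
make_suite <- function(n_per_class = 3, seed = 1, labels = scenario_labels(),
                       ...) {
  stopifnot(n_per_class >= 1)
  labels <- match.arg(labels, scenario_labels(), several.ok = TRUE)
  out <- vector("list", n_per_class * length(labels))
  k <- 0L
  for (lab in labels) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      child <- (as.integer(seed) * 1009L + k * 7919L) %% 2147483647L
      out[[k]] <- generate_scenario(scenario_spec(lab, seed = child, ...))
    }
  }
  out
}
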