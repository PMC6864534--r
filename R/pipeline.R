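#' Pipeline configuration
#'
#' One flat configuration covering every detector, round-trippable through
#' YAML with [read_pipeline_config()]/[write_pipeline_config()]. Defaults are
#' the device's operating parameters (thresholds in g, degrees, metres, ppm;
#' durations in seconds, so the same file works at any sampling rate).
#'
#' @param acc_units Acceleration units of CSV inputs: `"ms2"` or `"g"`.
#' @param detectors Which detectors to run: subset of `"fall"`, `"lopp"`,
#'   `"co"`.
#' @param algorithm Fall-cascade variant, see [detect_falls()].
#' @param uth,upt,lpt,postfall_delay_s,postfall_window_s,posture_recheck_s,refractory_s
#'   Fall cascade parameters, see [fall_config()].
#' @param theta_th_deg,pitch_th_deg,roll_th_deg Posture thresholds, degrees.
#' @param madgwick_beta Orientation filter gain.
#' @param use_mag Use magnetometer channels (MARG variant) when present.
#' @param lu_mov_g,ll_mov_g,lopp_window_s,alt_band_m Quiescence parameters,
#'   see [lopp_config()].
#' @param p0_hpa Reference sea-level pressure.
#' @param baro_exponent_denominator Barometric exponent denominator.
#' @param kalman_r,kalman_q,kalman_p_init Scalar Kalman parameters.
#' @param co_alert_ppm,co_hold_s CO alerting parameters, see [co_config()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(acc_units = "ms2",
                            detectors = c("fall", "lopp", "co"),
                            algorithm = "algorithm1",
                            uth = 1.8, upt = 1.25, lpt = 0.75,
                            postfall_delay_s = 3, postfall_window_s = 2,
                            posture_recheck_s = 0.5, refractory_s = 6,
                            theta_th_deg = 25, pitch_th_deg = 30,
                            roll_th_deg = 30, madgwick_beta = 0.1,
                            use_mag = FALSE,
                            lu_mov_g = 1.2, ll_mov_g = 0.8,
                            lopp_window_s = 4, alt_band_m = 0.5,
                            p0_hpa = 1013.25,
                            baro_exponent_denominator = 5.225,
                            kalman_r = 1, kalman_q = 0.01, kalman_p_init = 1,
                            co_alert_ppm = 33, co_hold_s = 2) {
  detectors <- match.arg(detectors, c("fall", "lopp", "co"),
                         several.ok = TRUE)
  cfg <- list(acc_units = match.arg(acc_units, c("ms2", "g")),
              detectors = detectors,
              algorithm = match.arg(algorithm, FALL_ALGORITHMS),
              uth = uth, upt = upt, lpt = lpt,
              postfall_delay_s = postfall_delay_s,
              postfall_window_s = postfall_window_s,
              posture_recheck_s = posture_recheck_s,
              refractory_s = refractory_s,
              theta_th_deg = theta_th_deg, pitch_th_deg = pitch_th_deg,
              roll_th_deg = roll_th_deg, madgwick_beta = madgwick_beta,
              use_mag = use_mag,
              lu_mov_g = lu_mov_g, ll_mov_g = ll_mov_g,
              lopp_window_s = lopp_window_s, alt_band_m = alt_band_m,
              p0_hpa = p0_hpa,
              baro_exponent_denominator = baro_exponent_denominator,
              kalman_r = kalman_r, kalman_q = kalman_q,
              kalman_p_init = kalman_p_init,
              co_alert_ppm = co_alert_ppm, co_hold_s = co_hold_s)
  # instantiate the per-detector configs now so invariants fail early
  fall_config(uth, upt, lpt, postfall_delay_s, postfall_window_s,
              posture_recheck_s, refractory_s, theta_th_deg, pitch_th_deg,
              roll_th_deg)
  lopp_config(lu_mov_g, ll_mov_g, lopp_window_s, alt_band_m)
  co_config(co_alert_ppm, hold_s = co_hold_s)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; omitted keys take their defaults.
#'
#' @param path YAML file with flat `key: value` pairs.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to YAML
#'
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full detection pipeline over one sensor log
#'
#' Single pass per the detection flowchart: RMS acceleration feeds both the
#' fall gate (`Acc > Uth` opens the three-feature cascade) and the quiescence
#' gate (band-bounded acceleration for the configured window opens the
#' altitude disambiguation); the CO path runs independently. Events are
#' merged with fall-before-lopp precedence: quiescence events overlapping an
#' emitted fall's evaluation window are dropped, since the flowchart branches
#' on the fall gate first.
#'
#' Channels gate the detectors: no gyroscope disables posture-based fall
#' cascades (only `algorithm4` can run without one), no barometer degrades
#' the quiescence path (see [detect_lopp()]), no CO channel disables CO
#' alerting.
#'
#' @param x A `sensor_frame` or a CSV path readable by [read_sensor_csv()].
#' @param config A [pipeline_config()].
#' @return A `pipeline_result`: list with `events` (merged
#'   `detection_events`), `report` (per-kind counts), and `log` (data.frame
#'   of threshold crossings and gate decisions, timestamped in trace
#'   seconds).
#' @export
run_pipeline <- function(x, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  frame <- if (inherits(x, "sensor_frame")) x else
    read_sensor_csv(x, acc_units = config$acc_units)
  validate_sensor_frame(frame)
  fs <- frame$fs
  acc <- rms_acceleration(frame)
  log_rows <- list()
  note <- function(time, what, detail = "") {
    log_rows[[length(log_rows) + 1L]] <<-
      data.frame(time = time, what = what, detail = detail)
  }

  fall_ev <- NULL
  fall_windows <- NULL
  if ("fall" %in% config$detectors) {
    needs_pr <- config$algorithm != "algorithm4"
    if (needs_pr && is.null(frame$gx)) {
      warning("no gyroscope channels: fall detector disabled (posture needs ",
              "the orientation filter)", call. = FALSE)
    } else {
      angles <- if (!is.null(frame$gx)) {
        estimate_posture(frame, beta = config$madgwick_beta,
                         use_mag = config$use_mag)
      } else {
        # algorithm4 needs theta only
        out <- data.frame(theta = theta_angle(frame$ax, frame$ay, frame$az),
                          pitch = 0, roll = 0, yaw = 0)
        attr(out, "fs") <- fs
        out
      }
      fcfg <- fall_config(config$uth, config$upt, config$lpt,
                          config$postfall_delay_s, config$postfall_window_s,
                          config$posture_recheck_s, config$refractory_s,
                          config$theta_th_deg, config$pitch_th_deg,
                          config$roll_th_deg)
      fall_ev <- detect_falls(acc, angles, fcfg, algorithm = config$algorithm)
      cands <- attr(fall_ev, "candidates")
      for (i in seq_len(nrow(cands)))
        note(cands$index[i] / fs, "uth_crossing",
             sprintf("postfall=%s posture=%s emitted=%s", cands$postfall[i],
                     cands$posture[i], cands$emitted[i]))
      d_eval <- config$postfall_delay_s + config$postfall_window_s +
        config$posture_recheck_s
      fall_windows <- cbind(fall_ev$index, fall_ev$index +
                              seconds_to_samples(d_eval, fs))
    }
  }

  lopp_ev <- NULL
  if ("lopp" %in% config$detectors) {
    lcfg <- lopp_config(config$lu_mov_g, config$ll_mov_g,
                        config$lopp_window_s, config$alt_band_m)
    altitude <- if (!is.null(frame$pressure))
      altitude_trace(frame, p0 = config$p0_hpa,
                     exponent_denominator = config$baro_exponent_denominator,
                     kalman_r = config$kalman_r, kalman_q = config$kalman_q,
                     kalman_p_init = config$kalman_p_init) else NULL
    lopp_ev <- detect_lopp(acc, altitude, lcfg)
    for (i in seq_len(nrow(lopp_ev)))
      note(lopp_ev$index[i] / fs, "quiescence",
           paste0("class=", lopp_ev$kind[i]))
    # fall precedence: drop quiescence events overlapping a fall evaluation
    if (!is.null(fall_windows) && nrow(lopp_ev) && nrow(fall_windows)) {
      keep <- vapply(seq_len(nrow(lopp_ev)), function(i) {
        !any(lopp_ev$index[i] <= fall_windows[, 2] &
               lopp_ev$index[i] >= fall_windows[, 1])
      }, logical(1))
      dropped <- which(!keep)
      for (i in dropped)
        note(lopp_ev$index[i] / fs, "precedence",
             "quiescence event dropped: overlaps fall evaluation window")
      lopp_ev <- lopp_ev[keep, , drop = FALSE]
    }
  }

  co_ev <- NULL
  if ("co" %in% config$detectors && !is.null(frame$co)) {
    ccfg <- co_config(config$co_alert_ppm, hold_s = config$co_hold_s)
    co_ev <- detect_co(frame$co, fs = fs, cfg = ccfg,
                       kalman = kalman_state(x = frame$co[1],
                                             p = config$kalman_p_init,
                                             r = config$kalman_r,
                                             q = config$kalman_q))
    for (i in seq_len(nrow(co_ev)))
      note(co_ev$index[i] / fs, "co_crossing", paste0("kind=", co_ev$kind[i]))
  }

  events <- bind_events(fall_ev, lopp_ev, co_ev)
  report <- as.data.frame(table(factor(events$kind, levels = EVENT_KINDS)),
                          stringsAsFactors = FALSE)
  names(report) <- c("kind", "n")
  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(time = numeric(), what = character(), detail = character())
  log <- log[order(log$time), , drop = FALSE]
  rownames(log) <- NULL
  structure(list(events = events, report = report, log = log,
                 n_samples = length(frame$ax), fs = fs),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d samples @ %g Hz\n", x$n_samples, x$fs))
  print(x$events)
  invisible(x)
}
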