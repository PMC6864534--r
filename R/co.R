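#' CO alerting configuration
#'
#' The operational alert threshold defaults to 33 ppm, chosen from empirical
#' smoke-room measurements; 35 ppm is retained as the documented OSHA
#' reference for a hazardous work environment but is not the default trigger.
#'
#' @param alert_ppm Alert threshold in ppm (default 33, inclusive comparison).
#' @param reference_hazard_ppm Documentation-only OSHA reference (35 ppm).
#' @param hold_s Debounce: the smoothed level must stay at/above (or below)
#'   the threshold this long before an alert (or all-clear) opens. Default 2 s.
#' @return A `co_config` list.
#' @export
co_config <- function(alert_ppm = 33, reference_hazard_ppm = 35, hold_s = 2) {
  check_positive_scalar(alert_ppm, "alert_ppm")
  check_positive_scalar(hold_s, "hold_s")
  structure(list(alert_ppm = alert_ppm,
                 reference_hazard_ppm = reference_hazard_ppm,
                 hold_s = hold_s), class = "co_config")
}

#' High-CO alerting with Kalman smoothing and debounce
#'
#' The ppm trace is smoothed with the scalar Kalman filter, then a two-state
#' machine opens a `co_alert` event when the smoothed level holds at or above
#' `alert_ppm` for `hold_s` continuously, and a `co_safe` event when it holds
#' below for `hold_s` (so the breathing apparatus can be removed to save
#' compressed air). Alert and safe events strictly alternate; the trace
#' starts in the safe state with no event.
#'
#' @param co Numeric ppm trace (non-negative), or a `sensor_frame` with a CO
#'   channel.
#' @param fs Sampling rate in Hz (taken from the frame when given one).
#' @param cfg A [co_config()].
#' @param kalman Initial `kalman_state` for the smoother; default seeds at
#'   the first sample with r = 1, q = 0.01.
#' @return A `detection_events` table of `co_alert`/`co_safe` events, with
#'   attribute `smoothed` (the filtered trace).
#' @export
detect_co <- function(co, fs = NULL, cfg = co_config(), kalman = NULL) {
  if (inherits(co, "sensor_frame")) {
    fs <- co$fs
    co <- co$co
  }
  if (is.null(co) || !length(co)) stop("empty CO trace", call. = FALSE)
  if (any(co < 0)) stop("`co` must be non-negative (ppm)", call. = FALSE)
  if (is.null(fs)) stop("`fs` is required with a bare ppm vector", call. = FALSE)
  sm <- kalman_smooth(co, init = kalman)
  hold <- seconds_to_samples(cfg$hold_s, fs)
  above <- sm >= cfg$alert_ppm
  kinds <- character(); idx <- integer(); details <- list()
  state <- "safe"
  run_start <- NA_integer_
  for (i in seq_along(above)) {
    crossing <- (state == "safe") == above[i]   # sample arguing for a switch
    if (crossing) {
      if (is.na(run_start)) run_start <- i
      if (i - run_start + 1L >= hold) {
        state <- if (state == "safe") "alert" else "safe"
        kinds <- c(kinds, if (state == "alert") "co_alert" else "co_safe")
        idx <- c(idx, run_start - 1L)
        details[[length(details) + 1L]] <-
          list(ppm = sm[i], threshold = cfg$alert_ppm)
        run_start <- NA_integer_
      }
    } else {
      run_start <- NA_integer_
    }
  }
  out <- detection_events(kinds, idx, fs = fs, detail = details,
                          n_samples = length(co))
  attr(out, "smoothed") <- sm
  out
}
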