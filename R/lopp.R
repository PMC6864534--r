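#' Loss-of-physical-performance configuration
#'
#' @param lu_mov,ll_mov Upper/lower bounds in g of the quiescence band
#'   (`ll_mov < 1 < lu_mov`; defaults 1.2 and 0.8).
#' @param window Quiescence duration T in seconds required before the state
#'   is classified (default 4).
#' @param alt_band Altitude-change magnitude in metres separating elevator
#'   travel from incapacitation (default 0.5; applied symmetrically).
#' @return A `lopp_config` list.
#' @export
lopp_config <- function(lu_mov = 1.2, ll_mov = 0.8, window = 4,
                        alt_band = 0.5) {
  if (!(ll_mov < 1 && 1 < lu_mov))
    stop("need ll_mov < 1 < lu_mov", call. = FALSE)
  check_positive_scalar(window, "window")
  check_positive_scalar(alt_band, "alt_band")
  structure(list(lu_mov = lu_mov, ll_mov = ll_mov, window = window,
                 alt_band = alt_band), class = "lopp_config")
}

#' Maximal quiescence windows of the RMS acceleration
#'
#' Finds the maximal runs in which every sample lies strictly inside the band
#' `(ll_mov, lu_mov)` and that span at least the configured window (the run
#' must cover `window` seconds, i.e. `window * fs + 1` samples with both
#' endpoints included).
#'
#' @param acc An `acc_magnitude`.
#' @param cfg A [lopp_config()].
#' @return A data.frame with 0-based `start` and `end` sample indices of each
#'   maximal quiescent run (may have zero rows).
#' @export
quiescence_windows <- function(acc, cfg = lopp_config()) {
  stopifnot(inherits(acc, "acc_magnitude"))
  a <- acc$acc
  if (!length(a)) stop("empty acceleration trace", call. = FALSE)
  wlen <- seconds_to_samples(cfg$window, acc$fs)
  inside <- a > cfg$ll_mov & a < cfg$lu_mov
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= wlen + 1L
  data.frame(start = starts[keep] - 1L, end = ends[keep] - 1L)
}

#' Classify a quiescent window from its altitude change
#'
#' `delta = h_filtered[j + T] - h_filtered[j]` over the window of length `T`
#' seconds: above `+alt_band` means the wearer is riding an elevator up,
#' below `-alt_band` down; within the band the wearer is motionless at a
#' fixed altitude, i.e. loss of physical performance.
#'
#' @param j 0-based window-start sample index.
#' @param altitude An `altitude_trace` covering the window.
#' @param cfg A [lopp_config()].
#' @return Character scalar: `"moving_up"`, `"moving_down"` or `"lopp"`,
#'   with attribute `delta` (metres).
#' @export
classify_state <- function(j, altitude, cfg = lopp_config()) {
  stopifnot(inherits(altitude, "altitude_trace"))
  wlen <- seconds_to_samples(cfg$window, altitude$fs)
  i1 <- as.integer(j) + 1L
  h <- altitude$h_filtered
  if (i1 < 1L || i1 + wlen > length(h))
    stop("altitude trace does not cover the window", call. = FALSE)
  delta <- h[i1 + wlen] - h[i1]
  kind <- if (delta > cfg$alt_band) "moving_up"
          else if (delta < -cfg$alt_band) "moving_down"
          else "lopp"
  structure(kind, delta = delta)
}

#' Detect loss of physical performance with barometric disambiguation
#'
#' Slides the T-second window over each maximal quiescent run, classifies
#' every window position with [classify_state()], and coalesces consecutive
#' windows of the same class into one event. Quiescence with flat altitude
#' raises a `lopp` alert; quiescence with a sustained altitude ramp instead
#' yields `moving_up`/`moving_down` floor-direction events and suppresses the
#' alert (the elevator case). Without an altitude trace the elevator case
#' cannot be ruled out: `lopp` events are still emitted, flagged
#' `degraded = TRUE`, with a warning.
#'
#' @param acc An `acc_magnitude`.
#' @param altitude An `altitude_trace` aligned with `acc`, or `NULL`.
#' @param cfg A [lopp_config()].
#' @return A `detection_events` table with attribute `windows` (the
#'   per-position classifications).
#' @export
detect_lopp <- function(acc, altitude = NULL, cfg = lopp_config()) {
  stopifnot(inherits(acc, "acc_magnitude"))
  runs <- quiescence_windows(acc, cfg)
  wlen <- seconds_to_samples(cfg$window, acc$fs)
  kinds <- character(); idx <- integer(); details <- list()
  win_log <- list()
  if (is.null(altitude)) {
    if (nrow(runs))
      warning("no altitude channel: loss of physical performance cannot be ",
              "disambiguated from elevator travel (degraded mode)",
              call. = FALSE)
    for (r in seq_len(nrow(runs))) {
      kinds <- c(kinds, "lopp"); idx <- c(idx, runs$start[r])
      details[[length(details) + 1L]] <-
        list(degraded = TRUE, run_end = runs$end[r])
    }
  } else {
    stopifnot(inherits(altitude, "altitude_trace"))
    if (length(altitude$h_filtered) != length(acc$acc))
      stop("`acc` and `altitude` lengths differ", call. = FALSE)
    for (r in seq_len(nrow(runs))) {
      js <- runs$start[r]:(runs$end[r] - wlen)
      cls <- vapply(js, function(j)
        as.character(classify_state(j, altitude, cfg)), character(1))
      win_log[[length(win_log) + 1L]] <-
        data.frame(run = r, start = js, class = cls)
      # coalesce consecutive same-class window positions
      rl <- rle(cls)
      pos <- cumsum(rl$lengths) - rl$lengths + 1L
      for (g in seq_along(rl$values)) {
        j0 <- js[pos[g]]
        kinds <- c(kinds, rl$values[g]); idx <- c(idx, j0)
        details[[length(details) + 1L]] <- list(
          degraded = FALSE,
          delta_altitude = attr(classify_state(j0, altitude, cfg), "delta"),
          n_windows = rl$lengths[g])
      }
    }
  }
  out <- detection_events(kinds, idx, fs = acc$fs, detail = details,
                          n_samples = length(acc$acc))
  attr(out, "windows") <- if (length(win_log)) do.call(rbind, win_log) else
    data.frame(run = integer(), start = integer(), class = character())
  out
}
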