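#' Fall-cascade configuration
#'
#' Thresholds and timings of the three-feature fall cascade. Defaults are the
#' device's operating parameters: upper threshold 1.8 g, post-fall band
#' (0.75, 1.25) g checked from 3 s to 5 s after the trigger, posture
#' recognition double-checked 0.5 s apart.
#'
#' @param uth Upper threshold in g that a fall impact must exceed.
#' @param upt,lpt Upper/lower post-fall band bounds in g (`lpt < 1 < upt < uth`).
#' @param postfall_delay Seconds after the trigger before the rest state is
#'   checked (default 3, letting the body settle).
#' @param postfall_window Length of the rest-state check in seconds (default 2).
#' @param posture_recheck Interval between the two posture checks, seconds.
#' @param refractory Suppression period after an emitted fall event, seconds.
#' @param theta_th,pitch_th,roll_th Posture thresholds in degrees.
#' @return A `fall_config` list.
#' @export
fall_config <- function(uth = 1.8, upt = 1.25, lpt = 0.75,
                        postfall_delay = 3, postfall_window = 2,
                        posture_recheck = 0.5, refractory = 6,
                        theta_th = 25, pitch_th = 30, roll_th = 30) {
  if (!(lpt < 1 && 1 < upt && upt < uth))
    stop("need lpt < 1 < upt < uth", call. = FALSE)
  for (nm in c("postfall_delay", "postfall_window", "posture_recheck",
               "refractory"))
    check_positive_scalar(get(nm), nm)
  structure(list(uth = uth, upt = upt, lpt = lpt,
                 postfall_delay = postfall_delay,
                 postfall_window = postfall_window,
                 posture_recheck = posture_recheck, refractory = refractory,
                 theta_th = theta_th, pitch_th = pitch_th, roll_th = roll_th),
            class = "fall_config")
}

FALL_ALGORITHMS <- c("algorithm1", "algorithm2", "algorithm3", "algorithm4")

# posture check of one candidate under a given cascade variant.
# i1 is the 1-based trigger index.
posture_check <- function(angles, i1, d5, drc, cfg, algorithm) {
  a1 <- angles[i1 + d5, ]
  cond <- function(row, theta = TRUE, pr = TRUE) {
    ok <- TRUE
    if (theta) ok <- ok && row$theta > cfg$theta_th
    if (pr) ok <- ok && abs(row$pitch) > cfg$pitch_th &&
        abs(row$roll) > cfg$roll_th
    ok
  }
  switch(algorithm,
    algorithm1 = cond(a1) && cond(angles[i1 + d5 + drc, ]),
    algorithm2 = cond(a1),
    algorithm3 = cond(a1, theta = FALSE),
    algorithm4 = cond(a1, pr = FALSE))
}

#' Detect falls with the three-feature threshold cascade
#'
#' Scans the RMS acceleration for samples exceeding the upper threshold; each
#' trigger `j` becomes a candidate that is confirmed only if (a) every sample
#' from `j + 3 s` to `j + 5 s` lies strictly inside the post-fall band
#' `(lpt, upt)` and (b) the posture decision holds at `j + 5 s` and
#' `j + 5.5 s`. Reduced cascade variants drop parts of the posture check (see
#' [ablation_variant()]). Super-threshold samples inside an open candidate's
#' evaluation window fold into that candidate; after an emitted event further
#' triggers are suppressed for the refractory period.
#'
#' @param acc An `acc_magnitude` (from [rms_acceleration()]).
#' @param angles A `posture_trace` (from [estimate_posture()]) with the same
#'   length and sampling rate.
#' @param cfg A [fall_config()].
#' @param algorithm Cascade variant: `"algorithm1"` (full, default),
#'   `"algorithm2"` (single posture check), `"algorithm3"` (no theta
#'   condition), `"algorithm4"` (no pitch/roll condition).
#' @return A `detection_events` table of `fall` events, with an attribute
#'   `candidates`: a data.frame logging every evaluated trigger (0-based
#'   index, post-fall and posture outcomes, emitted flag).
#' @export
detect_falls <- function(acc, angles, cfg = fall_config(),
                         algorithm = "algorithm1") {
  stopifnot(inherits(acc, "acc_magnitude"))
  algorithm <- match.arg(algorithm, FALL_ALGORITHMS)
  a <- acc$acc
  n <- length(a)
  fs <- acc$fs
  if (!is.null(attr(angles, "fs")) && attr(angles, "fs") != fs)
    stop("`acc` and `angles` sampling rates differ", call. = FALSE)
  if (nrow(angles) != n)
    stop("`acc` and `angles` lengths differ", call. = FALSE)
  d3 <- seconds_to_samples(cfg$postfall_delay, fs)
  d5 <- seconds_to_samples(cfg$postfall_delay + cfg$postfall_window, fs)
  drc <- seconds_to_samples(cfg$posture_recheck, fs)
  refr <- seconds_to_samples(cfg$refractory, fs)
  ev_idx <- integer()
  ev_detail <- list()
  cand <- list()
  i <- 1L
  while (i <= n) {
    if (a[i] > cfg$uth) {
      j <- i
      end_eval <- j + d5 + drc
      if (end_eval > n) {
        warning(sprintf(
          "trigger at %.2f s too close to trace end for the %.1f s cascade; evaluated as non-fall",
          (j - 1) / fs, (d5 + drc) / fs), call. = FALSE)
        post_ok <- FALSE; posture_ok <- FALSE
      } else {
        w <- a[(j + d3):(j + d5)]
        post_ok <- all(w > cfg$lpt & w < cfg$upt)
        posture_ok <- post_ok && posture_check(angles, j, d5, drc, cfg,
                                               algorithm)
      }
      emitted <- post_ok && posture_ok
      cand[[length(cand) + 1L]] <-
        data.frame(index = j - 1L, postfall = post_ok, posture = posture_ok,
                   emitted = emitted)
      if (emitted) {
        ev_idx <- c(ev_idx, j - 1L)
        ev_detail[[length(ev_detail) + 1L]] <- list(
          peak_g = max(a[j:min(n, j + d3)]),
          theta = angles$theta[j + d5], pitch = angles$pitch[j + d5],
          roll = angles$roll[j + d5], algorithm = algorithm)
        i <- j + refr
      } else {
        i <- j + d5 + drc + 1L
      }
    } else {
      i <- i + 1L
    }
  }
  out <- detection_events(rep("fall", length(ev_idx)), ev_idx, fs = fs,
                          detail = ev_detail, n_samples = n)
  attr(out, "candidates") <- if (length(cand)) do.call(rbind, cand) else
    data.frame(index = integer(), postfall = logical(), posture = logical(),
               emitted = logical())
  out
}

#' Reduced fall-cascade variants
#'
#' Returns a detector function implementing the requested cascade variant:
#' `algorithm1` is the full cascade (posture double-check); `algorithm2`
#' drops the 0.5 s recheck; `algorithm3` additionally drops the theta
#' condition; `algorithm4` instead drops the pitch/roll (orientation filter)
#' condition. Used to study what each feature contributes.
#'
#' @param name One of `"algorithm1" ... "algorithm4"`.
#' @return A function `(acc, angles, cfg)` returning `detection_events`.
#' @export
ablation_variant <- function(name) {
  name <- match.arg(name, FALL_ALGORITHMS)
  function(acc, angles, cfg = fall_config())
    detect_falls(acc, angles, cfg, algorithm = name)
}
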