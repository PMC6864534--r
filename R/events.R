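# Detection events are data.frames with columns:
#   kind   : "fall" | "lopp" | "moving_up" | "moving_down" | "co_alert" | "co_safe"
#   index  : 0-based trigger sample
#   time   : seconds, index / fs
#   detail : list-column of per-kind diagnostics
# moving_up / moving_down / co_safe are informational; fall / lopp / co_alert
# are the alert kinds that page the incident commander.

EVENT_KINDS <- c("fall", "lopp", "moving_up", "moving_down",
                 "co_alert", "co_safe")
ALERT_KINDS <- c("fall", "lopp", "co_alert")

#' Construct a detection-event table
#'
#' @param kind Character vector of event kinds (see Details).
#' @param index Integer vector of 0-based trigger sample indices.
#' @param fs Sampling rate in Hz, used to derive `time = index / fs`.
#' @param detail List of per-event diagnostic lists (peak g, angles,
#'   altitude change, ppm, ...).
#' @param n_samples Optional trace length for bounds checking.
#' @return A `detection_events` data.frame.
#' @details Valid kinds: `fall`, `lopp`, `moving_up`, `moving_down`,
#'   `co_alert`, `co_safe`. The last three of the non-fall kinds are
#'   informational rather than alerts.
#' @export
detection_events <- function(kind = character(), index = integer(), fs = 1,
                             detail = NULL, n_samples = NULL) {
  kind <- as.character(kind)
  bad <- setdiff(unique(kind), EVENT_KINDS)
  if (length(bad))
    stop("unknown event kind(s): ", paste(bad, collapse = ", "), call. = FALSE)
  index <- as.integer(index)
  if (length(index) != length(kind))
    stop("`kind` and `index` must have equal length", call. = FALSE)
  if (any(index < 0)) stop("`index` must be >= 0 (0-based)", call. = FALSE)
  if (!is.null(n_samples) && any(index >= n_samples))
    stop("event index out of trace bounds", call. = FALSE)
  detail <- detail %||% rep(list(list()), length(kind))
  out <- data.frame(kind = kind, index = index, time = index / fs,
                    stringsAsFactors = FALSE)
  out$detail <- detail
  class(out) <- c("detection_events", "data.frame")
  out
}

#' @export
print.detection_events <- function(x, ...) {
  cat(sprintf("<detection_events> %d event(s)\n", nrow(x)))
  if (nrow(x))
    print(data.frame(kind = x$kind, index = x$index,
                     time_s = round(x$time, 3)))
  invisible(x)
}

bind_events <- function(...) {
  pieces <- Filter(function(e) !is.null(e) && nrow(e) > 0, list(...))
  if (!length(pieces))
    return(detection_events())
  out <- do.call(rbind, lapply(pieces, function(e) {
    class(e) <- "data.frame"; e
  }))
  out <- out[order(out$index), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("detection_events", "data.frame")
  out
}

#' Write detection events to CSV
#'
#' Columns `kind,index,time_s,detail_json`; the diagnostic list is serialised
#' as JSON so the file stays flat and machine-parseable.
#'
#' @param events A `detection_events` table.
#' @param path Output path.
#' @export
write_events <- function(events, path) {
  df <- data.frame(kind = events$kind, index = events$index,
                   time_s = events$time,
                   detail_json = vapply(events$detail, function(d)
                     as.character(jsonlite::toJSON(d, auto_unbox = TRUE,
                                                   digits = NA)),
                     character(1)),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read detection events from CSV
#'
#' @param path Path written by [write_events()].
#' @param fs Sampling rate used to recompute `time` (defaults to the stored
#'   `time_s`, so `fs` is only needed for consistency checks).
#' @return A `detection_events` table.
#' @export
read_events <- function(path, fs = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  detail <- lapply(df$detail_json, function(s) jsonlite::fromJSON(s))
  out <- data.frame(kind = df$kind, index = as.integer(df$index),
                    time = df$time_s, stringsAsFactors = FALSE)
  if (!is.null(fs)) out$time <- out$index / fs
  out$detail <- detail
  class(out) <- c("detection_events", "data.frame")
  out
}
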