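#' Confusion counts
#'
#' @param tp,fp,tn,fn Non-negative integer tallies.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp = 0, fp = 0, tn = 0, fn = 0) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0) || any(v != round(v)))
    stop("counts must be non-negative integers", call. = FALSE)
  structure(lapply(as.list(v), as.integer), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d  FP %d  TN %d  FN %d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' @export
`+.confusion_counts` <- function(e1, e2) {
  confusion_counts(e1$tp + e2$tp, e1$fp + e2$fp, e1$tn + e2$tn, e1$fn + e2$fn)
}

#' Score one trace against its ground truth (trial level)
#'
#' A trial whose truth contains an alert counts as TP if any detected event of
#' the matching kind lies within `tolerance_s` of the truth time, else FN. A
#' trial without a truth alert counts as FP if any alert fired, else TN.
#' Alert kinds are `fall`, `lopp` and `co_alert`; `moving_up`/`moving_down`/
#' `co_safe` are informational and never scored as alarms.
#'
#' @param truth Data.frame with columns `kind` and `time` (or `index` plus
#'   `fs`) of ground-truth events.
#' @param events A `detection_events` table.
#' @param tolerance_s Matching tolerance in seconds (`>= 0`, default 2).
#' @param ignore_kinds Event kinds to disregard entirely (both in truth and in
#'   detections) for this trial.
#' @param fs Sampling rate, needed only if `truth` lacks a `time` column.
#' @return A `confusion_counts` with exactly one non-zero cell.
#' @export
score_trace <- function(truth, events, tolerance_s = 2,
                        ignore_kinds = character(), fs = NULL) {
  stopifnot(tolerance_s >= 0)
  if (!"time" %in% names(truth)) {
    if (is.null(fs)) stop("`truth` lacks `time`; supply `fs`", call. = FALSE)
    truth$time <- truth$index / fs
  }
  truth <- truth[truth$kind %in% setdiff(ALERT_KINDS, ignore_kinds), ,
                 drop = FALSE]
  ev <- events[events$kind %in% setdiff(ALERT_KINDS, ignore_kinds), ,
               drop = FALSE]
  if (nrow(truth)) {
    hit <- any(vapply(seq_len(nrow(truth)), function(i)
      any(ev$kind == truth$kind[i] &
            abs(ev$time - truth$time[i]) <= tolerance_s), logical(1)))
    if (hit) confusion_counts(tp = 1) else confusion_counts(fn = 1)
  } else {
    if (nrow(ev)) confusion_counts(fp = 1) else confusion_counts(tn = 1)
  }
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `Sen = TP/(TP+FN)`, `Spec = TN/(TN+FP)`, `Acc = (TP+TN)/(TP+TN+FP+FN)`,
#' as percentages. Exact values are returned; round only for reporting. A
#' zero denominator yields `NA` with a warning rather than 0.
#'
#' @param c A `confusion_counts`.
#' @return Named numeric vector `c(sen, spec, acc)` in percent.
#' @examples
#' m <- detection_metrics(confusion_counts(tp = 724, fn = 31, tn = 762))
#' round(m, 2) # 95.89, 100, 97.96
#' @export
detection_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined: zero denominator", what), call. = FALSE)
      return(NA_real_)
    }
    100 * num / den
  }
  c(sen = safe_div(c$tp, c$tp + c$fn, "sensitivity"),
    spec = safe_div(c$tn, c$tn + c$fp, "specificity"),
    acc = safe_div(c$tp + c$tn, c$tp + c$tn + c$fp + c$fn, "accuracy"))
}

#' Run and score a scenario suite
#'
#' Runs the detection pipeline over every scenario and scores each trace at
#' trial level. Quiet standing satisfies the quiescence band by definition
#' but is operationally benign, so `lopp` events are disregarded on `stand`
#' traces (standing is scored under fall specificity only); all other labels
#' score every alert kind.
#'
#' @param suite List of scenarios from [make_suite()].
#' @param config A [pipeline_config()].
#' @param tolerance_s Event-matching tolerance in seconds.
#' @return List with `pooled` (`confusion_counts`), `metrics` (percent),
#'   `per_class` (data.frame of counts by label).
#' @export
evaluate_suite <- function(suite, config = pipeline_config(),
                           tolerance_s = 2) {
  rows <- list()
  pooled <- confusion_counts()
  for (sc in suite) {
    res <- suppressWarnings(run_pipeline(sc$frame, config))
    ign <- if (sc$spec$label == "stand") "lopp" else character()
    cc <- score_trace(sc$truth, res$events, tolerance_s = tolerance_s,
                      ignore_kinds = ign)
    pooled <- pooled + cc
    rows[[length(rows) + 1L]] <-
      data.frame(label = sc$spec$label, tp = cc$tp, fp = cc$fp,
                 tn = cc$tn, fn = cc$fn)
  }
  per <- do.call(rbind, rows)
  per_class <- stats::aggregate(cbind(tp, fp, tn, fn) ~ label, per, sum)
  list(pooled = pooled, metrics = detection_metrics(pooled),
       per_class = per_class)
}
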