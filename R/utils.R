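#' Convert a duration in seconds to a sample count
#'
#' All detector windows in this package are specified in seconds and converted
#' to sample counts through this one function, so the same configuration works
#' unchanged at 100 Hz (the device rate) and 25 Hz (public-style logs).
#'
#' @param duration Duration in seconds (scalar or vector, `>= 0`).
#' @param fs Sampling rate in Hz (`> 0`).
#' @return Integer sample count(s), `round(duration * fs)`.
#' @examples
#' seconds_to_samples(3, 100)   # 300
#' seconds_to_samples(0.5, 100) # 50
#' @export
seconds_to_samples <- function(duration, fs) {
  stopifnot(is.numeric(duration), is.numeric(fs), length(fs) == 1L)
  if (any(duration < 0)) stop("`duration` must be >= 0", call. = FALSE)
  if (fs <= 0) stop("`fs` must be > 0", call. = FALSE)
  as.integer(round(duration * fs))
}

#' Standard gravity used for g-normalisation
#'
#' @keywords internal
GRAVITY_MS2 <- 9.81

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared argument check for scalar positive numbers
check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  invisible(x)
}
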