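# Fixture builders and independent brute-force oracles used across tests.

make_acc <- function(mag, fs = 100) {
  structure(list(acc = mag, fs = fs), class = "acc_magnitude")
}

make_angles <- function(n, fs = 100, theta = 0, pitch = 0, roll = 0) {
  out <- data.frame(theta = rep_len(theta, n), pitch = rep_len(pitch, n),
                    roll = rep_len(roll, n), yaw = 0)
  attr(out, "fs") <- fs
  class(out) <- c("posture_trace", "data.frame")
  out
}

make_alt <- function(h, fs = 100) {
  structure(list(h_raw = h, h_filtered = h, p0 = 1013.25, fs = fs),
            class = "altitude_trace")
}

# rest / spike / tilted-rest acceleration magnitude with matching hand-set
# angle trace; spike at `spike_s`
spike_fixture <- function(fs = 100, dur = 12, spike_s = 3,
                          theta = 60, pitch = 50, roll = 45,
                          angles_from_s = 3.5) {
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  mag <- rep(1, n)
  mag[t >= spike_s & t < spike_s + 0.1] <- 3
  th <- ifelse(t >= angles_from_s, theta, 0)
  pi_ <- ifelse(t >= angles_from_s, pitch, 0)
  ro <- ifelse(t >= angles_from_s, roll, 0)
  list(acc = make_acc(mag, fs),
       angles = {
         a <- data.frame(theta = th, pitch = pi_, roll = ro, yaw = 0)
         attr(a, "fs") <- fs
         class(a) <- c("posture_trace", "data.frame")
         a
       })
}

# Brute-force fall-cascade checker: a literal transcription of the cascade
# rules, scanning sample by sample with no shared code with detect_falls().
oracle_falls <- function(acc, angles, cfg = fall_config(),
                         algorithm = "algorithm1") {
  a <- acc$acc
  fs <- acc$fs
  n <- length(a)
  to_n <- function(s) as.integer(round(s * fs))
  d3 <- to_n(cfg$postfall_delay)
  d5 <- to_n(cfg$postfall_delay + cfg$postfall_window)
  drc <- to_n(cfg$posture_recheck)
  ok_angles <- function(i, theta = TRUE, pr = TRUE) {
    res <- TRUE
    if (theta) res <- res && (angles$theta[i] > cfg$theta_th)
    if (pr) res <- res && (abs(angles$pitch[i]) > cfg$pitch_th) &&
        (abs(angles$roll[i]) > cfg$roll_th)
    res
  }
  hits <- integer()
  i <- 1L
  repeat {
    if (i > n) break
    if (a[i] <= cfg$uth) { i <- i + 1L; next }
    confirmed <- FALSE
    if (i + d5 + drc <= n) {
      rest_ok <- TRUE
      for (k in (i + d3):(i + d5))
        if (!(a[k] > cfg$lpt && a[k] < cfg$upt)) { rest_ok <- FALSE; break }
      if (rest_ok) {
        confirmed <- switch(algorithm,
          algorithm1 = ok_angles(i + d5) && ok_angles(i + d5 + drc),
          algorithm2 = ok_angles(i + d5),
          algorithm3 = ok_angles(i + d5, theta = FALSE),
          algorithm4 = ok_angles(i + d5, pr = FALSE))
      }
    }
    if (confirmed) {
      hits <- c(hits, i - 1L)
      i <- i + to_n(cfg$refractory)
    } else {
      i <- i + d5 + drc + 1L
    }
  }
  hits
}

# Brute-force maximal quiescence runs: test every start position directly.
oracle_quiescence <- function(acc, cfg = lopp_config()) {
  a <- acc$acc
  w <- as.integer(round(cfg$window * acc$fs))
  inside <- function(i) a[i] > cfg$ll_mov && a[i] < cfg$lu_mov
  starts <- integer(); ends <- integer()
  i <- 1L
  while (i <= length(a)) {
    if (inside(i)) {
      j <- i
      while (j < length(a) && inside(j + 1L)) j <- j + 1L
      if (j - i >= w) { starts <- c(starts, i - 1L); ends <- c(ends, j - 1L) }
      i <- j + 1L
    } else i <- i + 1L
  }
  data.frame(start = starts, end = ends)
}
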