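test_that("barometric altitude matches closed-form values", {
  expect_equal(pressure_to_altitude(1013.25), 0)
  # direct evaluation of 44330*(1-(890.0651/1013.25)^(1/5.225))
  expect_equal(pressure_to_altitude(890.0651), 1086.2251, tolerance = 1e-4)
  dh <- abs(pressure_to_altitude(890.0651) - pressure_to_altitude(890.0402))
  expect_equal(round(dh, 2), 0.23)
  expect_error(pressure_to_altitude(-3), "positive")
})

test_that("altitude is strictly decreasing in pressure and zero at the reference", {
  set.seed(21)
  p <- sort(runif(50, 700, 1050))
  h <- pressure_to_altitude(p)
  expect_true(all(diff(h) < 0))
  expect_identical(pressure_to_altitude(1013.25), 0)
  # inverse formula round-trips
  expect_equal(altitude_to_pressure(h), p, tolerance = 1e-10)
})

test_that("Kalman step is a convex blend with the documented limits", {
  s <- kalman_state(x = 1, p = 2, r = 2)
  expect_equal(kalman_step(s, 5)$x, 3)          # equal uncertainties: midpoint
  s2 <- kalman_step(kalman_state(x = 4, p = 0.7), 4)
  expect_equal(s2$x, 4)                         # measurement equal to estimate
  s3 <- kalman_step(kalman_state(x = 2, p = 0), 99)
  expect_equal(s3$x, 2)                         # fully confident prior
  set.seed(5)
  for (i in 1:25) {
    st <- kalman_state(x = rnorm(1), p = runif(1, 0, 5), r = runif(1, 0.1, 5),
                       q = runif(1, 0, 0.5))
    z <- rnorm(1, sd = 3)
    out <- kalman_step(st, z)
    expect_gte(out$x, min(st$x, z))
    expect_lte(out$x, max(st$x, z))
    expect_gte(out$p, 0)
  }
})

test_that("Kalman smoothing preserves constants bit-exactly and reduces noise variance", {
  expect_identical(kalman_smooth(rep(2.5, 400)), rep(2.5, 400))
  set.seed(31)
  z <- rnorm(2000, 0, 0.3)
  f <- kalman_smooth(z)
  expect_lt(var(f), var(z))
})

test_that("Kalman step response converges monotonically and matches hand iteration", {
  z <- c(0, rep(3, 5))
  f <- kalman_smooth(z)
  # hand-iterated recurrence: x = 0, p = 1, r = 1, q = 0.01
  x <- 0; p <- 1; expected <- numeric(0)
  for (zi in z) {
    k <- p / (p + 1)
    xn <- x * (1 - k) + k * zi
    p <- (1 - k) * p + abs(x - xn) * 0.01
    x <- xn
    expected <- c(expected, x)
  }
  expect_equal(f, expected)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f <= 3))
})

test_that("altitude traces are built from frames and re-smoothable", {
  sc <- generate_scenario(scenario_spec("elevator_up", seed = 2))
  at <- altitude_trace(sc$frame)
  expect_length(at$h_filtered, length(sc$frame$ax))
  expect_gt(at$h_filtered[length(at$h_filtered)] - at$h_filtered[1], 2)
  at2 <- smooth_altitude(at, init = kalman_state(x = at$h_raw[1], p = 1))
  expect_equal(at2$h_filtered, at$h_filtered)
  fr <- sensor_frame(100, ax = 1, ay = 1, az = 1)
  expect_error(altitude_trace(fr), "pressure")
})
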