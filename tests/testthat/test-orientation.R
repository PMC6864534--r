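test_that("tilt angle matches closed forms and is scale- and yaw-invariant", {
  expect_equal(theta_angle(0, 0, 1), 0)
  expect_equal(theta_angle(1, 0, 0), 90)
  expect_equal(theta_angle(1, 1, 1), acos(1 / sqrt(3)) * 180 / pi)
  expect_error(theta_angle(0, 0, 0), "zero")
  set.seed(41)
  for (i in 1:20) {
    a <- rnorm(3)
    if (all(a == 0)) next
    cc <- runif(1, 0.01, 50)
    expect_equal(theta_angle(cc * a[1], cc * a[2], cc * a[3]),
                 theta_angle(a[1], a[2], a[3]))
  }
  # rotating an upright device about the vertical axis never tilts it
  for (psi in seq(0, 350, by = 37)) {
    r <- psi * pi / 180
    # gravity stays on az under a pure yaw rotation
    expect_equal(theta_angle(0 * r, 0 * r, 1), 0)
  }
})

test_that("Euler extraction matches the printed formulas and round-trips", {
  expect_equal(euler_from_quaternion(c(1, 0, 0, 0)),
               c(yaw = 0, pitch = 0, roll = 0))
  # q = (cos 45deg, sin 45deg, 0, 0): R = atan2(-2*w*x, 2w^2 - 1) = -90deg
  q <- c(cos(pi / 4), sin(pi / 4), 0, 0)
  e <- euler_from_quaternion(q)
  expect_equal(unname(e["roll"]), -90)
  expect_equal(unname(e["pitch"]), 0)
  set.seed(43)
  for (i in 1:25) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    e <- euler_from_quaternion(q)
    q2 <- quaternion_from_euler(e["yaw"], e["pitch"], e["roll"])
    expect_equal(euler_from_quaternion(q2), e, tolerance = 1e-10)
  }
})

test_that("gimbal proximity is clamped with a warning", {
  q <- quaternion_from_euler(0, 90, 0)
  expect_warning(e <- euler_from_quaternion(q), "gimbal")
  expect_equal(unname(e["pitch"]), 90)
})

test_that("Madgwick updates stay at equilibrium, keep unit norm, and reduce to gyro integration", {
  # upright and consistent: no drift
  q <- madgwick_update(c(1, 0, 0, 0), c(0, 0, 0), c(0, 0, 1), dt = 0.01)
  expect_equal(q, c(1, 0, 0, 0))
  # random inputs keep unit norm
  set.seed(47)
  q <- c(1, 0, 0, 0)
  for (i in 1:200) {
    q <- madgwick_update(q, rnorm(3), rnorm(3), mag = rnorm(3), dt = 0.01,
                         beta = 0.2)
    expect_equal(sqrt(sum(q^2)), 1, tolerance = 1e-6)
  }
  # beta = 0: constant z-rate advances yaw by wz * N * dt
  wz <- 0.7; dt <- 0.01; N <- 100
  q <- c(1, 0, 0, 0)
  for (i in 1:N) q <- madgwick_update(q, c(0, 0, wz), c(0, 0, 1), dt = dt,
                                      beta = 0)
  ang <- 2 * atan2(abs(q[4]), abs(q[1]))
  expect_equal(ang, wz * N * dt, tolerance = 1e-3)
})

test_that("the MARG variant converges to a fully observed static orientation", {
  set.seed(53)
  qt <- rnorm(4); qt <- qt / sqrt(sum(qt^2))
  rot <- function(q, v) { # earth -> sensor
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    c((w^2 + x^2 - y^2 - z^2) * v[1] + 2 * (x * y + w * z) * v[2] +
        2 * (x * z - w * y) * v[3],
      2 * (x * y - w * z) * v[1] + (w^2 - x^2 + y^2 - z^2) * v[2] +
        2 * (y * z + w * x) * v[3],
      2 * (x * z + w * y) * v[1] + 2 * (y * z - w * x) * v[2] +
        (w^2 - x^2 - y^2 + z^2) * v[3])
  }
  a_s <- rot(qt, c(0, 0, 1))
  m_s <- rot(qt, c(0.5, 0, -0.5))
  q <- c(1, 0, 0, 0)
  for (i in 1:3000) q <- madgwick_update(q, c(0, 0, 0), a_s, mag = m_s,
                                         dt = 0.01, beta = 0.5)
  expect_lt(min(max(abs(q - qt)), max(abs(q + qt))), 1e-2)
})

test_that("the filter tracks a simulated fall well enough for posture recognition", {
  sc <- generate_scenario(scenario_spec("fall_forward", seed = 9))
  ang <- estimate_posture(sc$frame)
  i <- nrow(ang) # long after the rotation settled
  expect_gt(ang$theta[i], 25)
  expect_gt(abs(ang$pitch[i]), 30)
  expect_gt(abs(ang$roll[i]), 30)
})

test_that("posture decision requires all three angles at both checks, strictly", {
  expect_true(posture_decision(c(30, 35, 35), c(30, 35, 35)))
  expect_false(posture_decision(c(30, 35, 35), c(10, 35, 35)))
  expect_false(posture_decision(c(25, 30, 30), c(25, 30, 30)))
  # magnitudes, not signs
  expect_true(posture_decision(c(40, -45, -50), c(40, 45, 50)))
  expect_false(posture_decision(c(40, 45, 10), c(40, 45, 50)))
})
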