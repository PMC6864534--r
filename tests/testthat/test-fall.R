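test_that("a canonical fall trace yields exactly one event at the impact", {
  sc <- generate_scenario(scenario_spec("fall_forward", seed = 1,
                                        noise_sd_acc = 0))
  acc <- rms_acceleration(sc$frame)
  ang <- estimate_posture(sc$frame)
  ev <- detect_falls(acc, ang)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "fall")
  expect_equal(ev$index, sc$truth$index)   # clean limit: exact agreement
})

test_that("walking never triggers and stand-up recovery is eliminated", {
  sc <- generate_scenario(scenario_spec("walk", seed = 2))
  ev <- detect_falls(rms_acceleration(sc$frame), estimate_posture(sc$frame))
  expect_equal(nrow(ev), 0L)
  rec <- generate_scenario(scenario_spec("fall_forward", seed = 2,
                                         recovery_s = 6))
  ev2 <- detect_falls(rms_acceleration(rec$frame), estimate_posture(rec$frame))
  expect_equal(nrow(ev2), 0L)
  expect_equal(nrow(rec$truth), 0L)
})

test_that("no trace without a super-threshold sample can produce an event", {
  set.seed(61)
  for (i in 1:5) {
    mag <- 1 + 0.7 * sin(2 * pi * 2 * seq(0, 10, by = 0.01)) +
      rnorm(1001, 0, 0.02)
    acc <- make_acc(pmin(mag, 1.79))
    ev <- detect_falls(acc, make_angles(length(acc$acc), theta = 60,
                                        pitch = 50, roll = 50))
    expect_equal(nrow(ev), 0L)
  }
})

test_that("raising the upper threshold only removes events", {
  fx <- spike_fixture()
  lo <- detect_falls(fx$acc, fx$angles, fall_config(uth = 1.8))
  hi <- detect_falls(fx$acc, fx$angles, fall_config(uth = 3.5))
  expect_equal(nrow(lo), 1L)
  expect_equal(nrow(hi), 0L)
  expect_true(all(hi$index %in% lo$index))
})

test_that("a trigger too close to the trace end is a warned non-fall", {
  fx <- spike_fixture(dur = 6, spike_s = 3)
  expect_warning(ev <- detect_falls(fx$acc, fx$angles), "trace end")
  expect_equal(nrow(ev), 0L)
})

test_that("the streaming cascade agrees with the brute-force checker", {
  scenarios <- list(
    generate_scenario(scenario_spec("fall_forward", seed = 71)),
    generate_scenario(scenario_spec("fall_left", seed = 72)),
    generate_scenario(scenario_spec("fall_forward", seed = 73, recovery_s = 6)),
    generate_scenario(scenario_spec("run", seed = 74)),
    generate_scenario(scenario_spec("jump", seed = 75)))
  for (sc in scenarios) {
    acc <- rms_acceleration(sc$frame)
    ang <- estimate_posture(sc$frame)
    for (alg in c("algorithm1", "algorithm2", "algorithm3", "algorithm4")) {
      got <- suppressWarnings(detect_falls(acc, ang, algorithm = alg))
      want <- suppressWarnings(oracle_falls(acc, ang, algorithm = alg))
      expect_identical(got$index, want,
                       info = paste(sc$spec$label, alg))
    }
  }
  # adversarial trace: random spikes against hand-set angles
  set.seed(77)
  for (i in 1:6) {
    n <- 2500
    mag <- pmax(0, 1 + rnorm(n, 0, 0.1))
    mag[sample(n, 6)] <- runif(6, 2, 4)
    acc <- make_acc(mag)
    ang <- make_angles(n, theta = sample(c(10, 60), 1),
                       pitch = sample(c(5, 50), 1), roll = 50)
    for (alg in c("algorithm1", "algorithm3", "algorithm4")) {
      got <- suppressWarnings(detect_falls(acc, ang, algorithm = alg))
      expect_identical(got$index,
                       suppressWarnings(oracle_falls(acc, ang, algorithm = alg)))
    }
  }
})

test_that("reduced cascade variants drop exactly the stated feature", {
  n <- 1200
  mag <- rep(1, n); mag[401:410] <- 3   # trigger at 4 s
  acc <- make_acc(mag)
  # transient posture: exceeded at j+5 s but back upright by j+5.5 s
  t <- (seq_len(n) - 1) / 100
  late <- make_angles(n)
  hold <- t >= 8.8 & t < 9.3
  late$theta[hold] <- 60; late$pitch[hold] <- 50; late$roll[hold] <- 50
  expect_equal(nrow(detect_falls(acc, late, algorithm = "algorithm1")), 0L)
  expect_equal(nrow(detect_falls(acc, late, algorithm = "algorithm2")), 1L)
  # flat tilt but strong pitch/roll: only the no-theta variant fires
  pr_only <- make_angles(n, theta = 10, pitch = 40, roll = 40)
  expect_equal(nrow(detect_falls(acc, pr_only, algorithm = "algorithm1")), 0L)
  expect_equal(nrow(detect_falls(acc, pr_only, algorithm = "algorithm3")), 1L)
  # strong tilt but flat pitch/roll: only the no-orientation variant fires
  th_only <- make_angles(n, theta = 40, pitch = 5, roll = 5)
  expect_equal(nrow(detect_falls(acc, th_only, algorithm = "algorithm1")), 0L)
  expect_equal(nrow(detect_falls(acc, th_only, algorithm = "algorithm4")), 1L)
  expect_error(ablation_variant("algorithm9"))
  # the variant constructor matches the algorithm= argument
  v2 <- ablation_variant("algorithm2")
  expect_equal(v2(acc, late)$index,
               detect_falls(acc, late, algorithm = "algorithm2")$index)
})

test_that("whenever the full cascade confirms a fall, every reduced variant does too", {
  for (rs in list(NULL, 6, 8.4, 9.0)) {
    sc <- generate_scenario(scenario_spec("fall_backward", seed = 81,
                                          recovery_s = rs))
    acc <- rms_acceleration(sc$frame)
    ang <- estimate_posture(sc$frame)
    full <- detect_falls(acc, ang, algorithm = "algorithm1")
    for (alg in c("algorithm2", "algorithm3", "algorithm4")) {
      red <- detect_falls(acc, ang, algorithm = alg)
      expect_true(all(full$index %in% red$index),
                  info = paste("recovery", paste(rs, collapse = ""), alg))
    }
  }
})
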