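test_that("RMS acceleration matches hand values and preserves length", {
  fr <- sensor_frame(fs = 100, ax = c(0, 3, 0), ay = c(0, 4, 0),
                     az = c(9.81, 0, 0))
  g <- rms_acceleration(fr)
  expect_s3_class(g, "acc_magnitude")
  expect_equal(g$acc, c(1, 5 / 9.81, 0))
  expect_length(g$acc, 3L)
  expect_equal(g$fs, 100)
})

test_that("magnitude is invariant to axis permutation and sign flips, and scales linearly", {
  set.seed(11)
  for (rep in 1:10) {
    a <- matrix(rnorm(30, sd = 5), ncol = 3)
    base <- rms_acceleration(sensor_frame(100, a[, 1], a[, 2], a[, 3]))$acc
    perm <- sample(3)
    sgn <- sample(c(-1, 1), 3, replace = TRUE)
    b <- sweep(a[, perm, drop = FALSE], 2, sgn, `*`)
    expect_equal(rms_acceleration(sensor_frame(100, b[, 1], b[, 2], b[, 3]))$acc,
                 base)
    cc <- runif(1, 0.1, 4)
    expect_equal(rms_acceleration(sensor_frame(100, cc * a[, 1], cc * a[, 2],
                                               cc * a[, 3]))$acc,
                 cc * base)
  }
})

test_that("seconds-to-samples conversion works at both device rates", {
  expect_identical(seconds_to_samples(3, 100), 300L)
  expect_identical(seconds_to_samples(0.5, 100), 50L)
  expect_identical(seconds_to_samples(4, 25), 100L)
  expect_error(seconds_to_samples(-1, 100), "duration")
  expect_error(seconds_to_samples(1, 0), "fs")
})

test_that("frame validation enforces uniform grid, channel lengths and units", {
  expect_error(sensor_frame(100, ax = 1:5, ay = 1:5, az = 1:4), "length")
  expect_error(sensor_frame(100, ax = 1:3, ay = 1:3, az = 1:3,
                            t = c(0, 0.01, 0.05)), "uniform")
  expect_error(sensor_frame(100, ax = 1, ay = 1, az = 1, pressure = -2),
               "positive")
  expect_error(sensor_frame(100, ax = 1, ay = 1, az = 1, co = -1),
               "non-negative")
  # g-declared input is converted to m/s2 at ingest
  fr <- sensor_frame(100, ax = 0, ay = 0, az = 1, acc_units = "g")
  expect_equal(fr$az, 9.81)
  expect_equal(rms_acceleration(fr)$acc, 1)
})

test_that("the pre-filter hook is applied at ingest", {
  clamp <- function(fr) { fr$az <- pmin(fr$az, 10); fr }
  fr <- sensor_frame(100, ax = c(0, 0), ay = c(0, 0), az = c(9.81, 50),
                     prefilter = clamp)
  expect_equal(fr$az, c(9.81, 10))
})

test_that("CSV logs round-trip and missing channels stay missing", {
  sc <- generate_scenario(scenario_spec("walk", seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sensor_csv(sc$frame, path)
  back <- read_sensor_csv(path)
  expect_equal(back$fs, sc$frame$fs)
  expect_equal(back$ax, sc$frame$ax, tolerance = 1e-12)
  expect_equal(back$pressure, sc$frame$pressure, tolerance = 1e-12)
  expect_null(back$co)
  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(read_sensor_csv(empty))
})

test_that("resampling reproduces a smooth signal at the target rate", {
  t <- seq(0, 2, by = 0.01)
  fr <- sensor_frame(100, ax = sin(2 * pi * t), ay = 0 * t, az = cos(2 * pi * t))
  lo <- resample_frame(fr, 25)
  expect_equal(lo$fs, 25)
  expect_equal(lo$ax, sin(2 * pi * lo$t), tolerance = 5e-3)
})
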