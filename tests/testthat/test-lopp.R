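test_that("quiescence windows match the stated examples", {
  # 5 s of rest inside the band: one maximal run from sample 0
  qa <- quiescence_windows(make_acc(rep(1, 500)))
  expect_equal(qa, data.frame(start = 0L, end = 499L))
  # running oscillation violates the band every stride
  t <- seq(0, 10, by = 0.01)
  qb <- quiescence_windows(make_acc(1 + 1.05 * sin(2 * pi * 3 * t)))
  expect_equal(nrow(qb), 0L)
  # a single spike resets the run: quiescence only accumulates after it
  mag <- rep(1, 1000); mag[201] <- 1.5
  qc <- quiescence_windows(make_acc(mag))
  expect_equal(qc$start, 201L)
  expect_equal(qc$end, 999L)
})

test_that("window extraction agrees with the brute-force scan and widening is monotone", {
  set.seed(91)
  for (i in 1:8) {
    mag <- pmax(0.05, 1 + rnorm(1500, 0, 0.25))
    acc <- make_acc(mag)
    cfg <- lopp_config()
    expect_identical(quiescence_windows(acc, cfg), oracle_quiescence(acc, cfg))
    wide <- lopp_config(lu_mov = 1.5, ll_mov = 0.5)
    nar <- quiescence_windows(acc, cfg)
    wid <- quiescence_windows(acc, wide)
    # every narrow-band run is contained in some wide-band run
    for (r in seq_len(nrow(nar)))
      expect_true(any(wid$start <= nar$start[r] & wid$end >= nar$end[r]))
  }
})

test_that("altitude change classifies elevator direction versus incapacitation", {
  fs <- 100; n <- 1000
  flat <- make_alt(rep(5, n), fs)
  up <- make_alt(seq(0, 7.5, length.out = n), fs)     # +3 m over 4 s
  expect_equal(as.character(classify_state(0, flat)), "lopp")
  expect_equal(as.character(classify_state(0, up)), "moving_up")
  down <- make_alt(-seq(0, 7.5, length.out = n), fs)
  expect_equal(as.character(classify_state(0, down)), "moving_down")
  expect_error(classify_state(700, flat), "cover")
  # antisymmetry under altitude negation
  set.seed(93)
  for (i in 1:10) {
    h <- cumsum(rnorm(n, 0, 0.05))
    a <- make_alt(h, fs); b <- make_alt(-h, fs)
    ca <- as.character(classify_state(0, a)); cb <- as.character(classify_state(0, b))
    expect_equal(cb, switch(ca, moving_up = "moving_down",
                            moving_down = "moving_up", lopp = "lopp"))
  }
})

test_that("quiescence accidents alert and elevator rides never do", {
  sc <- generate_scenario(scenario_spec("crawl_then_fall", seed = 4))
  acc <- rms_acceleration(sc$frame)
  ev <- detect_lopp(acc, altitude_trace(sc$frame))
  expect_equal(ev$kind, "lopp")
  expect_equal(nrow(ev), 1L)
  for (seed in c(1, 17, 23)) for (lab in c("elevator_up", "elevator_down")) {
    el <- generate_scenario(scenario_spec(lab, seed = seed))
    eev <- detect_lopp(rms_acceleration(el$frame), altitude_trace(el$frame))
    expect_false(any(eev$kind == "lopp"), info = paste(lab, seed))
    expect_true(any(eev$kind == sub("elevator", "moving", lab)))
  }
  # no quiescence at all: empty event list
  t <- seq(0, 10, by = 0.01)
  expect_equal(nrow(detect_lopp(make_acc(1 + 0.9 * sin(2 * pi * 3 * t)),
                                make_alt(rep(0, length(t))))), 0L)
})

test_that("a missing barometer degrades but does not silence the alert", {
  sc <- generate_scenario(scenario_spec("stuck_narrow_path", seed = 5))
  acc <- rms_acceleration(sc$frame)
  expect_warning(ev <- detect_lopp(acc, NULL), "degraded")
  expect_equal(ev$kind, "lopp")
  expect_true(ev$detail[[1]]$degraded)
})
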