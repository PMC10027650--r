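test_that("expression intensities are clamped to [0, 5] and neutral is all zeros", {
  e <- expression_state(AU12 = 7, AU45 = -2)
  expect_equal(unname(e[["AU12"]]), 5)
  expect_equal(unname(e[["AU45"]]), 0)
  expect_true(all(expression_state() == 0))
  expect_error(expression_state(AU99 = 1), "unknown action unit")
})

test_that("the calibration script holds frontal 1.5 s then yaw +25 for 0.5 s", {
  scr <- make_calibration_script()
  expect_equal(scr$period_s, 2.0)
  expect_true(scr$loop)
  expect_equal(script_state_at(scr, 0)$pose[["ry"]], 0)
  expect_equal(script_state_at(scr, 1.49)$pose[["ry"]], 0)
  expect_equal(script_state_at(scr, 1.5)$pose[["ry"]], 25)
  expect_equal(script_state_at(scr, 1.99)$pose[["ry"]], 25)
  # abrupt turn: no intermediate yaw value anywhere in a dense sweep
  yaws <- vapply(seq(0, 2, by = 1e-3), function(t) script_state_at(scr, t)$pose[["ry"]],
                 numeric(1))
  expect_true(all(yaws %in% c(0, 25)))
})

test_that("rest scripts modulate tz/AU25 sinusoidally and keep the face at rest", {
  rs <- make_rest_script(duration_s = 8, breathing_amplitude = 0.5,
                         breathing_period_s = 4)
  s <- sample_states(rs, fps = 30, n_frames = 240)
  t <- (0:239) / 30
  fit <- stats::lm(s$tz ~ sin(2 * pi * t / 4) + cos(2 * pi * t / 4))
  amp <- sqrt(sum(stats::coef(fit)[2:3]^2))
  expect_equal(amp, 0.5, tolerance = 0.02)         # peak-to-peak 2 * 0.5
  expect_lt(max(abs(s$ry)), 1e-12)                 # yaw stays at rest
  expect_true(all(s$AU25 >= 0 & s$AU25 <= 0.5 + 1e-9))

  flat <- sample_states(make_rest_script(8, breathing_amplitude = 0), 30, 100)
  expect_true(all(flat$tz == 0) && all(flat$AU25 == 0))
  expect_error(make_rest_script(8, breathing_amplitude = -1), "non-negative")
})

test_that("sampling the calibration script at 120 fps yields the printed hold pattern", {
  tr <- sample_states(make_calibration_script(), fps = 120, n_frames = 240)
  expect_equal(tr$ry[1:180], rep(0, 180))
  expect_equal(tr$ry[181:240], rep(25, 60))
  expect_equal(tr$capture_time_ms, (0:239) * 1000 / 120)
})

test_that("sampling is deterministic per seed and noise has the requested SD", {
  scr <- make_calibration_script()
  a <- sample_states(scr, 120, 500, noise_sd = 0.1, seed = 42)
  b <- sample_states(scr, 120, 500, noise_sd = 0.1, seed = 42)
  expect_identical(a, b)
  big <- sample_states(scr, 120, 10000, noise_sd = 0.1, seed = 1)
  resid <- big$tx   # true tx is 0 throughout
  expect_equal(stats::sd(resid), 0.1, tolerance = 0.02)
})

test_that("looped scripts are periodic under noiseless sampling", {
  scr <- make_calibration_script()
  for (t in c(0.2, 1.3, 1.7)) {
    expect_equal(script_state_at(scr, t)$pose, script_state_at(scr, t + 2)$pose)
    expect_equal(script_state_at(scr, t)$pose, script_state_at(scr, t + 10)$pose)
  }
  # unlooped scripts hold the final state beyond their end
  once <- motion_script(list(script_segment(1, face_state(pose = head_pose(ry = 10)))))
  expect_equal(script_state_at(once, 5)$pose[["ry"]], 10)
})

test_that("track CSV io round-trips, tolerates shuffled columns, rejects missing ones", {
  tr <- sample_states(make_calibration_script(), 60, 100, noise_sd = 0.3, seed = 9)
  f <- withr::local_tempfile(fileext = ".csv")
  write_track(tr, f)
  back <- read_track(f)
  for (col in setdiff(names(tr), c("frame", "valid")))
    expect_equal(back[[col]], tr[[col]], tolerance = 1e-6)

  shuffled <- utils::read.csv(f)
  shuffled <- shuffled[rev(names(shuffled))]
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(shuffled, f2, row.names = FALSE)
  expect_equal(read_track(f2)$ry, tr$ry, tolerance = 1e-6)

  broken <- utils::read.csv(f)
  broken$ry <- NULL
  f3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(broken, f3, row.names = FALSE)
  expect_error(read_track(f3), class = "mirror_format_error")
})

test_that("camera intrinsics validate focal lengths and principal point", {
  expect_silent(camera_intrinsics())
  expect_error(camera_intrinsics(fx = -1), "positive")
  expect_error(camera_intrinsics(cx = 900), "inside the image")
})

test_that("face states round-trip through namespaced data maps", {
  set.seed(11)
  for (i in 1:20) {
    st <- random_face_state()
    back <- data_to_state(state_to_data(st))
    expect_equal(back$pose, st$pose)
    expect_equal(back$expression, st$expression)
    expect_equal(back$confidence, st$confidence)
  }
})
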