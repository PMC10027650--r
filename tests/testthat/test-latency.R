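test_that("preprocessing standardizes to mean 0, SD 1 and rejects constants", {
  set.seed(5)
  tr <- pose_track(stats::rnorm(500, 10, 3), 120)
  z <- preprocess_track(tr, smooth_window = 1)
  expect_equal(mean(z$samples), 0, tolerance = 1e-9)
  expect_equal(stats::sd(z$samples), 1, tolerance = 1e-9)
  expect_error(preprocess_track(pose_track(rep(2, 100), 120)), "constant")
})

test_that("smoothing is a centered moving average (impulse response oracle)", {
  x <- c(rep(0, 50), 1, rep(0, 49))
  tr <- pose_track(x, 120)
  sm <- preprocess_track(tr, smooth_window = 5)
  # direct convolution oracle on the standardized impulse
  z <- (x - mean(x)) / stats::sd(x)
  expected <- as.numeric(stats::filter(z, rep(1 / 5, 5), sides = 2))
  core <- 3:98  # full windows only
  expect_equal(sm$samples[core], expected[core])
  # the five frames around the impulse share one value: peak spread over 1/5
  expect_equal(length(unique(round(sm$samples[49:53], 9))), 1)
})

test_that("a mimic identical to the reference yields shift 0 with SD 0", {
  y <- calibration_yaw(10)
  est <- estimate_frame_shift(pose_track(y, 120), pose_track(y, 120), n_sub = 10)
  expect_equal(est$mean_shift, 0)
  expect_equal(est$sd_shift, 0)
})

test_that("a 24-frame roll is recovered exactly and matches brute force", {
  y <- calibration_yaw(30)
  ref <- pose_track(y, 120)
  mim <- pose_track(roll(y, 24), 120)
  est <- estimate_frame_shift(ref, mim, n_sub = 50, seed = 3)
  expect_equal(est$mean_shift, 24)
  expect_equal(est$sd_shift, 0)
  # independent brute-force argmax over all admissible lags, same windows
  zr <- preprocess_track(ref)$samples
  zm <- preprocess_track(mim)$samples
  for (s in c(1, 500, 1500)) {
    expect_equal(brute_force_shift(zr, zm, s, L = 360, period_f = 240), 24)
  }
})

test_that("periodic shifts are identified modulo the period for shifts across 3 periods", {
  y <- calibration_yaw(30)
  ref <- pose_track(y, 120)
  set.seed(77)
  ks <- sort(sample(0:719, 36))
  for (k in ks) {
    est <- estimate_frame_shift(ref, pose_track(roll(y, k), 120),
                                n_sub = 8, seed = 1)
    expect_equal(est$mean_shift, k %% 240, info = paste("shift", k))
    expect_equal(est$sd_shift, 0, info = paste("shift", k))
  }
})

test_that("estimation requires matching fps and long-enough tracks", {
  y <- calibration_yaw(10)
  expect_error(estimate_frame_shift(pose_track(y, 120), pose_track(y, 60)),
               "equal fps")
  short <- pose_track(y[1:300], 120)
  expect_error(estimate_frame_shift(short, short), "too short")
})

test_that("noisy tracks are recovered to within one frame", {
  y <- calibration_yaw(30)
  n <- length(y)
  zr <- preprocess_track(pose_track(y, 120), smooth_window = 1)$samples
  set.seed(55)
  hits <- 0L
  for (rep in 1:20) {
    noisy <- zr + stats::rnorm(n, 0, 0.1)
    mim <- pose_track(roll(noisy, 24), 120)
    est <- estimate_frame_shift(pose_track(zr, 120), mim, n_sub = 50,
                                seed = rep, preprocess = FALSE)
    if (abs(est$mean_shift - 24) <= 1) hits <- hits + 1L
  }
  expect_gte(hits, 19)
})

test_that("averaging over sub-sequences shrinks the spread of the estimate", {
  y <- calibration_yaw(30)
  zr <- preprocess_track(pose_track(y, 120), smooth_window = 1)$samples
  set.seed(66)
  single <- c(); averaged <- c()
  for (rep in 1:15) {
    mim <- pose_track(roll(zr + stats::rnorm(length(zr), 0, 0.3), 24), 120)
    e1 <- estimate_frame_shift(pose_track(zr, 120), mim, n_sub = 1,
                               seed = rep, preprocess = FALSE)
    e50 <- estimate_frame_shift(pose_track(zr, 120), mim, n_sub = 50,
                                seed = rep, preprocess = FALSE)
    single <- c(single, e1$mean_shift)
    averaged <- c(averaged, e50$mean_shift)
  }
  expect_lte(stats::sd(averaged), stats::sd(single))
})

test_that("frame shifts convert to milliseconds as shift * 1000 / fps", {
  expect_equal(frames_to_ms(0, 120), 0)
  expect_equal(frames_to_ms(24, 120), 200)
  expect_equal(frames_to_ms(19.3, 120), 160.8333, tolerance = 1e-4)
  expect_error(frames_to_ms(10, 0))
})

test_that("an injected 200 ms pipeline delay is recovered end to end", {
  spec <- parse_pipeline_spec(
    "synth_source script=calibration fps=120\ndelay delay_ms=200\nrender width=64 height=64\nsink")
  rep <- calibrate_end_to_end(spec, duration_s = 20, fps = 120, n_sub = 25, seed = 2)
  expect_lte(abs(rep$end_to_end_ms - 200), 1000 / 120)
  # report invariant: ms = mean(shifts) * 1000 / fps
  expect_equal(rep$end_to_end_ms, mean(rep$shifts) * 1000 / rep$fps)
})

test_that("a zero-delay passthrough pipeline measures at most one frame interval", {
  spec <- parse_pipeline_spec(
    "synth_source script=calibration fps=120\nrender width=64 height=64\nsink")
  rep <- calibrate_end_to_end(spec, duration_s = 20, fps = 120, n_sub = 25, seed = 2)
  expect_lte(rep$end_to_end_ms, 1000 / 120)
})

test_that("doubling the recorder fps leaves the estimate within one frame interval", {
  for (fps in c(120, 240)) {
    scr <- make_calibration_script()
    y <- sample_states(scr, fps, as.integer(20 * fps))$ry
    k <- as.integer(round(0.2 * fps))  # 200 ms in frames at this fps
    est <- estimate_frame_shift(pose_track(y, fps), pose_track(roll(y, k), fps),
                                n_sub = 10, seed = 4)
    expect_lte(abs(frames_to_ms(est$mean_shift, fps) - 200), 1000 / fps)
  }
})
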