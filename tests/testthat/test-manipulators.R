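test_that("zero delay is the identity and a step input is delayed by d", {
  tr <- sample_states(make_calibration_script(), fps = 120, n_frames = 600)
  out0 <- delay_stream(tr, 0)
  expect_true(all(!out0$flagged))
  expect_equal(out0$ry, tr$ry)
  expect_true(all(out0$age_ms == 0))

  # yaw steps 0 -> 25 at t = 1500 ms; with d = 2000 the output steps at 3500 ms
  out <- delay_stream(tr, 2000)
  step_time <- min(out$emit_time_ms[!out$flagged & out$ry == 25])
  expect_lte(abs(step_time - 3500), 1000 / 120 + 1e-6)
})

test_that("delay contract: age >= d always and <= d + one frame interval in steady state", {
  tr <- sample_states(make_calibration_script(), fps = 120, n_frames = 720)
  for (d in c(0, 500, 2000)) {
    out <- delay_stream(tr, d)
    ok <- !out$flagged
    expect_true(all(out$age_ms[ok] >= d - 1e-6))
    expect_true(all(out$age_ms[ok] <= d + 1000 / 120 + 1e-6))
    # before the buffer is old enough, flagged neutral states are emitted
    if (d > 0) {
      early <- out[out$emit_time_ms < d - 1000 / 120, ]
      expect_true(all(early$flagged))
      expect_true(all(early$ry == 0))
    }
  }
})

test_that("mean emitted age of a 500 ms delayed 120 fps stream sits in [500, 508.4]", {
  tr <- sample_states(make_calibration_script(), fps = 120, n_frames = 720)
  out <- delay_stream(tr, 500)
  ages <- out$age_ms[!out$flagged]
  expect_gte(mean(ages), 500)
  expect_lte(mean(ages), 508.4)
})

test_that("AU scaling multiplies intensities, clamps at 5, leaves pose alone", {
  st <- face_state(pose = head_pose(ry = 10),
                   expression = expression_state(AU12 = 2, AU06 = 4.5))
  expect_equal(scale_expression(st, 1), st)
  s15 <- scale_expression(st, 1.5)
  expect_equal(unname(s15$expression[["AU12"]]), 3.0)
  expect_equal(s15$pose, st$pose)
  s20 <- scale_expression(st, 2)
  expect_equal(unname(s20$expression[["AU06"]]), 5.0)  # clamped
  expect_error(scale_expression(st, -0.5), "non-negative")
  # invalid states pass through untouched
  bad <- face_state(expression = expression_state(AU12 = 2), valid = FALSE)
  expect_equal(scale_expression(bad, 2), bad)
})

test_that("scaling composes multiplicatively below the clamp", {
  set.seed(21)
  for (i in 1:20) {
    au <- stats::setNames(stats::runif(length(AU_SET), 0, 1), AU_SET)
    st <- face_state(expression = au)
    s1 <- stats::runif(1, 0.5, 1.5); s2 <- stats::runif(1, 0.5, 1.5)
    if (max(au) * s1 * s2 <= 5) {
      expect_equal(scale_expression(scale_expression(st, s2), s1)$expression,
                   scale_expression(st, s1 * s2)$expression)
    }
  }
})

test_that("condition gating implements the four study conditions", {
  st <- face_state(pose = head_pose(ry = 10),
                   expression = expression_state(AU12 = 3))
  p <- condition_gate(st, "P")
  expect_equal(p$pose, st$pose)
  expect_true(all(p$expression == 0))

  e <- condition_gate(st, "E")
  expect_equal(e$pose, head_pose())          # rest pose
  expect_equal(unname(e$expression[["AU12"]]), 3)

  expect_equal(condition_gate(st, "PE"), st)

  rest <- sample_states(make_rest_script(4), 30, 120)
  b <- condition_gate(st, "B", replay_state = replay_state_at(rest, 1000))
  expect_equal(b, replay_state_at(rest, 1000))
  expect_error(condition_gate(st, "B"), class = "mirror_config_error")
})

test_that("gate algebra: PE is identity, P idempotent, P then E fully neutralizes", {
  set.seed(31)
  for (i in 1:25) {
    st <- random_face_state()
    expect_equal(condition_gate(st, "PE"), st)
    p1 <- condition_gate(st, "P")
    expect_equal(condition_gate(p1, "P"), p1)
    pe <- condition_gate(condition_gate(st, "P"), "E")
    expect_equal(pe$pose, head_pose())
    expect_true(all(pe$expression == 0))
  }
})

test_that("replay wraps around on loop, holds the last state otherwise", {
  rec <- sample_states(make_rest_script(4, breathing_amplitude = 1), 30, 120)
  dur_ms <- 120 * 1000 / 30
  expect_equal(replay_state_at(rec, dur_ms, loop = TRUE),
               track_row_state(rec, 1))
  expect_equal(replay_state_at(rec, 99999, loop = FALSE),
               track_row_state(rec, 120))
  expect_error(replay_state_at(rec[0, ], 0), "non-empty")
})

test_that("baseline replay is fully decoupled from the live stream", {
  rec <- sample_states(make_rest_script(4, breathing_amplitude = 1), 30, 120)
  quiet <- neutral_state()
  wild <- face_state(pose = head_pose(ry = 45, rx = 30),
                     expression = expression_state(values = stats::setNames(rep(5, 17), AU_SET)))
  for (t in c(0, 333, 1500, 3999)) {
    rp <- replay_state_at(rec, t)
    expect_equal(condition_gate(quiet, "B", replay_state = rp),
                 condition_gate(wild, "B", replay_state = rp))
  }
})
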