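#' Motion scripts
#'
#' A motion script is an ordered list of segments, each holding a target face
#' state for a duration (`transition = "hold"`) or ramping linearly from the
#' previous segment's end state to the target (`transition = "linear"`).
#' Looped scripts repeat with period equal to the sum of segment durations;
#' unlooped scripts hold the final state beyond their end. Scripts generate
#' the deterministic synthetic motion used in place of a webcam and tracker:
#' the periodic calibration stimulus and the baseline rest sequence.
#'
#' @param segments A list of segments created by [script_segment()].
#' @param loop Logical; repeat the script indefinitely.
#' @return Object of class `motion_script` with a `period_s` field.
#' @export
motion_script <- function(segments, loop = FALSE) {
  stopifnot(length(segments) >= 1)
  durs <- vapply(segments, function(s) s$duration_s, numeric(1))
  if (any(durs <= 0)) stop("segment durations must be positive")
  structure(
    list(segments = segments, loop = isTRUE(loop), period_s = sum(durs)),
    class = "motion_script"
  )
}

#' @rdname motion_script
#' @param duration_s Segment duration in seconds (> 0).
#' @param target Target [face_state()] at the end of the segment.
#' @param transition `"hold"` (state equals target throughout) or `"linear"`
#'   (interpolate from the previous segment's end state).
#' @export
script_segment <- function(duration_s, target, transition = c("hold", "linear")) {
  transition <- match.arg(transition)
  stopifnot(duration_s > 0, inherits(target, "face_state"))
  list(duration_s = duration_s, target = target, transition = transition)
}

#' Calibration stimulus script
#'
#' The periodic stimulus used for end-to-end latency calibration: a face held
#' frontal for 1.5 s, then abruptly turned 25 degrees to the subject's left
#' (yaw +25) and held for 0.5 s, looped. One cycle lasts 2 s; the recommended
#' analysis sub-sequence is 1.5 times that period, i.e. 3 s.
#'
#' @return A looped `motion_script` with period 2 s.
#' @export
make_calibration_script <- function() {
  motion_script(
    list(
      script_segment(1.5, neutral_state(), "hold"),
      script_segment(0.5, face_state(pose = head_pose(ry = 25)), "hold")
    ),
    loop = TRUE
  )
}

#' Rest sequence script
#'
#' A near-neutral looped script emulating a face at rest: low-amplitude
#' periodic modulation of depth (`tz`, breathing motion) and of AU25 (slight
#' lip parting), approximating a sinusoid with piecewise-linear segments.
#' `tz` oscillates around 0 with peak amplitude `breathing_amplitude`
#' (peak-to-peak twice that); AU25 is offset to `a/2 * (1 + sin)` so it stays
#' non-negative. Yaw stays exactly 0: the face remains at rest. Amplitude 0
#' yields a strictly constant neutral script.
#'
#' @param duration_s Total scripted duration (loop period), seconds.
#' @param breathing_amplitude Peak amplitude, mm for `tz` and AU units for AU25.
#' @param breathing_period_s Breathing cycle length, seconds.
#' @param segments_per_cycle Piecewise-linear resolution of the sinusoid.
#' @return A looped `motion_script`.
#' @export
make_rest_script <- function(duration_s = 60, breathing_amplitude = 0.5,
                             breathing_period_s = 4, segments_per_cycle = 24) {
  if (duration_s <= 0) stop("duration must be positive")
  if (breathing_amplitude < 0) stop("breathing amplitude must be non-negative")
  if (breathing_amplitude == 0) {
    return(motion_script(list(script_segment(duration_s, neutral_state(), "hold")),
                         loop = TRUE))
  }
  n <- max(2L, as.integer(ceiling(duration_s / breathing_period_s * segments_per_cycle)))
  dt <- duration_s / n
  a <- breathing_amplitude
  segs <- lapply(seq_len(n), function(k) {
    ph <- 2 * pi * (k * dt) / breathing_period_s
    target <- face_state(
      pose = head_pose(tz = a * sin(ph)),
      expression = expression_state(AU25 = a / 2 * (1 + sin(ph)))
    )
    script_segment(dt, target, "linear")
  })
  motion_script(segs, loop = TRUE)
}

lerp_state <- function(from, to, w) {
  face_state(
    pose = from$pose + w * (to$pose - from$pose),
    expression = clamp_au(from$expression + w * (to$expression - from$expression)),
    valid = to$valid,
    confidence = from$confidence + w * (to$confidence - from$confidence)
  )
}

#' Evaluate a motion script at a point in time
#'
#' Looped scripts are evaluated at `t mod period`; unlooped scripts hold the
#' final state beyond their end. Within a segment, `"hold"` returns the
#' target; `"linear"` interpolates from the previous segment's end state.
#' Segment boundaries belong to the following segment.
#'
#' @param script A `motion_script`.
#' @param t_s Time in seconds (>= 0).
#' @return A [face_state()].
#' @export
script_state_at <- function(script, t_s) {
  stopifnot(inherits(script, "motion_script"), t_s >= 0)
  period <- script$period_s
  if (script$loop) {
    t_s <- t_s %% period
  } else if (t_s >= period) {
    return(script$segments[[length(script$segments)]]$target)
  }
  ends <- cumsum(vapply(script$segments, function(s) s$duration_s, numeric(1)))
  i <- which(t_s < ends)[1]
  seg <- script$segments[[i]]
  if (seg$transition == "hold") return(seg$target)
  start_t <- if (i == 1) 0 else ends[i - 1]
  prev <- if (i > 1) {
    script$segments[[i - 1]]$target
  } else if (script$loop) {
    script$segments[[length(script$segments)]]$target
  } else {
    seg$target
  }
  lerp_state(prev, seg$target, (t_s - start_t) / seg$duration_s)
}

#' Sample a motion script into a timestamped face track
#'
#' Emulates a markerless tracker's output: a fixed-rate stream of head pose
#' and AU intensities, optionally perturbed by independent Gaussian jitter
#' per channel. Frame `t` (0-based) has `capture_time_ms = t * 1000 / fps`.
#' Deterministic given `seed`; with `noise_sd = 0`, sampling a hold segment
#' reproduces its target exactly.
#'
#' @param script A `motion_script`.
#' @param fps Sampling rate, Hz (> 0).
#' @param n_frames Number of frames (>= 1).
#' @param noise_sd Gaussian jitter SD; a scalar applied to all channels, or a
#'   list with elements `pose` and `au` for different SDs.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A face track: `data.frame` with columns `frame`, `capture_time_ms`,
#'   the six pose fields, the 17 AU intensities, `valid`, `confidence`.
#' @export
sample_states <- function(script, fps, n_frames, noise_sd = 0, seed = NULL) {
  stopifnot(fps > 0, n_frames >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.list(noise_sd)) {
    sd_pose <- noise_sd$pose %||% 0
    sd_au <- noise_sd$au %||% 0
  } else {
    sd_pose <- sd_au <- noise_sd
  }
  t_s <- (seq_len(n_frames) - 1) / fps
  states <- lapply(t_s, function(t) script_state_at(script, t))
  pose <- t(vapply(states, function(s) s$pose, numeric(6)))
  au <- t(vapply(states, function(s) s$expression, numeric(length(AU_SET))))
  if (sd_pose > 0)
    pose <- pose + matrix(stats::rnorm(length(pose), 0, sd_pose), nrow(pose))
  if (sd_au > 0)
    au <- clamp_au(au + matrix(stats::rnorm(length(au), 0, sd_au), nrow(au)))
  track <- data.frame(
    frame = seq_len(n_frames) - 1L,
    capture_time_ms = (seq_len(n_frames) - 1) * 1000 / fps
  )
  track[POSE_FIELDS] <- as.data.frame(pose)
  track[AU_SET] <- as.data.frame(au)
  track$valid <- vapply(states, function(s) s$valid, logical(1))
  track$confidence <- vapply(states, function(s) s$confidence, numeric(1))
  track
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract one row of a face track as a face state
#' @param track A face track (see [sample_states()]).
#' @param i Row index.
#' @return A [face_state()].
#' @export
track_row_state <- function(track, i) {
  row <- track[i, ]
  face_state(
    pose = stats::setNames(as.numeric(row[POSE_FIELDS]), POSE_FIELDS),
    expression = stats::setNames(as.numeric(row[AU_SET]), AU_SET),
    valid = isTRUE(row$valid), confidence = row$confidence
  )
}
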