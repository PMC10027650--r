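#' Yaw pose tracks
#'
#' A pose track is the yaw-angle time series extracted from a video of a
#' moving face, sampled at a known frame rate with no missing frames (gaps
#' must be filled upstream). End-to-end latency is estimated from the frame
#' shift between the track of the original (stimulus) motion and the track
#' of the avatar mimicking it.
#'
#' @param samples Numeric vector of yaw angles, degrees, one per frame (>= 2).
#' @param fps Recording frame rate, Hz (> 0).
#' @return A `pose_track`.
#' @export
pose_track <- function(samples, fps) {
  stopifnot(fps > 0, length(samples) >= 2, all(is.finite(samples)))
  structure(list(samples = as.numeric(samples), fps = fps), class = "pose_track")
}

#' Standardize and smooth a pose track
#'
#' z-transforms the samples (mean 0, SD 1) and then applies a centered moving
#' average of width `smooth_window` frames. Edge frames where the window
#' would overrun are averaged over the partial window, so the track length is
#' preserved. A constant track cannot be standardized and is an error.
#'
#' @param track A [pose_track()].
#' @param smooth_window Moving-average width in frames (odd widths are
#'   symmetric; 1 disables smoothing).
#' @return A standardized `pose_track`.
#' @export
preprocess_track <- function(track, smooth_window = 5) {
  stopifnot(inherits(track, "pose_track"), smooth_window >= 1)
  x <- track$samples
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant track")
  z <- (x - mean(x)) / s
  if (smooth_window > 1) z <- moving_average(z, as.integer(smooth_window))
  pose_track(z, track$fps)
}

# centered moving average with partial windows at the edges
moving_average <- function(x, w) {
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (w - 1L - half), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Estimate the frame shift between a stimulus and its mimic
#'
#' Implements sub-sequence cross-correlation lag estimation: `n_sub`
#' sub-sequences of length `factor` times the stimulus period are drawn
#' (uniformly at random without replacement over admissible starts, seeded),
#' and for each the integer lag in `[0, period_frames)` that maximizes the
#' Pearson correlation between the reference sub-sequence and the lag-shifted
#' mimic is recorded; the mean and SD over sub-sequences are returned.
#' Because the stimulus is periodic, lags are identified modulo the period
#' (minimal non-negative representative); ties go to the smallest lag.
#'
#' Both tracks are standardized and smoothed first (see [preprocess_track()])
#' unless `preprocess = FALSE`.
#'
#' @param reference Stimulus [pose_track()].
#' @param mimic Mimicking-avatar [pose_track()]; must have the same fps.
#' @param period_s Period of the stimulus motion, seconds.
#' @param n_sub Number of sub-sequences.
#' @param factor Sub-sequence length as a multiple of the period (default 1.5,
#'   i.e. 3 s for the 2-s calibration stimulus).
#' @param seed Integer seed for the sub-sequence sampling.
#' @param smooth_window Passed to [preprocess_track()].
#' @param preprocess Standardize/smooth the inputs first.
#' @return List with `mean_shift`, `sd_shift`, `shifts` (frames, one per
#'   sub-sequence), `period_frames`, `n_sub`, `fps`.
#' @export
estimate_frame_shift <- function(reference, mimic, period_s = 2, n_sub = 50,
                                 factor = 1.5, seed = 1, smooth_window = 5,
                                 preprocess = TRUE) {
  stopifnot(inherits(reference, "pose_track"), inherits(mimic, "pose_track"))
  if (reference$fps != mimic$fps)
    stop("reference and mimic tracks must have equal fps")
  fps <- reference$fps
  if (preprocess) {
    reference <- preprocess_track(reference, smooth_window)
    mimic <- preprocess_track(mimic, smooth_window)
  }
  ref <- reference$samples
  mim <- mimic$samples
  L <- as.integer(round(factor * period_s * fps))
  period_f <- as.integer(round(period_s * fps))
  n <- min(length(ref), length(mim))
  max_start <- n - L - period_f + 1L
  if (max_start < 1L)
    stop("tracks too short for one sub-sequence plus the lag search window")
  set.seed(as.integer(seed))
  starts <- if (max_start <= n_sub) seq_len(max_start) else
    sort(sample.int(max_start, n_sub))
  lag_offsets <- outer(0:(L - 1L), 0:(period_f - 1L), `+`)  # L x period_f
  shifts <- vapply(starts, function(s) {
    refw <- ref[s:(s + L - 1L)]
    wins <- matrix(mim[lag_offsets + s], nrow = L)
    cors <- suppressWarnings(as.numeric(stats::cor(refw, wins)))
    cors[is.na(cors)] <- -Inf
    which.max(cors) - 1L   # which.max takes the first (smallest) lag on ties
  }, numeric(1))
  list(
    mean_shift = mean(shifts),
    sd_shift = if (length(shifts) > 1) stats::sd(shifts) else 0,
    shifts = shifts,
    period_frames = period_f,
    n_sub = length(starts),
    fps = fps
  )
}

#' Convert a frame shift to milliseconds
#'
#' `shift * 1000 / fps`: at a 120-fps recording, one frame is 8.33 ms, and a
#' mean shift of 19.3 frames corresponds to 160.83 ms.
#'
#' @param shift Shift in frames (may be fractional, e.g. a mean).
#' @param fps Recording frame rate, Hz (> 0).
#' @return Milliseconds.
#' @export
frames_to_ms <- function(shift, fps) {
  stopifnot(fps > 0)
  shift * 1000 / fps
}

#' End-to-end latency calibration of a pipeline
#'
#' Simulates the video-based calibration procedure entirely in software: the
#' periodic calibration stimulus drives the pipeline, and a simulated second
#' camera records, at `fps`, both the stimulus yaw and the yaw currently
#' shown by the (possibly delayed) pipeline output. The frame shift between
#' the two tracks is then estimated by sub-sequence correlation and converted
#' to milliseconds. This covers software-side delay only; camera exposure and
#' display response of a physical setup are outside the simulation and the
#' report says so.
#'
#' @param spec A `pipeline_spec` whose source plays the calibration script
#'   (see [make_calibration_script()]) and which contains a render stage; the
#'   `delay` module provides a configured artificial delay for self-tests.
#' @param duration_s Recording duration, seconds (default 30).
#' @param fps Recorder frame rate, Hz (default 120).
#' @param n_sub Number of analysis sub-sequences (default 50).
#' @param seed Seed for sub-sequence sampling.
#' @param smooth_window Smoothing width for [preprocess_track()].
#' @param clock Clock driving the pipeline run.
#' @return A `latency_report`: per-module timing, pipeline totals, and
#'   `end_to_end_ms`, `end_to_end_sd_ms`, `shifts`, `n_sub`, `fps`.
#' @export
calibrate_end_to_end <- function(spec, duration_s = 30, fps = 120, n_sub = 50,
                                 seed = 1, smooth_window = 5,
                                 clock = sim_clock()) {
  if (is.character(spec)) spec <- parse_pipeline_spec(spec)
  stopifnot(inherits(spec, "pipeline_spec"))
  types <- vapply(spec, function(d) d$type, "")
  if (!"render" %in% types)
    spec_error("calibration requires a pipeline with a render stage")
  script <- make_calibration_script()
  period_s <- script$period_s
  n_frames <- as.integer(round(duration_s * fps))
  if (n_frames < 1.5 * period_s * fps + period_s * fps)
    stop("duration too short for one analysis sub-sequence")

  t_start <- clock_now(clock)
  report <- run_pipeline(spec, n_messages = n_frames, clock = clock)
  if (!is.null(report$failed_module))
    stop("pipeline failed in module ", report$failed_module, ": ", report$error)

  # recorder ticks use the same arithmetic as the source's emission times so
  # that simultaneous events compare equal in floating point
  rec_t <- t_start + (seq_len(n_frames) - 1) * (1000 / fps)
  # sample at k/fps, the same arithmetic the source uses, so hold-segment
  # boundaries fall on identical frames in both tracks
  stimulus <- vapply(seq_len(n_frames) - 1, function(k) {
    script_state_at(script, k / fps)$pose[["ry"]]
  }, numeric(1))
  deliv_t <- vapply(report$messages, function(m) m$delivery_time, numeric(1))
  deliv_yaw <- vapply(report$messages, function(m) m$data$pose.ry %||% 0, numeric(1))
  # the recorder sees, at each tick, the most recently delivered frame; the
  # 1 ns slack keeps simultaneous delivery/tick events on the same frame
  idx <- findInterval(rec_t + 1e-6, deliv_t)
  mimic <- ifelse(idx >= 1, deliv_yaw[pmax(idx, 1)], 0)

  shift <- estimate_frame_shift(
    pose_track(stimulus, fps), pose_track(mimic, fps),
    period_s = period_s, n_sub = n_sub, seed = seed,
    smooth_window = smooth_window
  )
  timing <- module_timing(report)
  structure(list(
    per_module = timing$per_module,
    pipeline = timing$pipeline,
    end_to_end_ms = frames_to_ms(shift$mean_shift, fps),
    end_to_end_sd_ms = frames_to_ms(shift$sd_shift, fps),
    mean_shift = shift$mean_shift,
    shifts = shift$shifts,
    n_sub = shift$n_sub,
    fps = fps,
    scope = "software delay only: camera exposure and display response are not simulated"
  ), class = "latency_report")
}

#' @export
print.latency_report <- function(x, ...) {
  cat("<latency_report>\n")
  cat(sprintf("  end-to-end: %.2f ms (SD %.2f ms) from %d sub-sequences at %g fps\n",
              x$end_to_end_ms, x$end_to_end_sd_ms, x$n_sub, x$fps))
  cat(sprintf("  pipeline processing: mean %.2f ms (SD %.2f ms)\n",
              x$pipeline[["mean_ms"]], x$pipeline[["sd_ms"]]))
  cat("  note:", x$scope, "\n")
  invisible(x)
}
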