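#' Delay buffer
#'
#' Timestamp-based buffer behind the asynchrony manipulation: states are
#' inserted with their capture time and queried as "the newest state captured
#' at or before `now - delay_ms`". No interpolation is performed, so every
#' emitted state is exactly equal to a past input. Before the buffer holds a
#' state that old, a flagged neutral state is emitted (what the avatar shows
#' while the delay line fills is undefined in the mirror's contract; neutral
#' is this package's choice). Entries older than `now - delay_ms -
#' retention_ms` are evicted.
#'
#' @param retention_ms How long entries are kept beyond the queried delay.
#' @return A `delay_buffer` with `insert(t_ms, state)` and
#'   `query(now_ms, delay_ms)` functions.
#' @export
delay_buffer <- function(retention_ms = 5000) {
  times <- numeric(0)
  states <- list()
  buf <- list(
    insert = function(t_ms, state) {
      if (length(times) && t_ms < times[length(times)])
        stop("delay buffer entries must arrive in capture-time order")
      times[length(times) + 1] <<- t_ms
      states[[length(states) + 1]] <<- state
      invisible(NULL)
    },
    query = function(now_ms, delay_ms) {
      stopifnot(delay_ms >= 0)
      # a state captured exactly delay_ms ago is old enough; the 1 ns slack
      # keeps frame-grid boundaries from flipping on floating-point error
      cutoff <- now_ms - delay_ms + 1e-6
      idx <- which(times <= cutoff)
      if (!length(idx)) {
        st <- neutral_state(valid = TRUE)
        attr(st, "delay_flagged") <- TRUE
        return(st)
      }
      i <- max(idx)
      keep <- times > cutoff - retention_ms
      keep[i] <- TRUE
      times <<- times[keep]
      states <<- states[keep]
      states[[sum(keep[seq_len(i)])]]
    },
    size = function() length(times)
  )
  class(buf) <- "delay_buffer"
  buf
}

#' Delay a face track
#'
#' Applies the delay contract offline to a whole track: at each emission time
#' the newest input state with `capture_time <= now - delay_ms` is emitted.
#' With `delay_ms = 0` this is the identity (each frame re-emits itself).
#' The emitted age `now - capture_time` is always `>= delay_ms` and, in a
#' steady-state stream, at most one frame interval more.
#'
#' @param track A face track (see [sample_states()]).
#' @param delay_ms Delay in milliseconds (>= 0).
#' @param emit_times_ms Emission times; defaults to the track's capture times.
#' @return A face track of emitted states with columns `capture_time_ms`
#'   (original capture time of the emitted state), `emit_time_ms` and
#'   `age_ms`; rows emitted before the buffer filled carry `valid = TRUE`
#'   neutral values and `flagged = TRUE`.
#' @export
delay_stream <- function(track, delay_ms, emit_times_ms = track$capture_time_ms) {
  stopifnot(delay_ms >= 0)
  buf <- delay_buffer(retention_ms = delay_ms + 10000)
  out <- vector("list", length(emit_times_ms))
  n_in <- nrow(track)
  j <- 0L
  for (k in seq_along(emit_times_ms)) {
    now <- emit_times_ms[k]
    while (j < n_in && track$capture_time_ms[j + 1L] <= now) {
      j <- j + 1L
      buf$insert(track$capture_time_ms[j], track_row_state(track, j))
    }
    st <- buf$query(now, delay_ms)
    flagged <- isTRUE(attr(st, "delay_flagged"))
    row <- c(list(emit_time_ms = now, flagged = flagged),
             as.list(st$pose), as.list(st$expression))
    row$capture_time_ms <- if (flagged) NA_real_ else source_time_of(track, st, now, delay_ms)
    out[[k]] <- as.data.frame(row)
  }
  res <- do.call(rbind, out)
  res$age_ms <- res$emit_time_ms - res$capture_time_ms
  res
}

source_time_of <- function(track, st, now, delay_ms) {
  # same boundary slack as delay_buffer$query so both pick the same frame
  idx <- which(track$capture_time_ms <= now - delay_ms + 1e-6)
  track$capture_time_ms[max(idx)]
}

#' Scale expression intensities
#'
#' Multiplies every AU intensity by `factor` and clamps to the [0, 5] range;
#' the pose is untouched. `factor = 1` is the identity; the amplification
#' manipulation used in virtual-mirror studies typically scales by 1.5.
#' Invalid states pass through unchanged.
#'
#' @param state A [face_state()].
#' @param factor Non-negative scale factor.
#' @return A [face_state()] with scaled expression.
#' @export
scale_expression <- function(state, factor) {
  if (factor < 0) stop("scale factor must be non-negative")
  if (!state$valid) return(state)
  face_state(pose = state$pose, expression = clamp_au(state$expression * factor),
             valid = state$valid, confidence = state$confidence)
}

#' Gate a face state by experimental condition
#'
#' Implements the condition table of the validation design:
#' \describe{
#'   \item{P}{tracked head pose is transferred; expression remains neutral.}
#'   \item{E}{tracked expression is transferred; pose remains at `rest_pose`.}
#'   \item{PE}{both transferred (identity).}
#'   \item{B}{baseline: the live input is ignored and the prerecorded
#'     `replay_state` is emitted, fully decoupling avatar and participant.}
#' }
#' Invalid input states pass through unchanged.
#'
#' @param state Live input [face_state()].
#' @param mode One of `"B"`, `"P"`, `"E"`, `"PE"`.
#' @param rest_pose Pose used when the pose channel is gated off (mode E).
#' @param replay_state Prerecorded state, required for mode B.
#' @return A [face_state()].
#' @export
condition_gate <- function(state, mode = c("PE", "P", "E", "B"),
                           rest_pose = head_pose(), replay_state = NULL) {
  mode <- match.arg(mode)
  if (mode == "B") {
    if (is.null(replay_state))
      config_error("condition B requires a replay source")
    return(replay_state)
  }
  if (!state$valid) return(state)
  switch(mode,
    PE = state,
    P = face_state(pose = state$pose, expression = expression_state(),
                   valid = state$valid, confidence = state$confidence),
    E = face_state(pose = rest_pose, expression = state$expression,
                   valid = state$valid, confidence = state$confidence)
  )
}

#' Replay a prerecorded track
#'
#' Returns the recorded state with the greatest capture time at or before
#' `t_ms` (modulo the recording duration when `loop = TRUE`; with
#' `loop = FALSE`, times beyond the end hold the final state). Querying a
#' looped recording exactly at its duration wraps to the first state. Used
#' for the baseline condition, which continuously replays a rest sequence.
#'
#' @param recording A face track (see [sample_states()]), non-empty.
#' @param t_ms Query time in milliseconds.
#' @param loop Whether the recording repeats.
#' @return A [face_state()].
#' @export
replay_state_at <- function(recording, t_ms, loop = TRUE) {
  n <- nrow(recording)
  if (is.null(n) || n < 1) stop("replay recording must be non-empty")
  if (loop) {
    # duration = n frames at the recording's native interval
    step <- if (n > 1) recording$capture_time_ms[2] - recording$capture_time_ms[1] else 1
    dur <- recording$capture_time_ms[n] + step
    t_ms <- t_ms %% dur
  }
  idx <- which(recording$capture_time_ms <= t_ms)
  i <- if (length(idx)) max(idx) else 1L
  track_row_state(recording, i)
}
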