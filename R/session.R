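#' Mirror sessions: the host-experiment interface
#'
#' A mirror session wraps a running virtual-mirror pipeline behind the small
#' interface a stimulus-presentation host needs: launch in the background,
#' adjust parameters live, and retrieve the newest rendered frame without
#' blocking the host's drawing loop. Parameter changes (delay, condition,
#' avatar, amplification) take effect on the next processed frame. Under a
#' simulated clock the session is advanced explicitly with
#' [session_step()]; with a real monotonic clock each step processes one
#' frame immediately, so retrieval latency never depends on pipeline load.
#'
#' @param fps Source frame rate, Hz.
#' @param width,height Rendered image size.
#' @param source_script `motion_script` driving the synthetic participant
#'   (defaults to the calibration stimulus, a convenient moving input).
#' @param rest_recording Face track replayed in condition B; defaults to a
#'   sampled rest script.
#' @param clock A [sim_clock()] (default) or [monotonic_clock()].
#' @return A `mirror_session` environment.
#' @export
mirror_session <- function(fps = 30, width = 128, height = 128,
                           source_script = make_calibration_script(),
                           rest_recording = NULL,
                           clock = sim_clock()) {
  if (is.null(rest_recording))
    rest_recording <- sample_states(make_rest_script(duration_s = 8), fps = fps,
                                    n_frames = as.integer(8 * fps))
  s <- new.env(parent = emptyenv())
  s$fps <- fps
  s$width <- width
  s$height <- height
  s$clock <- clock
  s$running <- TRUE
  s$frame <- -1L
  s$delay_ms <- 0
  s$mode <- "PE"
  s$avatar_id <- "f01"
  s$amplification <- 1
  s$script <- source_script
  s$rest <- rest_recording
  s$buffer <- delay_buffer(retention_ms = 20000)
  s$latest <- NULL
  s$events <- list()
  class(s) <- "mirror_session"
  log_event(s, "session_start", "")
  s
}

log_event <- function(session, type, payload) {
  session$events[[length(session$events) + 1]] <- data.frame(
    time_ms = clock_now(session$clock), event = type, payload = as.character(payload)
  )
  invisible(NULL)
}

state_error <- function(msg) {
  stop(errorCondition(msg, class = c("mirror_state_error", "error", "condition")))
}

#' Adjust a running session
#'
#' Convenience controls for dynamic adjustment during an experiment: delay,
#' condition mode, avatar identity and expression amplification. Commands on
#' a stopped session are state errors; unknown avatar ids are rejected with
#' the registered list. The next delivered frame reflects the new parameter,
#' and a mid-stream avatar switch never mixes two identities within one
#' frame.
#'
#' @param session A [mirror_session()].
#' @param ms,mode,avatar_id,factor New parameter values.
#' @return The session, invisibly.
#' @export
set_delay <- function(session, ms) {
  check_running(session)
  stopifnot(ms >= 0)
  session$delay_ms <- ms
  log_event(session, "set_delay", ms)
  invisible(session)
}

#' @rdname set_delay
#' @export
set_condition <- function(session, mode) {
  check_running(session)
  if (!mode %in% c("B", "P", "E", "PE")) stop("unknown condition mode: ", mode)
  session$mode <- mode
  log_event(session, "set_condition", mode)
  invisible(session)
}

#' @rdname set_delay
#' @export
set_avatar <- function(session, avatar_id) {
  check_running(session)
  get_avatar(avatar_id)  # errors with the registered list if unknown
  session$avatar_id <- avatar_id
  log_event(session, "set_avatar", avatar_id)
  invisible(session)
}

#' @rdname set_delay
#' @export
set_amplification <- function(session, factor) {
  check_running(session)
  if (factor < 0) stop("amplification factor must be non-negative")
  session$amplification <- factor
  log_event(session, "set_amplification", factor)
  invisible(session)
}

check_running <- function(session) {
  if (!isTRUE(session$running))
    state_error("session is stopped; control commands require a running session")
}

#' Advance a session by n frames
#'
#' Processes `n` source frames through the session's manipulation chain
#' (delay, amplification, condition gate) and renders the newest one,
#' advancing the session clock by one frame interval per frame. Skipping the
#' render for all but the last frame of a step mirrors the latest-wins
#' policy: the mirror shows the freshest frame.
#'
#' @param session A running [mirror_session()].
#' @param n Number of frames.
#' @param render Render the final frame (set `FALSE` for timing-only runs).
#' @return The session, invisibly.
#' @export
session_step <- function(session, n = 1, render = TRUE) {
  check_running(session)
  interval <- 1000 / session$fps
  for (i in seq_len(n)) {
    session$frame <- session$frame + 1L
    now <- clock_now(session$clock)
    st <- script_state_at(session$script, session$frame / session$fps)
    session$buffer$insert(now, st)
    out <- session$buffer$query(now, session$delay_ms)
    out <- scale_expression(out, session$amplification)
    rp <- if (session$mode == "B")
      replay_state_at(session$rest, now, loop = TRUE) else NULL
    out <- condition_gate(out, session$mode, replay_state = rp)
    if (render && i == n) {
      session$latest <- list(
        frame_id = session$frame,
        image = render_state(out, session$avatar_id,
                             width = session$width, height = session$height),
        avatar_id = session$avatar_id,
        state = out,
        time_ms = now
      )
      log_event(session, "frame", session$frame)
    }
    clock_advance(session$clock, interval)
  }
  invisible(session)
}

#' Retrieve the newest rendered frame without blocking
#'
#' Returns the most recent rendered frame, or `NULL` before the first frame
#' has been produced. Repeated calls between frames return the same frame
#' (identical `frame_id`); the call never waits on the pipeline.
#'
#' @param session A [mirror_session()].
#' @return `list(frame_id, image, avatar_id, state, time_ms)` or `NULL`.
#' @export
get_latest_image <- function(session) {
  session$latest
}

#' Stop a session
#' @param session A [mirror_session()].
#' @return The session, invisibly.
#' @export
session_stop <- function(session) {
  session$running <- FALSE
  log_event(session, "session_stop", "")
  invisible(session)
}

#' Export the session event log
#'
#' One row per parameter change and rendered frame: monotonic time, event
#' type, payload.
#'
#' @param session A [mirror_session()].
#' @param path Optional CSV path; if given, the log is written there.
#' @return The event log `data.frame`.
#' @export
session_events <- function(session, path = NULL) {
  log <- do.call(rbind, session$events)
  if (!is.null(path)) utils::write.csv(log, path, row.names = FALSE)
  log
}
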