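#' Built-in pipeline module types
#'
#' Registered on package load, these cover a basic virtual-mirror pipeline:
#' \describe{
#'   \item{`synth_source`}{script-driven face source standing in for webcam +
#'     tracker: `script=calibration|rest|neutral fps=120 noise_sd=0 seed=1`.}
#'   \item{`tracker_stub`}{pass-through occupying the tracker's slot (the
#'     synthetic source already supplies pose and AUs).}
#'   \item{`identity`}{pass-through, useful for plumbing tests.}
#'   \item{`delay`}{asynchrony buffer: `delay delay_ms=2000`.}
#'   \item{`au_scale`}{expression amplification: `au_scale factor=1.5`.}
#'   \item{`gate`}{condition gating: `gate mode=P` (`mode=B` needs
#'     `replay_file=rest.csv` or a `replay` track parameter).}
#'   \item{`replay`}{substitutes a prerecorded track for the live stream:
#'     `replay file=rest.csv loop=true`.}
#'   \item{`render`}{schematic avatar renderer: `render avatar=f01 width=640
#'     height=480`.}
#'   \item{`sink`}{terminal collector.}
#' }
#' Every type accepts `proc_ms` (number or comma-separated list) as its
#' simulated per-message processing duration.
#'
#' @name builtin-modules
NULL

source_script <- function(params) {
  s <- params$script %||% "neutral"
  if (inherits(s, "motion_script")) return(s)
  switch(s,
    calibration = make_calibration_script(),
    rest = make_rest_script(duration_s = params$rest_duration_s %||% 60),
    neutral = motion_script(list(script_segment(1, neutral_state(), "hold")), loop = TRUE),
    spec_error(sprintf("unknown source script '%s'", s))
  )
}

make_synth_source <- function(params) {
  script <- source_script(params)
  fps <- params$fps %||% 120
  noise_sd <- params$noise_sd %||% 0
  seed <- params$seed
  intr <- camera_intrinsics()
  list(
    fps = fps,
    emit = function(frame_id, now) {
      st <- script_state_at(script, frame_id / fps)
      if (noise_sd > 0) {
        if (!is.null(seed)) set.seed(as.integer(seed) + frame_id)
        st <- face_state(
          pose = st$pose + stats::rnorm(6, 0, noise_sd),
          expression = clamp_au(st$expression +
                                  stats::rnorm(length(AU_SET), 0, noise_sd)),
          valid = st$valid, confidence = st$confidence
        )
      }
      data <- state_to_data(st)
      data[paste0("camera.", names(intr))] <- as.list(intr)
      list(frame_id = frame_id, capture_time = now, image = NULL, data = data)
    }
  )
}

make_passthrough <- function(params) {
  list(process = function(msg, now) msg)
}

make_delay_module <- function(params) {
  d <- params$delay_ms %||% 2000
  if (d < 0) spec_error("delay_ms must be non-negative")
  buf <- delay_buffer(retention_ms = d + 10000)
  list(
    process = function(msg, now) {
      buf$insert(msg$capture_time, data_to_state(msg$data))
      st <- buf$query(now, d)
      timing <- msg$data[grep("^(timing|camera)\\.", names(msg$data))]
      msg$data <- c(state_to_data(st), timing)
      if (isTRUE(attr(st, "delay_flagged"))) msg$data$delay.flagged <- TRUE
      msg
    }
  )
}

make_au_scale_module <- function(params) {
  s <- params$factor %||% 1.5
  if (s < 0) spec_error("au_scale factor must be non-negative")
  list(
    process = function(msg, now) {
      st <- data_to_state(msg$data)
      if (!st$valid) {
        msg$data$manipulator.skipped <- TRUE
        return(msg)
      }
      keys <- paste0("au.", AU_SET)
      msg$data[keys] <- as.list(clamp_au(unlist(msg$data[keys]) * s))
      msg
    }
  )
}

gate_replay_track <- function(params) {
  if (!is.null(params$replay)) return(params$replay)
  if (!is.null(params$replay_file)) return(read_track(params$replay_file))
  NULL
}

make_gate_module <- function(params) {
  mode <- params$mode %||% "PE"
  if (!mode %in% c("B", "P", "E", "PE"))
    spec_error(sprintf("unknown condition mode '%s'", mode))
  replay <- gate_replay_track(params)
  if (mode == "B" && is.null(replay))
    config_error("gate mode=B requires a replay source (replay_file=... )")
  rest <- if (identical(params$rest, "neutral") || is.null(params$rest))
    head_pose() else params$rest
  list(
    process = function(msg, now) {
      st <- data_to_state(msg$data)
      rp <- if (mode == "B") replay_state_at(replay, now, loop = TRUE) else NULL
      out <- condition_gate(st, mode, rest_pose = rest, replay_state = rp)
      keep <- msg$data[grep("^(timing|camera)\\.", names(msg$data))]
      msg$data <- c(state_to_data(out), keep)
      msg
    }
  )
}

make_replay_module <- function(params) {
  track <- gate_replay_track(params) %||% params$track
  if (is.null(track) && !is.null(params$file)) track <- read_track(params$file)
  if (is.null(track) || nrow(track) < 1) spec_error("replay requires a non-empty recording")
  loop <- params$loop %||% TRUE
  list(
    process = function(msg, now) {
      st <- replay_state_at(track, now, loop = loop)
      keep <- msg$data[grep("^(timing|camera)\\.", names(msg$data))]
      msg$data <- c(state_to_data(st), keep)
      msg
    }
  )
}

make_render_module <- function(params) {
  avatar_id <- params$avatar %||% "f01"
  get_avatar(avatar_id)  # fail fast on unknown ids
  w <- params$width %||% 640
  h <- params$height %||% 480
  list(
    process = function(msg, now) {
      st <- data_to_state(msg$data)
      msg$image <- render_state(st, avatar_id, width = w, height = h)
      msg$data$avatar.id <- avatar_id
      msg
    }
  )
}

register_builtin_modules <- function() {
  register_module_type("synth_source", make_synth_source, role = "source")
  register_module_type("tracker_stub", make_passthrough)
  register_module_type("identity", make_passthrough)
  register_module_type("delay", make_delay_module)
  register_module_type("au_scale", make_au_scale_module)
  register_module_type("gate", make_gate_module)
  register_module_type("replay", make_replay_module)
  register_module_type("render", make_render_module)
  register_module_type("sink", make_passthrough, role = "sink")
}

#' Build a pipeline spec programmatically
#'
#' Equivalent to [parse_pipeline_spec()] but takes descriptors directly, so
#' parameters may be R objects (e.g. a `motion_script` for `synth_source`, or
#' a replay track for `gate mode=B`).
#'
#' @param ... Descriptors: `list(type = "delay", delay_ms = 2000)` or bare
#'   type strings.
#' @return A `pipeline_spec`.
#' @export
pipeline <- function(...) {
  raw <- list(...)
  descriptors <- lapply(seq_along(raw), function(i) {
    d <- raw[[i]]
    if (is.character(d)) d <- list(type = d)
    if (is.null(d$type)) spec_error(sprintf("descriptor %d has no type", i))
    if (!exists(d$type, envir = .registry))
      spec_error(sprintf("descriptor %d: unknown module type '%s'", i, d$type))
    params <- d[setdiff(names(d), "type")]
    list(type = d$type, params = params, line = i)
  })
  if (!length(descriptors)) spec_error("empty pipeline specification")
  if (module_role(descriptors[[1]]$type) != "source")
    spec_error(sprintf("first module '%s' is not a source", descriptors[[1]]$type))
  structure(descriptors, class = "pipeline_spec")
}

.onLoad <- function(libname, pkgname) {
  register_builtin_modules()
  register_default_avatars()
}
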