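#' The tracked action-unit set
#'
#' Intensity action units reported by common markerless face trackers,
#' tracked here as continuous intensities on the conventional 0--5 scale.
#' Neutral is all zeros.
#'
#' @format Character vector of 17 AU labels.
#' @export
AU_SET <- c(
  "AU01", "AU02", "AU04", "AU05", "AU06", "AU07", "AU09", "AU10", "AU12",
  "AU14", "AU15", "AU17", "AU20", "AU23", "AU25", "AU26", "AU45"
)

POSE_FIELDS <- c("tx", "ty", "tz", "rx", "ry", "rz")

#' Head pose
#'
#' 6-DoF rigid head pose in the camera frame. Translations `tx`, `ty`, `tz`
#' are in millimetres; rotations are intrinsic Euler angles in degrees,
#' applied pitch (`rx`), then yaw (`ry`), then roll (`rz`). Positive yaw is a
#' turn to the subject's left, so the calibration stimulus turn is `ry = 25`.
#'
#' @param tx,ty,tz Translation, mm.
#' @param rx,ry,rz Pitch, yaw, roll, degrees.
#' @return Named numeric vector of length 6.
#' @export
head_pose <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0) {
  p <- c(tx = tx, ty = ty, tz = tz, rx = rx, ry = ry, rz = rz)
  if (!all(is.finite(p))) stop("head pose must be finite")
  p
}

#' Expression state
#'
#' Per-AU intensities on [0, 5]. Values outside the range are clamped, so an
#' expression produced anywhere in the system always satisfies the bound.
#'
#' @param ... Named AU intensities (e.g. `AU12 = 2`); unnamed AUs default to 0.
#' @param values Alternatively, a named numeric vector of intensities.
#' @return Named numeric vector over [AU_SET], each value in [0, 5].
#' @export
expression_state <- function(..., values = NULL) {
  au <- stats::setNames(numeric(length(AU_SET)), AU_SET)
  given <- if (is.null(values)) unlist(list(...)) else values
  if (length(given)) {
    bad <- setdiff(names(given), AU_SET)
    if (length(bad)) stop("unknown action unit(s): ", paste(bad, collapse = ", "))
    au[names(given)] <- given
  }
  clamp_au(au)
}

clamp_au <- function(au) pmin(pmax(au, 0), 5)  # au first: pmin/pmax keep its names

#' Face state
#'
#' The quantity that is tracked, manipulated and rendered: head pose plus
#' expression, with a validity flag and tracker confidence. Manipulators must
#' pass invalid states through unchanged (and flag them).
#'
#' @param pose A [head_pose()].
#' @param expression An [expression_state()].
#' @param valid Logical; tracker success.
#' @param confidence Tracker confidence in [0, 1].
#' @return Object of class `face_state`.
#' @export
face_state <- function(pose = head_pose(), expression = expression_state(),
                       valid = TRUE, confidence = 1) {
  stopifnot(length(pose) == 6, all(names(pose) == POSE_FIELDS))
  stopifnot(length(expression) == length(AU_SET))
  stopifnot(confidence >= 0, confidence <= 1)
  structure(
    list(pose = pose, expression = clamp_au(expression),
         valid = isTRUE(valid), confidence = confidence),
    class = "face_state"
  )
}

#' @export
print.face_state <- function(x, ...) {
  cat("<face_state>", if (x$valid) "valid" else "INVALID",
      sprintf("(confidence %.2f)\n", x$confidence))
  cat("  pose:", paste(sprintf("%s=%.2f", names(x$pose), x$pose), collapse = " "), "\n")
  on <- x$expression[x$expression > 0]
  cat("  AUs :", if (length(on)) paste(sprintf("%s=%.2f", names(on), on), collapse = " ")
      else "neutral", "\n")
  invisible(x)
}

#' Neutral face state
#' @param valid Validity flag to carry.
#' @param confidence Confidence to carry.
#' @return A neutral [face_state()].
#' @export
neutral_state <- function(valid = TRUE, confidence = 1) {
  face_state(valid = valid, confidence = confidence)
}

#' Camera intrinsics
#'
#' Pinhole intrinsics carried through the pipeline (populated from
#' configuration; estimating them from images is out of scope).
#'
#' @param fx,fy Focal lengths, pixels (> 0).
#' @param cx,cy Principal point, pixels; must lie inside the image.
#' @param width,height Image size the intrinsics refer to.
#' @return Named numeric vector.
#' @export
camera_intrinsics <- function(fx = 600, fy = 600, cx = 320, cy = 240,
                              width = 640, height = 480) {
  if (fx <= 0 || fy <= 0) stop("focal lengths must be positive")
  if (cx < 0 || cx > width || cy < 0 || cy > height)
    stop("principal point must lie inside the image")
  c(fx = fx, fy = fy, cx = cx, cy = cy, width = width, height = height)
}

## ---- conversion between face states and flat data maps -------------------

#' Convert a face state to a namespaced data map and back
#'
#' Pipeline messages carry a flat key-value map with namespaced keys
#' (`pose.*`, `au.*`, ...); these helpers translate between that map and a
#' [face_state()].
#'
#' @param state A `face_state`.
#' @return `state_to_data()`: named list; `data_to_state()`: a `face_state`.
#' @export
state_to_data <- function(state) {
  d <- c(
    as.list(stats::setNames(state$pose, paste0("pose.", POSE_FIELDS))),
    as.list(stats::setNames(state$expression, paste0("au.", AU_SET)))
  )
  d$valid <- state$valid
  d$confidence <- state$confidence
  d
}

#' @rdname state_to_data
#' @param data Named list with `pose.*` and `au.*` entries.
#' @export
data_to_state <- function(data) {
  pose <- vapply(paste0("pose.", POSE_FIELDS), function(k) {
    v <- data[[k]]
    if (is.null(v)) 0 else as.numeric(v)
  }, numeric(1))
  names(pose) <- POSE_FIELDS
  au <- vapply(paste0("au.", AU_SET), function(k) {
    v <- data[[k]]
    if (is.null(v)) 0 else as.numeric(v)
  }, numeric(1))
  names(au) <- AU_SET
  face_state(pose = pose, expression = au,
             valid = if (is.null(data$valid)) TRUE else isTRUE(data$valid),
             confidence = if (is.null(data$confidence)) 1 else data$confidence)
}
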