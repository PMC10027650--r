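#' Avatar models and the schematic renderer
#'
#' A deliberately simple, fully deterministic 2D stand-in for a photoreal
#' renderer: the head is an ellipse whose position follows the head pose
#' (yaw/pitch as affine shifts, no 3D projection) and whose schematic
#' features deform monotonically with AU intensity (brows respond to
#' AU01/02/04, eyes to AU05/07/45, mouth to AU12/15/20/25/26). Rendering is
#' a pure function of (avatar, state, size): repeated calls are identical to
#' the byte. This is sufficient to drive the latency-calibration tracks and
#' every pipeline test; external photorealistic renderers plug in through
#' the same callable contract `(state, avatar_id, size) -> raster`.
#'
#' @param avatar_id Identifier used in pipeline specs and avatar switching.
#' @param skin,feature,bg RGB triplets in [0, 1].
#' @param head_width,head_height Head half-axes as fractions of image size.
#' @return An `avatar_model`.
#' @export
avatar_model <- function(avatar_id, skin = c(0.87, 0.72, 0.60),
                         feature = c(0.25, 0.15, 0.12),
                         bg = c(0.12, 0.12, 0.14),
                         head_width = 0.22, head_height = 0.32) {
  stopifnot(is.character(avatar_id), length(skin) == 3, length(feature) == 3)
  structure(list(avatar_id = avatar_id, skin = skin, feature = feature, bg = bg,
                 head_width = head_width, head_height = head_height),
            class = "avatar_model")
}

.avatars <- new.env(parent = emptyenv())

#' Avatar registry
#'
#' Four schematic identities (`"f01"`--`"f04"`, differing in skin tone and
#' proportions) are registered on load, mirroring a study pool of four
#' avatars; further models can be registered by id.
#'
#' @param avatar An `avatar_model`.
#' @export
register_avatar <- function(avatar) {
  stopifnot(inherits(avatar, "avatar_model"))
  assign(avatar$avatar_id, avatar, envir = .avatars)
  invisible(avatar$avatar_id)
}

#' @rdname register_avatar
#' @export
registered_avatars <- function() sort(ls(.avatars))

#' @rdname register_avatar
#' @param avatar_id Registered identifier.
#' @export
get_avatar <- function(avatar_id) {
  if (!exists(avatar_id, envir = .avatars))
    stop(sprintf("unknown avatar id '%s' (registered: %s)",
                 avatar_id, paste(registered_avatars(), collapse = ", ")))
  get(avatar_id, envir = .avatars)
}

register_default_avatars <- function() {
  register_avatar(avatar_model("f01", skin = c(0.87, 0.72, 0.60)))
  register_avatar(avatar_model("f02", skin = c(0.76, 0.60, 0.48), head_width = 0.20))
  register_avatar(avatar_model("f03", skin = c(0.93, 0.80, 0.69), head_height = 0.30))
  register_avatar(avatar_model("f04", skin = c(0.64, 0.48, 0.38), head_width = 0.24))
}

#' Render a face state to a raster
#'
#' Pure, deterministic rendering of a [face_state()] with the given avatar.
#' Positive yaw shifts the head toward larger x (image columns); positive
#' pitch toward larger y. An invalid state is rendered as the neutral face
#' with a red warning border.
#'
#' @param state A [face_state()].
#' @param avatar An `avatar_model` or a registered avatar id.
#' @param width,height Image size in pixels, both >= 64.
#' @return Numeric array `height x width x 3` with values in [0, 1]
#'   (quantized to 8 bits on PNG export).
#' @export
render_state <- function(state, avatar = "f01", width = 640, height = 480) {
  if (is.character(avatar)) avatar <- get_avatar(avatar)
  stopifnot(inherits(state, "face_state"), width >= 64, height >= 64)
  invalid <- !state$valid
  if (invalid) state <- neutral_state()
  au <- state$expression
  pose <- state$pose

  X <- matrix(seq_len(width), height, width, byrow = TRUE)
  Y <- matrix(seq_len(height), height, width)
  img <- array(rep(avatar$bg, each = height * width), dim = c(height, width, 3))

  # pose -> affine placement (px per degree scales with image width)
  cx <- width / 2 + pose[["ry"]] * width / 320 + pose[["tx"]] * width / 1280
  cy <- height / 2 + pose[["rx"]] * height / 320 + pose[["ty"]] * height / 960
  scale <- max(0.5, 1 - pose[["tz"]] / 2000)
  a <- avatar$head_width * width * scale
  b <- avatar$head_height * height * scale
  roll <- pose[["rz"]] * pi / 180
  # head-frame coordinates (roll rotates the whole face)
  U <- cos(roll) * (X - cx) + sin(roll) * (Y - cy)
  V <- -sin(roll) * (X - cx) + cos(roll) * (Y - cy)

  paint <- function(mask, col) {
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- col[ch]
      img[, , ch] <<- plane
    }
  }
  ellipse <- function(u0, v0, ru, rv) ((U - u0) / ru)^2 + ((V - v0) / rv)^2 <= 1

  paint(ellipse(0, 0, a, b), avatar$skin)

  # brows: AU01/02 raise, AU04 lowers and knits
  brow_v <- -0.42 * b - 0.015 * b * (au[["AU01"]] + au[["AU02"]]) + 0.02 * b * au[["AU04"]]
  brow_in <- 0.18 * a - 0.01 * a * au[["AU04"]]
  brow_out <- 0.52 * a
  brow_mask <- abs(V - brow_v) <= 0.025 * b &
    (abs(U) >= brow_in & abs(U) <= brow_out)
  paint(brow_mask, avatar$feature)

  # eyes: AU05 widens, AU07 tightens, AU45 closes
  openness <- max(0.06, (1 + 0.12 * au[["AU05"]] - 0.08 * au[["AU07"]]) *
                          (1 - 0.19 * au[["AU45"]]))
  eye_ry <- 0.075 * b * openness
  for (s in c(-1, 1)) {
    paint(ellipse(s * 0.35 * a, -0.20 * b, 0.14 * a, eye_ry), c(0.97, 0.97, 0.97))
    paint(ellipse(s * 0.35 * a, -0.20 * b, 0.05 * a, min(eye_ry, 0.035 * b)),
          c(0.05, 0.05, 0.05))
  }

  # nose (static)
  paint(ellipse(0, 0.12 * b, 0.06 * a, 0.10 * b),
        pmax(0, avatar$skin - 0.12))

  # mouth: AU12/20 widen, AU25/26 open, AU15 depresses, AU23 tightens
  mw <- a * (0.28 + 0.022 * au[["AU12"]] + 0.016 * au[["AU20"]] - 0.012 * au[["AU23"]])
  mh <- b * (0.035 + 0.034 * (au[["AU25"]] + au[["AU26"]]) + 0.006 * au[["AU10"]])
  mv <- 0.50 * b + 0.012 * b * au[["AU15"]] - 0.008 * b * au[["AU12"]]
  paint(ellipse(0, mv, max(mw, 0.02 * a), max(mh, 0.015 * b)),
        c(0.55, 0.20, 0.20))
  if (mh > 0.09 * b)  # visible teeth when the mouth opens wide
    paint(ellipse(0, mv - 0.4 * mh, max(mw, 0.02 * a) * 0.7, mh * 0.25),
          c(0.95, 0.95, 0.92))

  if (invalid) {
    bw <- max(2L, round(0.01 * width))
    border <- X <= bw | X > width - bw | Y <= bw | Y > height - bw
    paint(border, c(0.85, 0.10, 0.10))
  }
  img
}

#' Mask and centroid of the rendered head
#'
#' Pixels that differ from the avatar's background colour, and their centroid
#' in (x, y) image coordinates. Used as the measurement oracle for pose-driven
#' displacement of the rendered head.
#'
#' @param img Array from [render_state()].
#' @param avatar The `avatar_model` (or id) the image was rendered with.
#' @return `head_mask()`: logical matrix; `head_centroid()`: named vector
#'   `c(x =, y =)`.
#' @export
head_mask <- function(img, avatar = "f01") {
  if (is.character(avatar)) avatar <- get_avatar(avatar)
  d <- abs(sweep(img, 3, avatar$bg))
  apply(d, c(1, 2), max) > 1e-9
}

#' @rdname head_mask
#' @export
head_centroid <- function(img, avatar = "f01") {
  m <- head_mask(img, avatar)
  idx <- which(m, arr.ind = TRUE)
  c(x = mean(idx[, 2]), y = mean(idx[, 1]))
}

#' Write a raster to PNG
#' @param img Array `H x W x 3` in [0, 1].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}
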