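#' Camera / display model
#'
#' Describes the projection geometry linking the 3-D scene to the flat display:
#' an observer eye at `eye_height` metres above the ground plane looks straight
#' ahead at a screen `viewing_distance` metres away. Screen coordinates are
#' metres from the screen centre, x to the right and y upward; pixel
#' coordinates are a derived view used only by the rasterizer.
#'
#' The defaults reproduce the projection setup of the experiments: a
#' 2.24 x 1.85 m backlit screen at 800 x 600 pixels, 60 Hz, viewed from 1 m,
#' with the simulated camera 1.8 m above the ground plane.
#'
#' @param viewing_distance Eye-to-screen distance (m).
#' @param screen_width,screen_height Physical screen size (m).
#' @param resolution_x,resolution_y Display resolution (pixels).
#' @param frame_rate Display refresh rate (Hz).
#' @param eye_height Height of the simulated camera above the ground plane (m).
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model()
#' heading_to_foe(observer_motion(5), cam)
#' @export
camera_model <- function(viewing_distance = 1.0,
                         screen_width = 2.24, screen_height = 1.85,
                         resolution_x = 800L, resolution_y = 600L,
                         frame_rate = 60, eye_height = 1.8) {
  vals <- c(viewing_distance, screen_width, screen_height,
            resolution_x, resolution_y, frame_rate, eye_height)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all camera parameters must be positive and finite")
  structure(list(
    viewing_distance = viewing_distance,
    screen_width = screen_width, screen_height = screen_height,
    resolution_x = as.integer(resolution_x),
    resolution_y = as.integer(resolution_y),
    frame_rate = frame_rate, eye_height = eye_height
  ), class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf(
    "camera_model: %gx%g m screen at %g m, %dx%d px, %g Hz, eye %g m above ground\n",
    x$screen_width, x$screen_height, x$viewing_distance,
    x$resolution_x, x$resolution_y, x$frame_rate, x$eye_height))
  invisible(x)
}

#' Observer self-motion
#'
#' Straight-line translation over the ground plane. The heading angle is
#' measured in the horizontal plane, 0 toward the screen centre, positive to
#' the right; the gaze stays straight ahead for all headings, so the focus of
#' expansion sits at screen x = viewing_distance * tan(heading).
#'
#' @param heading_angle Signed heading (degrees); the experiments use
#'   0, +/-5 and +/-10.
#' @param speed Translation speed (m/s).
#' @return An object of class `observer_motion`.
#' @export
observer_motion <- function(heading_angle = 0, speed = 1.5) {
  if (!is.finite(heading_angle)) stop("heading_angle must be finite")
  if (!is.finite(speed) || speed <= 0) stop("speed must be positive")
  structure(list(heading_angle = heading_angle, speed = speed),
            class = "observer_motion")
}

# translation velocity in the observer frame (x right, y up, z forward), m/s
translation_vector <- function(motion) {
  h <- motion$heading_angle * pi / 180
  motion$speed * c(sin(h), 0, cos(h))
}

#' Scene point
#'
#' A point attributed to the ground plane, the sky, or the walker body.
#' Ground and walker points carry a finite 3-D position in the observer frame
#' (x right, y up, z forward, eye at the origin); sky points are directions at
#' infinite depth.
#'
#' @param position Numeric length-3 position (or direction, for sky points).
#' @param kind One of `"ground"`, `"sky"`, `"walker"`.
#' @return An object of class `scene_point`.
#' @export
scene_point <- function(position, kind = c("ground", "sky", "walker")) {
  kind <- match.arg(kind)
  position <- as.numeric(position)
  if (length(position) != 3 || !all(is.finite(position)))
    stop("position must be a finite length-3 numeric")
  structure(list(position = position, kind = kind), class = "scene_point")
}

#' Project scene points onto the screen
#'
#' Pinhole projection onto the screen plane at `viewing_distance`:
#' `(sx, sy) = viewing_distance * (X, Y) / Z`. Sky points are directions and
#' project through their direction ratios, which gives the same formula.
#'
#' @param p A `scene_point`, or an n x 3 numeric matrix of positions.
#' @param cam A [camera_model()].
#' @return For a `scene_point`, a length-2 numeric `(sx, sy)` in metres from
#'   the screen centre; for a matrix, an n x 2 matrix with `NA` rows for
#'   points at or behind the camera plane.
#' @export
project_to_screen <- function(p, cam) {
  if (inherits(p, "scene_point")) {
    s <- project_points(matrix(p$position, 1L, 3L), cam)
    if (anyNA(s)) stop("point at or behind the camera plane is not projectable")
    return(drop(s))
  }
  project_points(p, cam)
}

project_points <- function(pos, cam) {
  pos <- matrix(as.numeric(pos), ncol = 3L)
  z <- pos[, 3L]
  bad <- !(z > 0 & is.finite(z))
  sx <- cam$viewing_distance * pos[, 1L] / z
  sy <- cam$viewing_distance * pos[, 2L] / z
  sx[bad] <- NA_real_
  sy[bad] <- NA_real_
  cbind(sx = sx, sy = sy)
}

#' Back-project a screen position onto the ground plane
#'
#' Inverse of [project_to_screen()] for ground points: the ray through a
#' screen position below the horizon intersects the plane `y = -eye_height`
#' at a unique point.
#'
#' @param s Length-2 screen position (m), or an n x 2 matrix.
#' @param cam A [camera_model()].
#' @return A `scene_point` (or n x 3 matrix) on the ground plane.
#' @export
ground_point_from_screen <- function(s, cam) {
  if (is.matrix(s)) return(ground_points(s[, 1L], s[, 2L], cam))
  if (s[2] >= 0)
    stop("screen position at or above the horizon has no ground intersection")
  p <- ground_points(s[1], s[2], cam)
  scene_point(drop(p), "ground")
}

# vectorised: rows with sy >= 0 come back NA
ground_points <- function(sx, sy, cam) {
  z <- -cam$eye_height * cam$viewing_distance / sy
  z[sy >= 0] <- NA_real_
  cbind(x = sx * z / cam$viewing_distance,
        y = rep(-cam$eye_height, length(sx)),
        z = z)
}

#' Finite-step background optic flow
#'
#' Screen displacement over `dt` of a background dot under observer
#' translation. Ground dots are back-projected onto the plane, shifted by
#' `-T * dt` in the observer frame (the observer advances by `T * dt`), and
#' re-projected — an exact finite step rather than an integrated velocity
#' field, so there is no discretization drift over a trial. Sky dots are
#' infinitely far and do not move.
#'
#' @param s Length-2 screen position (m) or n x 2 matrix.
#' @param motion An [observer_motion()].
#' @param cam A [camera_model()].
#' @param dt Time step (s), typically `1 / cam$frame_rate`.
#' @param kind `"ground"` or `"sky"`, recycled to the number of rows. By
#'   default positions below the horizon are ground and the rest sky.
#' @return Displacement(s) `(dx, dy)` in screen metres; `NA` rows flag dots
#'   whose updated ground point falls at or behind the camera (off scene —
#'   the caller respawns them).
#' @export
background_flow <- function(s, motion, cam, dt, kind = NULL) {
  single <- !is.matrix(s)
  s <- matrix(as.numeric(s), ncol = 2L)
  if (is.null(kind)) kind <- ifelse(s[, 2L] < 0, "ground", "sky")
  kind <- rep_len(kind, nrow(s))
  out <- matrix(0, nrow(s), 2L, dimnames = list(NULL, c("dx", "dy")))
  g <- kind == "ground"
  if (any(g)) {
    p <- ground_points(s[g, 1L], s[g, 2L], cam)
    p2 <- sweep(p, 2L, translation_vector(motion) * dt, `-`)
    s2 <- project_points(p2, cam)
    out[g, ] <- s2 - s[g, , drop = FALSE]
  }
  if (single) drop(out) else out
}

#' Focus of expansion for a translating observer
#'
#' For pure translation with fixed gaze the flow field radiates from the
#' screen projection of the translation direction.
#'
#' @inheritParams background_flow
#' @return Length-2 screen position (m): `(viewing_distance * tan(heading), 0)`.
#' @export
heading_to_foe <- function(motion, cam) {
  if (abs(motion$heading_angle) >= 90)
    stop("|heading_angle| must be below 90 degrees")
  c(x = cam$viewing_distance * tan(motion$heading_angle * pi / 180), y = 0)
}

#' Convert a horizontal screen position to a heading angle
#'
#' Inverse of [heading_to_foe()]; used to express heading-adjustment
#' responses (screen metres) in degrees.
#'
#' @param x Horizontal screen position(s), metres from centre.
#' @param cam A [camera_model()].
#' @return Heading angle(s) in degrees.
#' @export
screen_x_to_heading <- function(x, cam) {
  if (any(abs(x) >= cam$screen_width / 2 + 1e-9))
    stop("screen position outside the display")
  atan(x / cam$viewing_distance) * 180 / pi
}
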