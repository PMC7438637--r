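#' Walker path specification
#'
#' Two paths are used in the experiments. The *equidistant* walker crosses
#' the display laterally from 1.02 m on one side of the centre to 1.02 m on
#' the other while being shifted in depth with the observer so that it keeps
#' a fixed 1.5-m distance. The *approaching* walker starts 5 m ahead on the
#' midline and walks along a 45-degree tilted path toward the observer's
#' track, facing in its walking direction.
#'
#' `direction` is the walker's facing side. Under forward articulation and
#' normal translation the walker also moves toward that side; backward
#' articulation or a moonwalk translation (see [walker_state_at()]) reverse
#' the translation while leaving facing untouched.
#'
#' @param kind `"equidistant"` or `"approaching"`.
#' @param direction `"left"` or `"right"` (facing side).
#' @param walk_speed Walking speed along the path (m/s).
#' @param start_lateral Equidistant start offset from the display centre (m).
#' @param fixed_distance Equidistant observer-frame depth (m).
#' @param start_depth Approaching start depth ahead of the observer (m).
#' @param path_angle Approaching path tilt from straight-toward-observer
#'   (degrees).
#' @return An object of class `walker_path`.
#' @export
walker_path <- function(kind = c("equidistant", "approaching"),
                        direction = c("right", "left"),
                        walk_speed = 1.2, start_lateral = 1.02,
                        fixed_distance = 1.5, start_depth = 5,
                        path_angle = 45) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  if (!is.finite(walk_speed) || walk_speed <= 0)
    stop("walk_speed must be positive")
  structure(list(kind = kind, direction = direction, walk_speed = walk_speed,
                 start_lateral = start_lateral,
                 fixed_distance = fixed_distance,
                 start_depth = start_depth, path_angle = path_angle),
            class = "walker_path")
}

#' Walker state and joint positions at a time point
#'
#' Combines path kinematics, gait articulation and the observer's own motion
#' into the walker's body centre, facing and the 18 joint positions in the
#' observer frame.
#'
#' Equidistant path: the observer-frame depth is held at `fixed_distance`
#' exactly (the walker is shifted in depth with the observer) and the lateral
#' position runs from `-s * start_lateral` at `t = 0` with velocity
#' `s * walk_speed`, where `s` is the translation sign: facing side, negated
#' under backward articulation and again under a moonwalk translation.
#' Approaching path: the walker starts `start_depth` m ahead in the world and
#' translates along the tilted path with the same sign rule; the returned
#' positions subtract the observer's displacement `T * t`.
#'
#' @param path A [walker_path()].
#' @param gait A `gait_cycle` (see [synthesize_gait()]).
#' @param t Time since stimulus onset (s).
#' @param articulation `"forward"` or `"backward"` (reversed frame order).
#' @param translation `"normal"` (matches articulation) or `"moonwalk"`
#'   (opposes it).
#' @param observer An [observer_motion()]; needed for the approaching path's
#'   observer-frame correction.
#' @param cam A [camera_model()] (for the ground height).
#' @return A list of class `walker_state`: `time`, `phase`, `facing`
#'   (degrees), `body_center` (length-3, observer frame, on the ground under
#'   the body), and `joints` (18 x 3 observer-frame positions, m).
#' @export
walker_state_at <- function(path, gait, t,
                            articulation = c("forward", "backward"),
                            translation = c("normal", "moonwalk"),
                            observer = observer_motion(0),
                            cam = camera_model()) {
  articulation <- match.arg(articulation)
  translation <- match.arg(translation)
  if (!is.finite(t) || t < 0) stop("t must be a nonnegative time")
  s_face <- if (path$direction == "right") 1 else -1
  s_art <- if (articulation == "forward") 1 else -1
  s_trans <- if (translation == "normal") 1 else -1
  s <- s_face * s_art * s_trans

  if (path$kind == "equidistant") {
    centre <- c(s * (-path$start_lateral + path$walk_speed * t),
                -cam$eye_height,
                path$fixed_distance)
    facing <- s_face * 90
  } else {
    a <- path$path_angle * pi / 180
    d <- c(s_face * sin(a), 0, -cos(a))      # facing direction along the path
    world <- c(0, -cam$eye_height, path$start_depth) +
      s_art * s_trans * path$walk_speed * t * d
    shift <- translation_vector(observer) * t
    centre <- world - c(shift[1], 0, shift[3])
    facing <- atan2(d[1], d[3]) * 180 / pi
  }

  phase <- (t / gait$period) %% 1
  pose <- gait_pose(gait, phase, articulation)
  th <- facing * pi / 180
  fwd <- c(sin(th), 0, cos(th))
  lft <- c(cos(th), 0, -sin(th))
  up <- c(0, 1, 0)
  joints <- matrix(centre, 18L, 3L, byrow = TRUE) +
    pose[, 1L] %o% fwd + pose[, 2L] %o% lft + pose[, 3L] %o% up
  rownames(joints) <- gait$joints
  structure(list(time = t, phase = phase, facing = facing,
                 articulation = articulation, translation = translation,
                 body_center = centre, joints = joints),
            class = "walker_state")
}

#' @export
print.walker_state <- function(x, ...) {
  cat(sprintf(
    "walker_state: t=%.3f s, phase %.3f, facing %g deg, centre (%.3f, %.3f, %.3f) m\n",
    x$time, x$phase, x$facing, x$body_center[1], x$body_center[2],
    x$body_center[3]))
  invisible(x)
}

#' Walker-body membership of screen positions
#'
#' The walker body is the union of 18 disks of `radius` metres, one per
#' joint. A screen position is inside iff the ray through it, intersected
#' with the fronto-parallel plane at the walker's body-centre depth, lies
#' within `radius` of a joint centre (joint x/y, depth ignored — the radius
#' is specified in world metres on the walker's plane, so membership is
#' exact regardless of the walker's distance).
#'
#' @param s n x 2 matrix (or length-2 vector) of screen positions (m).
#' @param state A `walker_state` for the same frame.
#' @param cam A [camera_model()].
#' @param radius Disk radius (m).
#' @return A list: `inside` (logical n), `joint` (nearest member joint index,
#'   `NA` outside), `height` (intersection height above ground, m, `NA`
#'   outside), and `plane_xy` (n x 2 intersection coordinates on the walker
#'   plane).
#' @export
body_membership <- function(s, state, cam, radius = 0.02) {
  s <- matrix(as.numeric(s), ncol = 2L)
  zw <- state$body_center[3]
  px <- s[, 1L] * zw / cam$viewing_distance
  py <- s[, 2L] * zw / cam$viewing_distance
  jx <- state$joints[, 1L]
  jy <- state$joints[, 2L]
  d2 <- outer(px, jx, `-`)^2 + outer(py, jy, `-`)^2
  j <- max.col(-d2, ties.method = "first")
  dmin <- d2[cbind(seq_along(j), j)]
  inside <- dmin <= radius^2
  j[!inside] <- NA_integer_
  height <- py + cam$eye_height
  height[!inside] <- NA_real_
  list(inside = inside, joint = j, height = height,
       plane_xy = cbind(px, py))
}
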