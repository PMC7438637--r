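# Shared fixtures: everything is built in code at test time.

default_cam <- camera_model()

# a cheap low-density configuration for engine mechanics tests
quick_config <- function(condition = "none", path_kind = "equidistant",
                         direction = "right", heading = 0, seed = 1L,
                         density = 0.3, ...) {
  path <- if (condition == "none") NULL else walker_path(path_kind, direction)
  stimulus_config(observer = observer_motion(heading),
                  path = path, condition = condition,
                  density = density, seed = seed, ...)
}

shared_gait <- synthesize_gait()

# displacement of a static point at depth z along the ray through screen s
static_point_flow <- function(s, z, motion, cam, dt) {
  p <- c(s[1] * z / cam$viewing_distance,
         s[2] * z / cam$viewing_distance, z)
  p2 <- p - flowwalker:::translation_vector(motion) * dt
  project_to_screen(scene_point(p2, "walker"), cam) - s
}

# analytic image-velocity field for observer translation (ground plane)
analytic_ground_velocity <- function(s, motion, cam) {
  vd <- cam$viewing_distance
  z <- -cam$eye_height * vd / s[2]
  T <- flowwalker:::translation_vector(motion)
  c((s[1] * T[3] - vd * T[1]) / z,
    (s[2] * T[3] - vd * T[2]) / z)
}
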