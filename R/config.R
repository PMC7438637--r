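#' Write a stimulus configuration to a YAML file
#'
#' @param cfg A [stimulus_config()].
#' @param file Output path.
#' @export
write_stimulus_config <- function(cfg, file) {
  x <- list(
    camera = cfg$camera[c("viewing_distance", "screen_width",
                          "screen_height", "resolution_x", "resolution_y",
                          "frame_rate", "eye_height")],
    observer = cfg$observer[c("heading_angle", "speed")],
    condition = cfg$condition,
    articulation = cfg$articulation,
    translation = cfg$translation,
    duration = cfg$duration,
    replace_prob = cfg$replace_prob,
    density = cfg$density,
    area_convention = cfg$area_convention,
    disk_radius = cfg$disk_radius,
    seed = cfg$seed)
  if (!is.null(cfg$path))
    x$path <- cfg$path[c("kind", "direction", "walk_speed", "start_lateral",
                         "fixed_distance", "start_depth", "path_angle")]
  yaml::write_yaml(x, file)
  invisible(file)
}

#' Read a stimulus configuration from a YAML file
#'
#' Keys follow the field names of [stimulus_config()], [camera_model()],
#' [observer_motion()] and [walker_path()]; absent keys take the package
#' defaults.
#'
#' @param file Path to a YAML configuration.
#' @return A [stimulus_config()].
#' @export
read_stimulus_config <- function(file) {
  x <- yaml::read_yaml(file)
  cam <- do.call(camera_model, x$camera %||% list())
  obs <- do.call(observer_motion, x$observer %||% list())
  path <- if (!is.null(x$path)) do.call(walker_path, x$path) else NULL
  args <- x[setdiff(names(x), c("camera", "observer", "path"))]
  do.call(stimulus_config,
          c(list(camera = cam, observer = obs, path = path), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
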