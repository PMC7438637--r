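#' Stimulus configuration
#'
#' Everything needed to generate one trial's dot stimulus: geometry, observer
#' motion, walker path and local-flow condition, duration, dot density and
#' the limited-lifetime replacement probability.
#'
#' The three walker conditions prescribe the motion of dots inside the body
#' silhouette: `congruent_with_walker` locks dots to the joint disks so they
#' move with the walker; `incongruent_with_walker` moves them with the
#' walker's velocity but with the lateral component negated (for the
#' equidistant walker going right the inside dots simply drift left);
#' `congruent_with_flow` treats each inside dot as a static scene point at
#' the walker's depth and the dot's height above ground, so its direction
#' matches the background flow while its speed exceeds the more distant
#' background. `none` admits no walker.
#'
#' @param camera A [camera_model()].
#' @param observer An [observer_motion()].
#' @param path A [walker_path()], or `NULL` for the no-walker condition.
#' @param condition Local-flow condition (see Details).
#' @param articulation,translation Walker articulation (`"forward"` /
#'   `"backward"`) and translation mode (`"normal"` / `"moonwalk"`).
#' @param duration Stimulus duration (s); must be a whole number of frames.
#' @param replace_prob Per-frame probability that a dot is replaced at a
#'   random position (limited lifetime).
#' @param density Dot density (dots per square degree).
#' @param area_convention How the total angular screen area is measured:
#'   `"product"` multiplies the horizontal and vertical angular extents;
#'   `"solid_angle"` uses the exact solid angle of the screen rectangle.
#' @param disk_radius Radius of each joint disk (m).
#' @param seed Master seed; init, lifetime and respawn use derived
#'   substreams.
#' @return An object of class `stimulus_config`.
#' @export
stimulus_config <- function(camera = camera_model(),
                            observer = observer_motion(),
                            path = NULL,
                            condition = c("none", "congruent_with_walker",
                                          "incongruent_with_walker",
                                          "congruent_with_flow"),
                            articulation = c("forward", "backward"),
                            translation = c("normal", "moonwalk"),
                            duration = 1.7, replace_prob = 0.15,
                            density = 1.4694,
                            area_convention = c("product", "solid_angle"),
                            disk_radius = 0.02, seed = 1L) {
  condition <- match.arg(condition)
  articulation <- match.arg(articulation)
  translation <- match.arg(translation)
  area_convention <- match.arg(area_convention)
  nf <- duration * camera$frame_rate
  if (abs(nf - round(nf)) > 1e-9)
    stop("duration must be an integer number of frames")
  if (replace_prob < 0 || replace_prob > 1)
    stop("replace_prob must be in [0, 1]")
  if (density < 0) stop("density must be nonnegative")
  if ((condition == "none") != is.null(path))
    stop("condition 'none' admits no walker path; walker conditions require one")
  structure(list(camera = camera, observer = observer, path = path,
                 condition = condition, articulation = articulation,
                 translation = translation, duration = duration,
                 n_frames = as.integer(round(nf)),
                 replace_prob = replace_prob, density = density,
                 area_convention = area_convention,
                 disk_radius = disk_radius, seed = as.integer(seed)),
            class = "stimulus_config")
}

#' Angular area of the screen
#'
#' @param cam A [camera_model()].
#' @param convention `"product"` (horizontal x vertical angular extents) or
#'   `"solid_angle"` (exact rectangle solid angle).
#' @return Area in square degrees.
#' @export
screen_angular_area <- function(cam, convention = c("product", "solid_angle")) {
  convention <- match.arg(convention)
  a <- cam$screen_width / 2
  b <- cam$screen_height / 2
  d <- cam$viewing_distance
  deg <- 180 / pi
  if (convention == "product") {
    (2 * atan(a / d) * deg) * (2 * atan(b / d) * deg)
  } else {
    4 * atan(a * b / (d * sqrt(a^2 + b^2 + d^2))) * deg^2
  }
}

#' Initialize the dot field
#'
#' Places `round(density * angular area)` dots uniformly over the screen.
#' Dots below the horizon are ground dots, the rest sky dots; in the
#' congruent-with-walker condition each joint disk is additionally seeded
#' with its own locked dot population at the background density.
#'
#' @param cfg A [stimulus_config()].
#' @param gait A `gait_cycle` (needed for walker conditions).
#' @return An object of class `dot_field`.
#' @export
init_dot_field <- function(cfg, gait = NULL) {
  cam <- cfg$camera
  n <- as.integer(round(cfg$density *
                          screen_angular_area(cam, cfg$area_convention)))
  streams <- list(init = new_stream(derive_seed(cfg$seed, 1L)),
                  life = new_stream(derive_seed(cfg$seed, 2L)),
                  respawn = new_stream(derive_seed(cfg$seed, 3L)))
  W <- cam$screen_width; H <- cam$screen_height
  fld <- with_stream(streams$init, {
    list(x = stats::runif(n, -W / 2, W / 2),
         y = stats::runif(n, -H / 2, H / 2))
  })
  joint <- rep(NA_integer_, n)
  off_u <- rep(NA_real_, n)
  off_v <- rep(NA_real_, n)
  if (cfg$condition == "congruent_with_walker") {
    if (is.null(gait)) stop("walker conditions need a gait cycle")
    st0 <- walker_state_at(cfg$path, gait, 1 / cam$frame_rate,
                           cfg$articulation, cfg$translation, cfg$observer,
                           cam)
    deg <- 180 / pi
    dist2 <- rowSums(st0$joints^2)
    per_disk <- pmax(1L, as.integer(round(
      cfg$density * pi * cfg$disk_radius^2 / dist2 * deg^2)))
    nj <- rep(seq_len(18L), per_disk)
    m <- length(nj)
    disk <- with_stream(streams$init, {
      r <- cfg$disk_radius * sqrt(stats::runif(m))
      a <- stats::runif(m, 0, 2 * pi)
      list(u = r * cos(a), v = r * sin(a))
    })
    joint <- c(joint, nj)
    off_u <- c(off_u, disk$u)
    off_v <- c(off_v, disk$v)
    p <- cbind(st0$joints[nj, 1L] + disk$u, st0$joints[nj, 2L] + disk$v,
               st0$body_center[3])
    s <- project_points(p, cam)
    fld$x <- c(fld$x, s[, 1L])
    fld$y <- c(fld$y, s[, 2L])
  }
  structure(list(x = fld$x, y = fld$y, joint = joint,
                 off_u = off_u, off_v = off_v,
                 fresh = rep(TRUE, length(fld$x)),
                 n_background = n, streams = streams),
            class = "dot_field")
}

# Local-flow displacement for inside dots (vectorised over dots).
# mem: body_membership() result restricted to the inside dots.
local_flow_inside <- function(sx, sy, mem_xy, cfg, state_t, state_t1, dt) {
  cam <- cfg$camera
  zw <- state_t$body_center[3]
  p <- cbind(mem_xy[, 1L], mem_xy[, 2L], zw)
  if (cfg$condition == "incongruent_with_walker") {
    vc <- (state_t1$body_center - state_t$body_center) / dt
    v <- c(-vc[1L], vc[2L], vc[3L])
    p2 <- sweep(p, 2L, v * dt, `+`)
  } else if (cfg$condition == "congruent_with_flow") {
    p2 <- sweep(p, 2L, translation_vector(cfg$observer) * dt, `-`)
  } else {
    stop("unknown local-flow condition")
  }
  s2 <- project_points(p2, cam)
  s2 - cbind(sx, sy)
}

#' Advance the dot field by one frame
#'
#' Applies, in order: condition-specific displacement of dots inside the
#' walker silhouette and background flow outside it; limited-lifetime
#' replacement at a fresh uniform position; respawn of dots that left the
#' screen. Attribution follows position, so a dot crossing the silhouette
#' outline is captured at the next frame boundary: from then on its motion
#' matches the intended flow at its current position.
#'
#' @param field A `dot_field`.
#' @param cfg A [stimulus_config()].
#' @param state_t,state_t1 `walker_state`s at the current and next frame
#'   (`NULL` in the no-walker condition).
#' @param mem Optional precomputed [body_membership()] result for
#'   `state_t` over the field's dots.
#' @return The updated `dot_field`.
#' @export
step_dot_field <- function(field, cfg, state_t = NULL, state_t1 = NULL,
                           mem = NULL) {
  cam <- cfg$camera
  dt <- 1 / cam$frame_rate
  W <- cam$screen_width; H <- cam$screen_height
  n <- length(field$x)
  cond <- cfg$condition
  disk <- !is.na(field$joint)

  if (is.null(mem) && !is.null(state_t))
    mem <- body_membership(cbind(field$x, field$y), state_t, cam,
                           cfg$disk_radius)
  inside <- if (is.null(mem)) rep(FALSE, n) else mem$inside

  x2 <- field$x; y2 <- field$y
  lost <- rep(FALSE, n)

  # dots following the condition's inside rule (never the disk-locked ones)
  loc <- inside & !disk & cond %in%
    c("incongruent_with_walker", "congruent_with_flow")
  bg <- !disk & !loc
  if (any(bg)) {
    d <- background_flow(cbind(field$x[bg], field$y[bg]), cfg$observer,
                         cam, dt)
    x2[bg] <- field$x[bg] + d[, 1L]
    y2[bg] <- field$y[bg] + d[, 2L]
    lost[bg] <- is.na(d[, 1L])
  }
  if (any(loc)) {
    d <- local_flow_inside(field$x[loc], field$y[loc],
                           mem$plane_xy[loc, , drop = FALSE],
                           cfg, state_t, state_t1, dt)
    x2[loc] <- field$x[loc] + d[, 1L]
    y2[loc] <- field$y[loc] + d[, 2L]
    lost[loc] <- is.na(d[, 1L])
  }
  if (any(disk)) {
    nj <- field$joint[disk]
    p <- cbind(state_t1$joints[nj, 1L] + field$off_u[disk],
               state_t1$joints[nj, 2L] + field$off_v[disk],
               state_t1$body_center[3L])
    s <- project_points(p, cam)
    x2[disk] <- s[, 1L]
    y2[disk] <- s[, 2L]
  }

  fresh <- rep(FALSE, n)

  # limited lifetime: uniform replacement position, fresh attribution
  repl <- with_stream(field$streams$life, stats::runif(n) < cfg$replace_prob)
  if (any(repl)) {
    nb <- sum(repl & !disk)
    if (nb) {
      pos <- with_stream(field$streams$life,
                         list(x = stats::runif(nb, -W / 2, W / 2),
                              y = stats::runif(nb, -H / 2, H / 2)))
      x2[repl & !disk] <- pos$x
      y2[repl & !disk] <- pos$y
    }
    nd <- sum(repl & disk)
    if (nd) {
      newd <- with_stream(field$streams$life, {
        j <- sample.int(18L, nd, replace = TRUE)
        r <- cfg$disk_radius * sqrt(stats::runif(nd))
        a <- stats::runif(nd, 0, 2 * pi)
        list(j = j, u = r * cos(a), v = r * sin(a))
      })
      field$joint[repl & disk] <- newd$j
      field$off_u[repl & disk] <- newd$u
      field$off_v[repl & disk] <- newd$v
      p <- cbind(state_t1$joints[newd$j, 1L] + newd$u,
                 state_t1$joints[newd$j, 2L] + newd$v,
                 state_t1$body_center[3L])
      s <- project_points(p, cam)
      x2[repl & disk] <- s[, 1L]
      y2[repl & disk] <- s[, 2L]
    }
    lost[repl] <- FALSE
    fresh[repl] <- TRUE
  }

  # respawn background dots that left the screen (disk dots stay anchored
  # and are simply not shown while off screen)
  off <- !disk & (lost | is.na(x2) | abs(x2) > W / 2 | abs(y2) > H / 2)
  if (any(off)) {
    m <- sum(off)
    pos <- with_stream(field$streams$respawn,
                       list(x = stats::runif(m, -W / 2, W / 2),
                            y = stats::runif(m, -H / 2, H / 2)))
    x2[off] <- pos$x
    y2[off] <- pos$y
    fresh[off] <- TRUE
  }

  field$x <- x2
  field$y <- y2
  field$fresh <- fresh
  field
}

# one frame's visible dots as a data.frame
emit_frame <- function(field, cfg, frame_idx, mem = NULL, labels = TRUE) {
  cam <- cfg$camera
  W <- cam$screen_width; H <- cam$screen_height
  disk <- !is.na(field$joint)
  onscreen <- abs(field$x) <= W / 2 & abs(field$y) <= H / 2
  inside <- if (is.null(mem)) rep(FALSE, length(field$x)) else mem$inside
  visible <- onscreen
  if (cfg$condition == "congruent_with_walker")
    visible <- visible & !(inside & !disk)   # occluded background dots
  out <- data.frame(frame = frame_idx,
                    id = which(visible),
                    x = field$x[visible],
                    y = field$y[visible],
                    fresh = field$fresh[visible])
  if (labels) {
    lab <- rep("background", length(field$x))
    lab[inside & !disk] <- "walker"
    lab[disk] <- "walker"
    if (cfg$condition != "congruent_with_walker") lab[disk] <- "background"
    out$label <- lab[visible]
  }
  out
}

#' Generate a full stimulus
#'
#' Runs the dot-field engine over the whole trial and returns the per-frame
#' dot positions. At the default 60 Hz and 1.7-s duration this is 102 frames
#' spanning 1.5 walking cycles.
#'
#' @param cfg A [stimulus_config()].
#' @param gait A `gait_cycle`; synthesized with defaults when omitted and a
#'   walker is present.
#' @param labels Keep per-dot diagnostic labels (`"background"` /
#'   `"walker"`)? These are never rendered; with `labels = FALSE` the frames
#'   carry positions only.
#' @return An object of class `fw_stimulus`: list with `config`, `frames`
#'   (list of per-frame data frames: `frame`, `id`, `x`, `y`, `fresh`
#'   and optionally `label`), and `n_frames`.
#' @examples
#' cfg <- stimulus_config(density = 0.05, seed = 7)
#' stim <- generate_stimulus(cfg)
#' length(stim$frames)
#' @export
generate_stimulus <- function(cfg, gait = NULL, labels = TRUE) {
  walker <- cfg$condition != "none"
  if (walker && is.null(gait)) gait <- synthesize_gait()
  nf <- cfg$n_frames
  dt <- 1 / cfg$camera$frame_rate
  # frame i shows the state after i frame intervals, so the last frame falls
  # exactly at the trial duration (1.5 gait cycles, walker at its end point)
  states <- if (walker) {
    lapply(seq_len(nf), function(i)
      walker_state_at(cfg$path, gait, i * dt, cfg$articulation,
                      cfg$translation, cfg$observer, cfg$camera))
  } else NULL
  field <- init_dot_field(cfg, gait)
  frames <- vector("list", nf)
  for (i in seq_len(nf)) {
    mem <- if (walker)
      body_membership(cbind(field$x, field$y), states[[i]], cfg$camera,
                      cfg$disk_radius)
    frames[[i]] <- emit_frame(field, cfg, i, mem, labels)
    if (i < nf)
      field <- step_dot_field(field, cfg, states[[i]], states[[i + 1L]], mem)
  }
  structure(list(config = cfg, frames = frames, n_frames = nf),
            class = "fw_stimulus")
}

#' @export
print.fw_stimulus <- function(x, ...) {
  cat(sprintf("fw_stimulus: %d frames, condition %s, ~%d dots/frame\n",
              x$n_frames, x$config$condition, nrow(x$frames[[1L]])))
  invisible(x)
}

#' Frame-to-frame dot correspondences
#'
#' Displacement vectors of dots tracked across consecutive frames — the
#' engine diagnostic consumed by the pooled-flow observer. Dots replaced by
#' the lifetime process or respawned contribute no displacement on the frame
#' they reappear.
#'
#' @param stim An `fw_stimulus`.
#' @return A data.frame: `frame` (source frame), `x`, `y` (position, m) and
#'   `dx`, `dy` (displacement to the next frame, m).
#' @export
stimulus_correspondences <- function(stim) {
  out <- vector("list", stim$n_frames - 1L)
  for (i in seq_len(stim$n_frames - 1L)) {
    a <- stim$frames[[i]]
    b <- stim$frames[[i + 1L]]
    k <- match(a$id, b$id)
    ok <- !is.na(k) & !b$fresh[pmax(k, 1L)]
    k <- k[ok]
    out[[i]] <- data.frame(frame = i, x = a$x[ok], y = a$y[ok],
                           dx = b$x[k] - a$x[ok], dy = b$y[k] - a$y[ok])
  }
  do.call(rbind, out)
}

#' Rasterize frames to PNG files
#'
#' Nearest-pixel rasterization: each dot lights one pixel of an
#' 8-bit grayscale image at the display resolution, white on black.
#'
#' @param stim An `fw_stimulus`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; files are `<prefix>_0001.png`, ...
#' @return Invisibly, the written file paths.
#' @export
render_frames <- function(stim, dir, prefix = "frame") {
  cam <- stim$config$camera
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  W <- cam$screen_width; H <- cam$screen_height
  paths <- character(stim$n_frames)
  for (i in seq_len(stim$n_frames)) {
    f <- stim$frames[[i]]
    img <- matrix(0, cam$resolution_y, cam$resolution_x)
    if (nrow(f)) {
      col <- pmin(cam$resolution_x,
                  pmax(1L, floor((f$x + W / 2) / W * cam$resolution_x) + 1L))
      row <- pmin(cam$resolution_y,
                  pmax(1L, floor((H / 2 - f$y) / H * cam$resolution_y) + 1L))
      img[cbind(row, col)] <- 1
    }
    paths[i] <- file.path(dir, sprintf("%s_%04d.png", prefix, i))
    png::writePNG(img, paths[i])
  }
  invisible(paths)
}

#' Write stimulus frames as a delimited text table
#'
#' @param stim An `fw_stimulus`.
#' @param file Output path (tab-separated, one row per visible dot).
#' @export
write_frames_table <- function(stim, file) {
  utils::write.table(do.call(rbind, stim$frames), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}
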