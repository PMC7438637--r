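#' Pooled-flow heading estimator parameters
#'
#' The estimator implements the rigid-scene pooling account of heading
#' perception: every motion vector in the field contributes to the focus-of-
#' expansion search, with no segmentation of independently moving regions.
#' Candidate FOEs lie on the horizontal axis (the task is a horizontal
#' adjustment); the residual at a candidate is the magnitude-weighted sum of
#' squared sines of the angles between each dot displacement and the radial
#' direction from the candidate, minimized by grid search with parabolic
#' refinement.
#'
#' @param grid_extent Half-extent of the candidate grid (degrees).
#' @param grid_step Grid step (degrees).
#' @param n_sample Maximum number of displacement vectors used (subsampled
#'   deterministically per seed when more are available).
#' @param min_vectors Minimum usable vectors below which estimation fails.
#' @param rotation `"yaw"` fits a free yaw-rotation component jointly with
#'   each candidate heading (the full rigid-scene interpretation; rotation
#'   and lateral translation are partially interchangeable, which is what
#'   produces the classic heading bias toward laterally moving objects);
#'   `"none"` fits pure translation.
#' @param gain Multiplicative response gain applied by the responder stage
#'   (perceived = gain x estimate), emulating the compressive centre bias of
#'   human adjustment.
#' @param noise_sd Response noise (degrees, sd) added per trial.
#' @param seed Seed for subsampling and response noise.
#' @return A list of class `observer_params`.
#' @export
observer_params <- function(grid_extent = 12, grid_step = 0.1,
                            n_sample = 30000L, min_vectors = 50L,
                            rotation = c("yaw", "none"),
                            gain = 0.548, noise_sd = 0, seed = 1L) {
  rotation <- match.arg(rotation)
  if (gain <= 0 || gain > 1) stop("gain must be in (0, 1]")
  if (grid_step <= 0 || grid_extent <= 0) stop("grid must be positive")
  structure(list(grid_extent = grid_extent, grid_step = grid_step,
                 n_sample = as.integer(n_sample),
                 min_vectors = as.integer(min_vectors),
                 rotation = rotation,
                 gain = gain, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "observer_params")
}

#' Estimate heading from pooled motion vectors
#'
#' Searches candidate FOEs on the horizontal screen axis for the point the
#' displacement field radiates from, pooling all vectors indiscriminately
#' under a rigid-scene interpretation. For a candidate `f`, each vector's
#' translational component is radial from `f` with a free per-dot magnitude
#' (unknown depth), so only the tangential component
#' `s = (dx * ry - dy * rx) / |r|` with `r = (x - f, y)` is unexplained —
#' its square is the displacement magnitude times the squared sine of the
#' angle to the radial direction. With `rotation = "yaw"` a free rotation
#' about the vertical axis is fitted jointly (closed form per candidate):
#' the residual becomes the tangential misfit left after the best rotation,
#' which makes the estimator sensitive to uniform lateral motion in the way
#' that produces the classic bias toward a laterally moving object.
#' Zero-magnitude vectors (static sky dots) contribute nothing and are
#' dropped.
#'
#' @param corr Correspondences from [stimulus_correspondences()] (columns
#'   `x`, `y`, `dx`, `dy`), or any data.frame with those columns.
#' @param cam A [camera_model()].
#' @param params An [observer_params()].
#' @return Estimated heading (degrees), with attribute `"residual"`.
#' @export
estimate_heading <- function(corr, cam = camera_model(),
                             params = observer_params()) {
  keep <- corr$dx != 0 | corr$dy != 0
  corr <- corr[keep, , drop = FALSE]
  if (nrow(corr) < params$min_vectors)
    stop("too few motion vectors for heading estimation")
  if (nrow(corr) > params$n_sample) {
    old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(params$seed)
    corr <- corr[sample.int(nrow(corr), params$n_sample), ]
  }
  grid <- seq(-params$grid_extent, params$grid_extent, by = params$grid_step)
  fx <- cam$viewing_distance * tan(grid * pi / 180)
  x <- corr$x; y <- corr$y; dx <- corr$dx; dy <- corr$dy
  vd <- cam$viewing_distance
  # yaw-rotation image displacement per unit rotation (scale irrelevant)
  qx <- vd + x^2 / vd
  qy <- x * y / vd
  yaw <- params$rotation == "yaw"
  res <- vapply(fx, function(f) {
    rx <- x - f
    L2 <- rx^2 + y^2
    sd <- (dx * y - dy * rx) / sqrt(L2)
    if (!yaw) return(sum(sd^2))
    sq <- (qx * y - qy * rx) / sqrt(L2)
    sum(sd^2) - sum(sd * sq)^2 / sum(sq^2)
  }, 0)
  i <- which.min(res)
  best <- fx[i]
  # parabolic refinement over the three points around the grid minimum
  if (i > 1L && i < length(fx)) {
    a <- res[i - 1L]; b <- res[i]; c <- res[i + 1L]
    denom <- a - 2 * b + c
    if (denom > 0)
      best <- fx[i] + 0.5 * (a - c) / denom * (fx[i + 1L] - fx[i])
  }
  structure(screen_x_to_heading(best, cam), residual = res[i])
}

#' Simulate heading-adjustment responses
#'
#' Machine responders for the heading experiment. With
#' `estimator = "pooled_flow"` each trial's stimulus is generated from its
#' schedule seed and the pooled-flow estimator produces the heading
#' estimate; with `estimator = "true"` the simulated heading itself is used
#' (a shortcut for exercising the analysis stage). The response is the
#' screen position `tan(gain * estimate + noise) * viewing_distance`.
#'
#' @param schedule A heading schedule from [build_heading_schedule()].
#' @param params An [observer_params()].
#' @param responders Character vector of responder ids.
#' @param cam A [camera_model()].
#' @param estimator `"true"` or `"pooled_flow"`.
#' @param gait Gait cycle used for stimulus generation (synthesized when
#'   omitted).
#' @param ... Passed to [trial_stimulus_config()] (e.g. `density`).
#' @return A data.frame of `ResponseRecord`s: `trial`, `responder`,
#'   `response` (screen x, m).
#' @export
simulate_heading_responses <- function(schedule, params = observer_params(),
                                       responders = "obs1",
                                       cam = camera_model(),
                                       estimator = c("true", "pooled_flow"),
                                       gait = NULL, ...) {
  estimator <- match.arg(estimator)
  if (estimator == "pooled_flow" && is.null(gait)) gait <- synthesize_gait()
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$seed)
  out <- lapply(responders, function(rid) {
    est <- vapply(seq_len(nrow(schedule)), function(i) {
      tr <- schedule[i, ]
      if (estimator == "true") return(tr$heading_angle)
      cfg <- trial_stimulus_config(tr, camera = cam, ...)
      stim <- generate_stimulus(cfg, gait = gait, labels = FALSE)
      as.numeric(estimate_heading(stimulus_correspondences(stim), cam,
                                  params))
    }, 0)
    noise <- if (params$noise_sd > 0)
      stats::rnorm(nrow(schedule), 0, params$noise_sd) else 0
    perceived <- params$gain * est + noise
    data.frame(trial = schedule$trial, responder = rid,
               response = tan(perceived * pi / 180) * cam$viewing_distance)
  })
  do.call(rbind, out)
}

#' Stochastic responder parameters for the choice experiments
#'
#' @param accuracy Named numeric vector of per-walker-condition probabilities
#'   of a correct response (names as in [walker_conditions()]), or a single
#'   probability applied to all conditions.
#' @param seed Integer seed.
#' @return A list of class `choice_params`.
#' @export
choice_params <- function(accuracy = 0.9, seed = 1L) {
  if (any(accuracy < 0 | accuracy > 1))
    stop("accuracies must be probabilities")
  structure(list(accuracy = accuracy, seed = as.integer(seed)),
            class = "choice_params")
}

#' Simulate facing / articulation choice responses
#'
#' Emits the trial's correct answer with the condition's programmed
#' accuracy and the opposite answer otherwise — a stochastic stand-in for
#' participants in the facing and articulation pipelines.
#'
#' @param schedule A schedule from [build_choice_schedule()].
#' @param params A [choice_params()].
#' @param responders Character vector of responder ids.
#' @return A data.frame: `trial`, `responder`, `response`.
#' @export
simulate_choice_responses <- function(schedule, params = choice_params(),
                                      responders = "obs1") {
  exps <- unique(schedule$experiment)
  if (length(exps) != 1L || !exps %in% c("facing", "articulation"))
    stop("schedule must be a facing or articulation design")
  acc <- params$accuracy
  if (length(acc) == 1L && is.null(names(acc)))
    acc <- stats::setNames(rep(acc, 6L), walker_conditions())
  missing <- setdiff(unique(schedule$walker_condition), names(acc))
  if (length(missing))
    stop("no accuracy for condition(s): ", paste(missing, collapse = ", "))
  truth <- if (exps == "facing") schedule$walker_direction
           else schedule$articulation
  flip_map <- c(left = "right", right = "left",
                forward = "backward", backward = "forward")
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$seed)
  do.call(rbind, lapply(responders, function(rid) {
    p <- acc[schedule$walker_condition]
    correct <- stats::runif(nrow(schedule)) < p
    data.frame(trial = schedule$trial, responder = rid,
               response = ifelse(correct, truth,
                                 unname(flip_map[truth])))
  }))
}
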