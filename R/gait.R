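#' Names of the 18 walker joints
#'
#' Head, left/right shoulders, elbows, wrists, hands, hips, knees, ankles and
#' foot tips are the 17 enumerated body parts; the 18th marker is a
#' pelvis/body-centre point.
#'
#' @return Character vector of length 18.
#' @export
walker_joints <- function() {
  side <- function(nm) paste(rep(c("l", "r"), each = length(nm)), nm, sep = "_")
  c("head",
    side(c("shoulder", "elbow", "wrist", "hand", "hip", "knee", "ankle", "foot")),
    "pelvis")
}

#' Parametric gait parameters
#'
#' Amplitudes (m) and joint heights (m above ground) for the sinusoidal
#' sagittal-plane gait synthesizer. Arm and leg swing are in counter-phase
#' (the right arm swings with the left leg) and the trunk bobs vertically at
#' twice the stride frequency, the standard kinematic signature of walking.
#'
#' @param leg_swing,arm_swing Peak forward excursion of ankle/foot and
#'   wrist/hand markers (m).
#' @param knee_swing,elbow_swing Peak forward excursion of mid-limb markers (m).
#' @param hip_sway Peak forward hip oscillation (m).
#' @param bob Peak-to-zero vertical trunk oscillation (m), at double frequency.
#' @param foot_lift Peak vertical lift of ankle/foot markers during swing (m).
#' @param shoulder_width,hip_width Half lateral offsets (m).
#' @param heights Named numeric vector of marker heights above ground (m).
#' @return A list of class `gait_params`.
#' @export
gait_params <- function(leg_swing = 0.30, arm_swing = 0.22,
                        knee_swing = 0.16, elbow_swing = 0.10,
                        hip_sway = 0.03, bob = 0.02, foot_lift = 0.06,
                        shoulder_width = 0.20, hip_width = 0.12,
                        heights = c(head = 1.72, shoulder = 1.45,
                                    elbow = 1.18, wrist = 0.95, hand = 0.86,
                                    hip = 0.95, knee = 0.52, ankle = 0.12,
                                    foot = 0.04, pelvis = 0.98)) {
  structure(list(leg_swing = leg_swing, arm_swing = arm_swing,
                 knee_swing = knee_swing, elbow_swing = elbow_swing,
                 hip_sway = hip_sway, bob = bob, foot_lift = foot_lift,
                 shoulder_width = shoulder_width, hip_width = hip_width,
                 heights = heights),
            class = "gait_params")
}

#' Synthesize one walking cycle
#'
#' Builds an 18-joint gait cycle from sinusoidal limb oscillations, standing
#' in for a motion-capture recording. Joint offsets are in body-centred
#' coordinates — x along the facing direction, y lateral (left positive),
#' z up from the ground — and carry no net forward drift over the cycle:
#' translation along the path is applied by the walker path, not the gait.
#'
#' @param params A [gait_params()] list.
#' @param period Cycle duration (s); the default `68/60` is the 1.1333-s
#'   cycle that spans exactly 68 frames at 60 Hz.
#' @param frame_rate Sampling rate (Hz) fixing `frames_per_cycle`.
#' @return A `gait_cycle`: list with `period`, `frames_per_cycle`, `joints`
#'   and a `[frame, joint, axis]` trajectory array (m).
#' @examples
#' g <- synthesize_gait()
#' g$frames_per_cycle  # 68
#' @export
synthesize_gait <- function(params = gait_params(), period = 68 / 60,
                            frame_rate = 60) {
  if (!is.finite(period) || period <= 0) stop("period must be positive")
  if (!is.finite(frame_rate) || frame_rate <= 0)
    stop("frame_rate must be positive")
  nf <- as.integer(round(period * frame_rate))
  if (nf < 4L) stop("period too short for the frame rate")
  joints <- walker_joints()
  traj <- array(0, dim = c(nf, 18L, 3L),
                dimnames = list(NULL, joints, c("x", "y", "z")))
  ph <- 2 * pi * (seq_len(nf) - 1L) / nf     # stride phase, right leg leads
  h <- params$heights
  put <- function(j, x, y, z) traj[, j, ] <<- cbind(x, y, z)

  leg <- function(side_sign, phase) {
    sw <- sin(phase)
    lift <- pmax(0, -cos(phase + pi / 4)) * params$foot_lift
    list(
      hip = cbind(params$hip_sway * sw, side_sign * params$hip_width,
                  h[["hip"]] + params$bob * cos(2 * ph)),
      knee = cbind(params$knee_swing * sw, side_sign * params$hip_width,
                   rep(h[["knee"]], length(ph))),
      ankle = cbind(params$leg_swing * sw, side_sign * params$hip_width,
                    h[["ankle"]] + lift),
      foot = cbind(params$leg_swing * 1.1 * sin(phase - 0.25),
                   side_sign * params$hip_width, h[["foot"]] + lift))
  }
  arm <- function(side_sign, phase) {
    sw <- sin(phase)
    list(
      shoulder = cbind(0.25 * params$hip_sway * sw,
                       side_sign * params$shoulder_width,
                       h[["shoulder"]] + params$bob * cos(2 * ph)),
      elbow = cbind(params$elbow_swing * sw,
                    side_sign * (params$shoulder_width + 0.03),
                    rep(h[["elbow"]], length(ph))),
      wrist = cbind(params$arm_swing * sw,
                    side_sign * (params$shoulder_width + 0.04),
                    rep(h[["wrist"]], length(ph))),
      hand = cbind(params$arm_swing * 1.1 * sin(phase + 0.15),
                   side_sign * (params$shoulder_width + 0.04),
                   rep(h[["hand"]], length(ph))))
  }
  # right leg at phase ph, left leg half a cycle later; arms counter-phase
  # to the ipsilateral leg
  rl <- leg(-1, ph); ll <- leg(+1, ph + pi)
  ra <- arm(-1, ph + pi); la <- arm(+1, ph)
  for (j in names(rl)) {
    put(paste0("r_", j), rl[[j]][, 1L], rl[[j]][, 2L], rl[[j]][, 3L])
    put(paste0("l_", j), ll[[j]][, 1L], ll[[j]][, 2L], ll[[j]][, 3L])
  }
  for (j in names(ra)) {
    put(paste0("r_", j), ra[[j]][, 1L], ra[[j]][, 2L], ra[[j]][, 3L])
    put(paste0("l_", j), la[[j]][, 1L], la[[j]][, 2L], la[[j]][, 3L])
  }
  put("head", rep(0, nf), rep(0, nf), h[["head"]] + params$bob * cos(2 * ph))
  put("pelvis", rep(0, nf), rep(0, nf),
      h[["pelvis"]] + params$bob * cos(2 * ph))
  # remove any residual forward/lateral drift so translation lives in the path
  for (ax in 1:2) traj[, , ax] <- traj[, , ax] - mean(traj[, , ax])
  structure(list(period = period, frames_per_cycle = nf, joints = joints,
                 traj = traj),
            class = "gait_cycle")
}

#' @export
print.gait_cycle <- function(x, ...) {
  cat(sprintf("gait_cycle: %d joints, %d frames, period %.4f s\n",
              length(x$joints), x$frames_per_cycle, x$period))
  invisible(x)
}

#' Pose at a phase of the cycle
#'
#' Samples the cycle at a phase in `[0, 1)`, interpolating linearly between
#' stored frames and wrapping cyclically. Backward articulation reads the
#' cycle in reverse frame order, so a backward pose at phase `p` equals the
#' forward pose at phase `1 - p`.
#'
#' @param gait A `gait_cycle`.
#' @param phase Cycle phase (any real; used modulo 1).
#' @param articulation `"forward"` or `"backward"`.
#' @return An 18 x 3 matrix of body-frame joint offsets (m).
#' @export
gait_pose <- function(gait, phase, articulation = c("forward", "backward")) {
  articulation <- match.arg(articulation)
  phase <- phase %% 1
  if (articulation == "backward") phase <- (1 - phase) %% 1
  nf <- gait$frames_per_cycle
  f <- phase * nf
  i0 <- floor(f) %% nf
  w <- f - floor(f)
  i1 <- (i0 + 1) %% nf
  (1 - w) * gait$traj[i0 + 1L, , ] + w * gait$traj[i1 + 1L, , ]
}

#' Write a gait cycle to a delimited text file
#'
#' One row per frame, 54 columns named `<joint>_<axis>`, preceded by a
#' `# period_s: <value>` metadata line. [load_gait()] reads the format back
#' losslessly.
#'
#' @param gait A `gait_cycle`.
#' @param file Output path.
#' @export
write_gait <- function(gait, file) {
  m <- matrix(aperm(gait$traj, c(1L, 3L, 2L)), nrow = gait$frames_per_cycle)
  colnames(m) <- paste(rep(gait$joints, each = 3L), c("x", "y", "z"),
                       sep = "_")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# period_s: %.17g", gait$period), con)
  utils::write.table(as.data.frame(m), con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' Load a gait cycle from a joint-trajectory table
#'
#' Validates the 18-joint x 3-axis schema, finiteness and the period header,
#' and removes (and reports) any mean forward/lateral drift so that
#' translation is carried by the walker path, not the gait.
#'
#' @param file Path to a file written by [write_gait()] (or any table with
#'   the same schema).
#' @return A `gait_cycle`. The removed drift (m) is attached as attribute
#'   `"removed_drift"`.
#' @export
load_gait <- function(file) {
  header <- readLines(file, n = 1L)
  if (!grepl("^# *period_s:", header))
    stop("missing '# period_s:' metadata line")
  period <- as.numeric(sub("^# *period_s:", "", header))
  if (!is.finite(period) || period <= 0) stop("invalid period_s value")
  tab <- utils::read.csv(file, skip = 1L, check.names = FALSE)
  joints <- walker_joints()
  want <- paste(rep(joints, each = 3L), c("x", "y", "z"), sep = "_")
  missing <- setdiff(want, names(tab))
  if (length(missing))
    stop("gait table is missing columns: ", paste(missing, collapse = ", "))
  m <- as.matrix(tab[, want])
  if (!all(is.finite(m))) stop("gait table contains non-finite values")
  nf <- nrow(m)
  if (nf < 4L) stop("gait table has too few frames")
  traj <- aperm(array(m, dim = c(nf, 3L, 18L)), c(1L, 3L, 2L))
  dimnames(traj) <- list(NULL, joints, c("x", "y", "z"))
  drift <- c(x = mean(traj[, , 1L]), y = mean(traj[, , 2L]))
  for (ax in 1:2) traj[, , ax] <- traj[, , ax] - drift[[ax]]
  out <- structure(list(period = period, frames_per_cycle = nf,
                        joints = joints, traj = traj),
                   class = "gait_cycle")
  attr(out, "removed_drift") <- drift
  out
}
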