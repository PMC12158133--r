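#' Skeleton dimensions for the synthetic generator
#'
#' Segment lengths of the articulated figure, all expressed as fractions of
#' image height. Defaults follow standard anthropometric proportions for an
#' adult whose standing figure fills most of the frame (biacromial width
#' about 0.23 of stature, bi-iliac about 0.16), which keeps the figure fully
#' inside the unit image in the neutral pose.
#'
#' @param shoulder_halfwidth,hip_halfwidth Lateral half-distances.
#' @param trunk_length Mid-hip to mid-shoulder.
#' @param arm_length Shoulder to wrist (elbow at midpoint).
#' @param leg_length Hip to ankle (knee at midpoint).
#' @param head_height Vertical offset from mid-shoulder (neck) to the
#'   ear/nose plane; the head is modeled as a circle of radius
#'   `inter_ear / 2` in the horizontal plane with the nose on the circle.
#' @param inter_eye,inter_ear Lateral eye and ear distances
#'   (`inter_eye < inter_ear`).
#' @param hip_y Image y (downward) of the mid-hip point.
#' @return List of class `skeleton_dims`.
#' @export
skeleton_dims <- function(shoulder_halfwidth = 0.115, hip_halfwidth = 0.08,
                          trunk_length = 0.25, arm_length = 0.28,
                          leg_length = 0.40, head_height = 0.10,
                          inter_eye = 0.07, inter_ear = 0.12, hip_y = 0.55) {
  dims <- list(
    shoulder_halfwidth = shoulder_halfwidth, hip_halfwidth = hip_halfwidth,
    trunk_length = trunk_length, arm_length = arm_length,
    leg_length = leg_length, head_height = head_height,
    inter_eye = inter_eye, inter_ear = inter_ear, hip_y = hip_y
  )
  if (any(unlist(dims) <= 0)) stop("all skeleton dimensions must be positive", call. = FALSE)
  if (inter_eye >= inter_ear) stop("inter_eye must be smaller than inter_ear", call. = FALSE)
  structure(dims, class = "skeleton_dims")
}

#' Articulated pose state
#'
#' The joint-angle configuration of the synthetic figure at one instant.
#' Body frame: X = subject's left (projects to image +x at yaw 0), Y = up,
#' Z = toward the camera. Signed angles are positive toward the subject's
#' left (tilt, rotation) or forward (pitch).
#'
#' @param yaw_deg Global rotation about the vertical axis in `[-90, 90]`
#'   (0 = facing the camera; sign picks the facing direction).
#' @param head_tilt_deg Lateral head tilt, `[-90, 90]`, + = left.
#' @param head_rot_deg Head rotation, `[-90, 90]`, + = left.
#' @param head_pitch_deg Head pitch, `[-90, 90]`, + = forward.
#' @param arm_abduction_left_deg,arm_abduction_right_deg Straight-arm
#'   abduction from the trunk-down axis, `[0, 180]`.
#' @param leg_abduction_left_deg,leg_abduction_right_deg Straight-leg
#'   abduction from vertical, `[0, 90]`.
#' @param trunk_tilt_deg Lateral trunk tilt, `[-90, 90]`, + = left.
#' @param trunk_pitch_deg Frontal trunk inclination, `[-90, 90]`,
#'   + = forward.
#' @return List of class `pose_state`.
#' @export
pose_state <- function(yaw_deg = 0, head_tilt_deg = 0, head_rot_deg = 0,
                       head_pitch_deg = 0, arm_abduction_left_deg = 0,
                       arm_abduction_right_deg = 0, leg_abduction_left_deg = 0,
                       leg_abduction_right_deg = 0, trunk_tilt_deg = 0,
                       trunk_pitch_deg = 0) {
  p <- list(
    yaw_deg = yaw_deg, head_tilt_deg = head_tilt_deg, head_rot_deg = head_rot_deg,
    head_pitch_deg = head_pitch_deg,
    arm_abduction_left_deg = arm_abduction_left_deg,
    arm_abduction_right_deg = arm_abduction_right_deg,
    leg_abduction_left_deg = leg_abduction_left_deg,
    leg_abduction_right_deg = leg_abduction_right_deg,
    trunk_tilt_deg = trunk_tilt_deg, trunk_pitch_deg = trunk_pitch_deg
  )
  rng <- list(
    yaw_deg = c(-90, 90), head_tilt_deg = c(-90, 90), head_rot_deg = c(-90, 90),
    head_pitch_deg = c(-90, 90), arm_abduction_left_deg = c(0, 180),
    arm_abduction_right_deg = c(0, 180), leg_abduction_left_deg = c(0, 90),
    leg_abduction_right_deg = c(0, 90), trunk_tilt_deg = c(-90, 90),
    trunk_pitch_deg = c(-90, 90)
  )
  for (nm in names(p)) {
    if (p[[nm]] < rng[[nm]][1] || p[[nm]] > rng[[nm]][2]) {
      stop(sprintf("%s = %g outside physical range [%g, %g]",
                   nm, p[[nm]], rng[[nm]][1], rng[[nm]][2]), call. = FALSE)
    }
  }
  structure(p, class = "pose_state")
}

.d2r <- pi / 180

# lean an up-vector toward +X by theta (degrees); frontal (X-Y) plane
.rot_lat <- function(p, theta) {
  t <- theta * .d2r
  c(p[1] * cos(t) + p[2] * sin(t), -p[1] * sin(t) + p[2] * cos(t), p[3])
}
# pitch: + rotates anterior (+Z) points downward; sagittal (Y-Z) plane
.rot_pitch <- function(p, theta) {
  t <- theta * .d2r
  c(p[1], p[2] * cos(t) - p[3] * sin(t), p[2] * sin(t) + p[3] * cos(t))
}
# rotate about the vertical axis; + turns +Z (anterior) toward +X (left)
.rot_yaw <- function(p, theta) {
  t <- theta * .d2r
  c(p[1] * cos(t) + p[3] * sin(t), p[2], -p[1] * sin(t) + p[3] * cos(t))
}

# 17 x 3 body-frame coordinates (origin at mid-hip) by forward kinematics
.skeleton_points <- function(pose, dims) {
  pts <- matrix(NA_real_, 17, 3, dimnames = list(coco_schema(), c("X", "Y", "Z")))
  pts["left_hip", ] <- c(dims$hip_halfwidth, 0, 0)
  pts["right_hip", ] <- c(-dims$hip_halfwidth, 0, 0)
  trunk_rot <- function(p) .rot_lat(.rot_pitch(p, pose$trunk_pitch_deg), pose$trunk_tilt_deg)
  neck <- trunk_rot(c(0, dims$trunk_length, 0))
  pts["left_shoulder", ] <- neck + trunk_rot(c(dims$shoulder_halfwidth, 0, 0))
  pts["right_shoulder", ] <- neck + trunk_rot(c(-dims$shoulder_halfwidth, 0, 0))
  for (side in c("left", "right")) {
    sgn <- if (side == "left") -1 else 1  # .rot_lat(-a) swings a down-vector to +X
    a <- pose[[paste0("arm_abduction_", side, "_deg")]]
    dir <- trunk_rot(.rot_lat(c(0, -1, 0), sgn * a))
    sh <- pts[paste0(side, "_shoulder"), ]
    pts[paste0(side, "_elbow"), ] <- sh + dir * dims$arm_length / 2
    pts[paste0(side, "_wrist"), ] <- sh + dir * dims$arm_length
    l <- pose[[paste0("leg_abduction_", side, "_deg")]]
    ldir <- .rot_lat(c(0, -1, 0), sgn * l)
    hp <- pts[paste0(side, "_hip"), ]
    pts[paste0(side, "_knee"), ] <- hp + ldir * dims$leg_length / 2
    pts[paste0(side, "_ankle"), ] <- hp + ldir * dims$leg_length
  }
  # head: circle of radius e in the horizontal plane, nose on the circle
  e <- dims$inter_ear / 2
  ey <- dims$inter_eye / 2
  h <- dims$head_height
  head_local <- rbind(
    nose = c(0, h, e),
    left_eye = c(ey, h + 0.15 * h, sqrt(e^2 - ey^2)),
    right_eye = c(-ey, h + 0.15 * h, sqrt(e^2 - ey^2)),
    left_ear = c(e, h, 0),
    right_ear = c(-e, h, 0)
  )
  head_rot <- function(p) {
    trunk_rot(.rot_lat(.rot_yaw(.rot_pitch(p, pose$head_pitch_deg),
                                pose$head_rot_deg), pose$head_tilt_deg))
  }
  for (nm in rownames(head_local)) {
    pts[nm, ] <- neck + head_rot(head_local[nm, ])
  }
  pts
}

#' Project a pose state to an image-frame keypoint frame
#'
#' Places the 17 keypoints by forward kinematics in the body frame, applies
#' the global yaw (orthographic projection: depth is discarded after the
#' rotation, so mediolateral offsets foreshorten by `cos(yaw)`), converts to
#' the normalized image frame (origin top-left, y down) and adds isotropic
#' Gaussian jitter per coordinate. The bounding box is the envelope of the
#' keypoints padded by 2% of the image.
#'
#' Jitter draws from the current R random stream; seed control belongs to
#' the caller (see [generate_sequence()]).
#'
#' @param pose A [pose_state()].
#' @param dims A [skeleton_dims()].
#' @param noise_sd Jitter standard deviation, fraction of image width.
#' @param t_ms Timestamp for the emitted frame.
#' @return A [keypoint_frame()].
#' @export
pose_to_frame <- function(pose, dims = skeleton_dims(), noise_sd = 0, t_ms = 0L) {
  pts <- .skeleton_points(pose, dims)
  xy <- t(apply(pts, 1, .rot_yaw, theta = pose$yaw_deg))[, 1:2, drop = FALSE]
  img <- cbind(x = 0.5 + xy[, 1], y = dims$hip_y - xy[, 2])
  if (noise_sd > 0) {
    img <- img + matrix(stats::rnorm(length(img), sd = noise_sd), ncol = 2)
  }
  if (any(img < 0) || any(img > 1)) {
    warning("figure extends outside the unit image; coordinates clipped", call. = FALSE)
    img <- pmin(pmax(img, 0), 1)
  }
  pad <- 0.02
  xr <- range(img[, 1]); yr <- range(img[, 2])
  xr <- pmin(pmax(xr + c(-pad, pad), 0), 1)
  yr <- pmin(pmax(yr + c(-pad, pad), 0), 1)
  bbox <- c(mean(xr), mean(yr), diff(xr), diff(yr))
  keypoint_frame(cbind(img, v = 2), bbox = bbox, t_ms = t_ms)
}

#' Trajectory specification
#'
#' A piecewise-linear schedule for each pose-state angle: a list of
#' `(time_ms, value_deg)` knots per angle (scalars are treated as constant
#' schedules), plus frame rate and duration. Angles not mentioned stay 0.
#'
#' @param angles Named list; names are [pose_state()] argument names, values
#'   either a scalar or a 2-column matrix / list of `c(time_ms, value_deg)`
#'   knots sorted by time.
#' @param duration_ms Total duration in milliseconds.
#' @param fps Frames per second.
#' @return List of class `trajectory_spec`.
#' @export
#' @examples
#' trajectory_spec(list(head_tilt_deg = rbind(c(0, 0), c(3000, 40))),
#'                 duration_ms = 3000, fps = 25)
trajectory_spec <- function(angles = list(), duration_ms = 1000, fps = 25) {
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  if (duration_ms < 1000 / fps) stop("duration shorter than one frame", call. = FALSE)
  valid <- setdiff(names(formals(pose_state)), "")
  angles <- lapply(angles, function(a) {
    if (is.list(a)) a <- do.call(rbind, a)
    if (is.null(dim(a))) a <- cbind(c(0, duration_ms), c(a, a))
    a <- matrix(as.numeric(a), ncol = 2)
    if (is.unsorted(a[, 1])) stop("trajectory knots must be time-sorted", call. = FALSE)
    a
  })
  bad <- setdiff(names(angles), valid)
  if (length(bad)) stop("unknown angle names: ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(angles = angles, duration_ms = duration_ms, fps = fps),
            class = "trajectory_spec")
}

# evaluate all scheduled angles at time t (linear interpolation, flat ends)
.eval_spec <- function(spec, t) {
  vals <- list()
  for (nm in names(spec$angles)) {
    k <- spec$angles[[nm]]
    vals[[nm]] <- stats::approx(k[, 1], k[, 2], xout = t, rule = 2, ties = "ordered")$y
  }
  vals
}

# map a pose-state angle set to the 17 ground-truth code values (degrees)
.pose_to_code_values <- function(vals) {
  g <- function(nm) vals[[nm]] %||% 0
  c(
    LHTL = max(g("head_tilt_deg"), 0), LHTR = max(-g("head_tilt_deg"), 0),
    HRL = max(g("head_rot_deg"), 0), HRR = max(-g("head_rot_deg"), 0),
    FHT = abs(g("head_pitch_deg")),
    WSAL = g("arm_abduction_left_deg"), WSAR = g("arm_abduction_right_deg"),
    AELL = min(g("arm_abduction_left_deg"), 90),
    AELR = min(g("arm_abduction_right_deg"), 90),
    HAAL = g("leg_abduction_left_deg"), HAAR = g("leg_abduction_right_deg"),
    LELI = min(g("leg_abduction_left_deg"), 90),
    LELR = min(g("leg_abduction_right_deg"), 90),
    LTTL = max(g("trunk_tilt_deg"), 0), LTTR = max(-g("trunk_tilt_deg"), 0),
    FTIF = max(g("trunk_pitch_deg"), 0), FTIB = max(-g("trunk_pitch_deg"), 0)
  )
}

#' Generate a synthetic motion sequence with ground truth
#'
#' Samples the trajectory at `1000 / fps` millisecond intervals, renders
#' each frame with [pose_to_frame()] and returns both the (possibly noisy)
#' keypoint sequence and the noise-free scheduled angles resampled at the
#' frame times as one ground-truth trace per parameter code. Identical
#' `(seed, spec)` pairs produce bit-identical output.
#'
#' @param spec A [trajectory_spec()].
#' @param dims A [skeleton_dims()].
#' @param noise_sd Keypoint jitter sd (fraction of image width).
#' @param seed Integer seed for the jitter stream.
#' @param with_weight,subject_id Session metadata for the sequence.
#' @return List with `sequence` (a [motion_sequence()]) and `ground_truth`
#'   (named list of [parameter_trace()] objects, one per code).
#' @export
generate_sequence <- function(spec, dims = skeleton_dims(), noise_sd = 0.01,
                              seed = 1L, with_weight = FALSE, subject_id = "synthetic") {
  stopifnot(inherits(spec, "trajectory_spec"))
  dt <- 1000 / spec$fps
  n_frames <- floor(spec$duration_ms / dt + 1e-9)
  if (n_frames < 1) stop("duration shorter than one frame", call. = FALSE)
  times <- unique(as.integer(round((seq_len(n_frames) - 1) * dt)))
  if (!is.null(seed)) set.seed(seed)
  frames <- vector("list", length(times))
  truth_vals <- matrix(0, length(times), 17,
                       dimnames = list(NULL, parameter_codes()$code))
  for (i in seq_along(times)) {
    vals <- .eval_spec(spec, times[i])
    pose <- do.call(pose_state, vals)
    frames[[i]] <- pose_to_frame(pose, dims, noise_sd = noise_sd, t_ms = times[i])
    truth_vals[i, ] <- .pose_to_code_values(vals)
  }
  truth <- lapply(parameter_codes()$code, function(code) {
    parameter_trace(code, times, truth_vals[, code])
  })
  names(truth) <- parameter_codes()$code
  list(
    sequence = motion_sequence(frames, with_weight = with_weight, subject_id = subject_id),
    ground_truth = truth
  )
}

#' Generate a labeled orientation dataset
#'
#' Draws `n` standing-pose frames with orientation labels balanced to
#' within one per class. For each frame the yaw magnitude is uniform inside
#' its label's band and the facing direction (yaw sign) is a fair coin;
#' keypoints get Gaussian jitter of `config$noise_sd`.
#'
#' @param n Number of frames (>= 3).
#' @param dims A [skeleton_dims()].
#' @param config A [default_config()] (uses `yaw_bands` and `noise_sd`).
#' @param seed Integer seed.
#' @return List with `frames` (list of [keypoint_frame()]), `labels`
#'   (factor with levels [orientation_labels()]) and `yaw_deg` (signed
#'   generating yaw).
#' @export
generate_orientation_dataset <- function(n, dims = skeleton_dims(),
                                         config = default_config(), seed = 1L) {
  if (n < 3) stop("n must be at least 3", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  labs <- orientation_labels()
  counts <- rep(n %/% 3, 3) + c(rep(1, n %% 3), rep(0, 3 - n %% 3))
  labels <- factor(rep(labs, counts), levels = labs)
  yaw <- numeric(n)
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    band <- config$yaw_bands[[as.character(labels[i])]]
    mag <- stats::runif(1, band[1], band[2])
    sgn <- if (stats::runif(1) < 0.5) -1 else 1
    yaw[i] <- sgn * mag
    frames[[i]] <- pose_to_frame(pose_state(yaw_deg = yaw[i]), dims,
                                 noise_sd = config$noise_sd, t_ms = 0L)
  }
  perm <- sample.int(n)
  list(frames = frames[perm], labels = labels[perm], yaw_deg = yaw[perm])
}
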