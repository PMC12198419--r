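# Articulated skeleton model: segment tree, generalized coordinates, virtual
# markers. The default layout carries the 20 video keypoints and 43 anatomical
# markers used by the marker-enhancer models, on a skeleton whose geometry is
# parameterized by subject stature.
#
# Conventions: right-handed frame, x forward, y up (gravity -y), z to the
# subject's right. Internal units metres / radians / seconds.

#' Subject metadata
#'
#' @param subject_id character id.
#' @param height subject stature in metres (of the unscaled subject).
#' @param mass subject body mass in kg.
#' @param scale_factor uniform geometric scale; one of 0.90, 0.95, 1.00,
#'   1.05, 1.10 (the scale-augmentation grid).
#' @return an object of class `subject_meta`.
#' @export
subject_meta <- function(subject_id, height, mass, scale_factor = 1.0) {
  if (!is.numeric(height) || height <= 0 || !is.numeric(mass) || mass <= 0)
    stopf("invalid metadata: height and mass must be positive")
  scales <- c(0.90, 0.95, 1.00, 1.05, 1.10)
  if (!any(abs(scale_factor - scales) < 1e-12))
    stopf("scale_factor must be one of %s", paste(scales, collapse = ", "))
  structure(list(subject_id = as.character(subject_id), height = height,
                 mass = mass, scale_factor = scale_factor),
            class = "subject_meta")
}

#' Effective stature of a subject variant
#'
#' @param meta a [subject_meta()] object.
#' @return height times scale factor, in metres.
#' @export
effective_stature <- function(meta) meta$height * meta$scale_factor

# Fractions of stature used for the default geometry (standing zero pose,
# pelvis origin at the hip-joint midpoint). Chosen from standard anthropometry
# tables; they sum such that head-top minus foot-sole equals stature exactly.
.seg_frac <- list(
  hip_half_width = 0.0475,
  lumbar_up      = 0.100,   # pelvis origin -> lumbar joint
  neck_up        = 0.240,   # lumbar joint -> neck keypoint (torso local)
  head_top_up    = 0.370,   # lumbar joint -> head top (torso local)
  shoulder_up    = 0.188,
  shoulder_half  = 0.129,
  thigh_len      = 0.245,
  shank_len      = 0.245,
  sole_down      = 0.040,   # ankle -> sole
  upperarm_len   = 0.188,
  forearm_len    = 0.145
)

.default_coordinates <- function() {
  co <- function(name, segment, kind, axis, lower, upper)
    data.frame(name = name, segment = segment, kind = kind, axis = axis,
               lower = lower, upper = upper, stringsAsFactors = FALSE)
  rbind(
    co("pelvis_tx", "pelvis", "t", "x", -10, 10),
    co("pelvis_ty", "pelvis", "t", "y", -10, 10),
    co("pelvis_tz", "pelvis", "t", "z", -10, 10),
    co("pelvis_yaw",   "pelvis", "r", "y", -2 * pi, 2 * pi),
    co("pelvis_pitch", "pelvis", "r", "z", -2 * pi, 2 * pi),
    co("pelvis_roll",  "pelvis", "r", "x", -2 * pi, 2 * pi),
    co("lumbar_ext",  "torso", "r", "z", -0.6, 0.8),
    co("lumbar_bend", "torso", "r", "x", -0.6, 0.6),
    co("lumbar_rot",  "torso", "r", "y", -0.8, 0.8),
    co("hip_flex_r", "thigh_r", "r", "z", -0.6, 2.2),
    co("hip_add_r",  "thigh_r", "r", "x", -0.8, 0.8),
    co("hip_rot_r",  "thigh_r", "r", "y", -0.8, 0.8),
    co("hip_flex_l", "thigh_l", "r", "z", -0.6, 2.2),
    co("hip_add_l",  "thigh_l", "r", "x", -0.8, 0.8),
    co("hip_rot_l",  "thigh_l", "r", "y", -0.8, 0.8),
    co("knee_r", "shank_r", "r", "z", -2.3, 0.1),
    co("knee_l", "shank_l", "r", "z", -2.3, 0.1),
    co("ankle_r",    "foot_r", "r", "z", -0.9, 0.9),
    co("subtalar_r", "foot_r", "r", "x", -0.6, 0.6),
    co("ankle_l",    "foot_l", "r", "z", -0.9, 0.9),
    co("subtalar_l", "foot_l", "r", "x", -0.6, 0.6),
    co("shoulder_flex_r", "upperarm_r", "r", "z", -1.6, 3.0),
    co("shoulder_add_r",  "upperarm_r", "r", "x", -1.6, 1.6),
    co("shoulder_rot_r",  "upperarm_r", "r", "y", -1.6, 1.6),
    co("shoulder_flex_l", "upperarm_l", "r", "z", -1.6, 3.0),
    co("shoulder_add_l",  "upperarm_l", "r", "x", -1.6, 1.6),
    co("shoulder_rot_l",  "upperarm_l", "r", "y", -1.6, 1.6),
    co("elbow_r", "forearm_r", "r", "z", 0, 2.6),
    co("elbow_l", "forearm_l", "r", "z", 0, 2.6)
  )
}

# The 21 analysis degrees of freedom (lumbar + pelvis + lower body).
#' @export
analysis_dofs <- function() {
  c("pelvis_tx", "pelvis_ty", "pelvis_tz",
    "pelvis_yaw", "pelvis_pitch", "pelvis_roll",
    "lumbar_ext", "lumbar_bend", "lumbar_rot",
    "hip_flex_r", "hip_add_r", "hip_rot_r",
    "hip_flex_l", "hip_add_l", "hip_rot_l",
    "knee_r", "knee_l", "ankle_r", "subtalar_r", "ankle_l", "subtalar_l")
}

.default_segments <- function(H) {
  f <- .seg_frac
  seg <- function(name, parent, offset)
    list(name = name, parent = parent, offset = offset * H)
  list(
    pelvis = seg("pelvis", NA, c(0, 0, 0)),
    torso = seg("torso", "pelvis", c(0, f$lumbar_up, 0)),
    thigh_r = seg("thigh_r", "pelvis", c(0, 0, f$hip_half_width)),
    thigh_l = seg("thigh_l", "pelvis", c(0, 0, -f$hip_half_width)),
    shank_r = seg("shank_r", "thigh_r", c(0, -f$thigh_len, 0)),
    shank_l = seg("shank_l", "thigh_l", c(0, -f$thigh_len, 0)),
    foot_r = seg("foot_r", "shank_r", c(0, -f$shank_len, 0)),
    foot_l = seg("foot_l", "shank_l", c(0, -f$shank_len, 0)),
    upperarm_r = seg("upperarm_r", "torso", c(0, f$shoulder_up, f$shoulder_half)),
    upperarm_l = seg("upperarm_l", "torso", c(0, f$shoulder_up, -f$shoulder_half)),
    forearm_r = seg("forearm_r", "upperarm_r", c(0, -f$upperarm_len, 0)),
    forearm_l = seg("forearm_l", "upperarm_l", c(0, -f$upperarm_len, 0))
  )
}

.default_marker_table <- function() {
  mk <- function(name, segment, ox, oy, oz, type,
                 is_foot = FALSE, in_body = FALSE, in_arm = FALSE)
    data.frame(name = name, segment = segment, ox = ox, oy = oy, oz = oz,
               type = type, is_foot = is_foot, in_body = in_body,
               in_arm = in_arm, stringsAsFactors = FALSE)
  f <- .seg_frac
  both_sides <- function(fun) rbind(fun(+1, "r"), fun(-1, "l"))

  kp <- rbind(
    mk("kp_midhip", "pelvis", 0, 0, 0, "keypoint"),
    both_sides(function(s, sd)
      mk(paste0("kp_hip_", sd), "pelvis", 0, 0, s * f$hip_half_width,
         "keypoint", in_body = TRUE)),
    mk("kp_neck", "torso", 0, f$neck_up, 0, "keypoint",
       in_body = TRUE, in_arm = TRUE),
    both_sides(function(s, sd)
      mk(paste0("kp_shoulder_", sd), "torso", 0, f$shoulder_up,
         s * f$shoulder_half, "keypoint", in_body = TRUE, in_arm = TRUE)),
    both_sides(function(s, sd)
      mk(paste0("kp_knee_", sd), paste0("thigh_", sd), 0, -f$thigh_len, 0,
         "keypoint", in_body = TRUE)),
    both_sides(function(s, sd)
      mk(paste0("kp_ankle_", sd), paste0("shank_", sd), 0, -f$shank_len, 0,
         "keypoint", in_body = TRUE)),
    both_sides(function(s, sd)
      mk(paste0("kp_heel_", sd), paste0("foot_", sd), -0.035, -f$sole_down, 0,
         "keypoint", in_body = TRUE)),
    both_sides(function(s, sd)
      mk(paste0("kp_bigtoe_", sd), paste0("foot_", sd), 0.110, -f$sole_down,
         -s * 0.015, "keypoint", in_body = TRUE)),
    both_sides(function(s, sd)
      mk(paste0("kp_smalltoe_", sd), paste0("foot_", sd), 0.085, -f$sole_down,
         s * 0.030, "keypoint", in_body = TRUE)),
    both_sides(function(s, sd)
      mk(paste0("kp_elbow_", sd), paste0("upperarm_", sd), 0, -f$upperarm_len,
         0, "keypoint", in_arm = TRUE)),
    both_sides(function(s, sd)
      mk(paste0("kp_wrist_", sd), paste0("forearm_", sd), 0, -f$forearm_len,
         0, "keypoint", in_arm = TRUE))
  )

  body <- rbind(
    both_sides(function(s, sd)
      mk(paste0("asis_", sd), "pelvis", 0.065, 0.030, s * 0.060, "anatomical")),
    both_sides(function(s, sd)
      mk(paste0("psis_", sd), "pelvis", -0.065, 0.040, s * 0.025, "anatomical")),
    mk("c7", "torso", -0.030, 0.230, 0, "anatomical"),
    mk("t10", "torso", -0.045, 0.100, 0, "anatomical"),
    mk("clav", "torso", 0.030, 0.215, 0, "anatomical"),
    mk("strn", "torso", 0.045, 0.130, 0, "anatomical"),
    mk("back_r", "torso", -0.040, 0.170, 0.050, "anatomical"),
    both_sides(function(s, sd) rbind(
      mk(paste0("thigh1_", sd), paste0("thigh_", sd), 0.015, -0.100, s * 0.045, "anatomical"),
      mk(paste0("thigh2_", sd), paste0("thigh_", sd), 0.000, -0.150, s * 0.050, "anatomical"),
      mk(paste0("thigh3_", sd), paste0("thigh_", sd), 0.020, -0.190, s * 0.040, "anatomical"),
      mk(paste0("knee_lat_", sd), paste0("thigh_", sd), 0, -f$thigh_len, s * 0.040, "anatomical"),
      mk(paste0("knee_med_", sd), paste0("thigh_", sd), 0, -f$thigh_len, -s * 0.035, "anatomical"),
      mk(paste0("tib1_", sd), paste0("shank_", sd), 0.010, -0.080, s * 0.038, "anatomical"),
      mk(paste0("tib2_", sd), paste0("shank_", sd), 0.000, -0.130, s * 0.042, "anatomical"),
      mk(paste0("tib3_", sd), paste0("shank_", sd), 0.015, -0.170, s * 0.035, "anatomical"),
      mk(paste0("ank_lat_", sd), paste0("shank_", sd), 0, -f$shank_len, s * 0.030, "anatomical"),
      mk(paste0("ank_med_", sd), paste0("shank_", sd), 0, -f$shank_len, -s * 0.025, "anatomical"),
      mk(paste0("cal_", sd), paste0("foot_", sd), -0.045, -0.028, 0, "anatomical", is_foot = TRUE),
      mk(paste0("mt1_", sd), paste0("foot_", sd), 0.100, -0.030, -s * 0.022, "anatomical", is_foot = TRUE),
      mk(paste0("mt5_", sd), paste0("foot_", sd), 0.080, -0.030, s * 0.032, "anatomical", is_foot = TRUE)))
  )
  body$in_body <- TRUE

  arm <- both_sides(function(s, sd) rbind(
    mk(paste0("elb_lat_", sd), paste0("upperarm_", sd), 0, -f$upperarm_len, s * 0.030, "anatomical"),
    mk(paste0("elb_med_", sd), paste0("upperarm_", sd), 0, -f$upperarm_len, -s * 0.028, "anatomical"),
    mk(paste0("wrist_lat_", sd), paste0("forearm_", sd), 0, -f$forearm_len, s * 0.024, "anatomical"),
    mk(paste0("wrist_med_", sd), paste0("forearm_", sd), 0, -f$forearm_len, -s * 0.024, "anatomical")))
  arm$in_arm <- TRUE

  rbind(kp, body, arm)
}

#' Build the default skeleton for a subject
#'
#' Constructs the articulated segment tree (pelvis root with 6 degrees of
#' freedom, lumbar, hips, knees, ankles, shoulders, elbows; 29 coordinates)
#' with the default layout of 20 video keypoints and 43 anatomical markers.
#' All geometry is proportional to the subject's effective stature
#' (`height * scale_factor`), so the zero-pose head-top to foot-sole distance
#' equals it exactly.
#'
#' @param meta a [subject_meta()] object.
#' @return an object of class `skeleton_model`.
#' @export
build_default_skeleton <- function(meta) {
  if (!inherits(meta, "subject_meta")) meta <- do.call(subject_meta, meta)
  H <- effective_stature(meta)
  segments <- .default_segments(H)
  coords <- .default_coordinates()
  mt <- .default_marker_table()
  mt$ox <- mt$ox * H; mt$oy <- mt$oy * H; mt$oz <- mt$oz * H
  virtual <- list(head_top = list(segment = "torso",
                                  offset = c(0, .seg_frac$head_top_up * H, 0)))
  structure(list(segments = segments, coordinates = coords, markers = mt,
                 virtual = virtual, meta = meta),
            class = "skeleton_model")
}

#' Uniformly scale a skeleton
#'
#' Multiplies every segment joint offset and marker offset by `factor`;
#' coordinates (names, bounds) are unchanged. Composition of scalings is the
#' scaling by the product of factors.
#'
#' @param skeleton a `skeleton_model`.
#' @param factor positive scale factor.
#' @return the scaled `skeleton_model`.
#' @export
scale_skeleton <- function(skeleton, factor) {
  if (!is.numeric(factor) || factor <= 0) stopf("scale factor must be > 0")
  skeleton$segments <- lapply(skeleton$segments, function(s) {
    s$offset <- s$offset * factor
    s
  })
  skeleton$markers$ox <- skeleton$markers$ox * factor
  skeleton$markers$oy <- skeleton$markers$oy * factor
  skeleton$markers$oz <- skeleton$markers$oz * factor
  skeleton$virtual <- lapply(skeleton$virtual, function(v) {
    v$offset <- v$offset * factor
    v
  })
  skeleton
}

#' Zero-pose stature of a skeleton
#'
#' Head-top to foot-sole vertical distance in the zero pose.
#'
#' @param skeleton a `skeleton_model`.
#' @return stature in metres.
#' @export
skeleton_stature <- function(skeleton) {
  q <- stats::setNames(rep(0, nrow(skeleton$coordinates)),
                       skeleton$coordinates$name)
  fr <- fk_frame(skeleton, q)
  ht <- skeleton$virtual$head_top
  top <- (fr$R[[ht$segment]] %*% ht$offset + fr$p[[ht$segment]])[2]
  pos <- fk_markers(skeleton, fr)
  top - min(pos[, 2])
}

#' Marker names of a skeleton, optionally filtered by role
#'
#' @param skeleton a `skeleton_model`.
#' @param type `"keypoint"`, `"anatomical"`, or `NULL` for all.
#' @return character vector of marker names in canonical order.
#' @export
marker_names <- function(skeleton, type = NULL) {
  mt <- skeleton$markers
  if (!is.null(type)) mt <- mt[mt$type == type, ]
  mt$name
}

# Single-frame forward kinematics: world rotation and origin per segment,
# plus per-coordinate world axis/point for Jacobian assembly.
fk_frame <- function(skeleton, q) {
  co <- skeleton$coordinates
  R <- list(); p <- list()
  dof_axis <- matrix(0, nrow(co), 3)
  dof_point <- matrix(0, nrow(co), 3)
  axis_vec <- list(x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  for (s in skeleton$segments) {
    if (is.na(s$parent)) {
      Rc <- diag(3); pc <- c(0, 0, 0)
    } else {
      Rc <- R[[s$parent]]
      pc <- p[[s$parent]] + as.vector(Rc %*% s$offset)
    }
    idx <- which(co$segment == s$name)
    for (i in idx) {
      a <- axis_vec[[co$axis[i]]]
      wa <- as.vector(Rc %*% a)
      if (co$kind[i] == "t") {
        dof_axis[i, ] <- wa
        pc <- pc + wa * q[[co$name[i]]]
      } else {
        dof_axis[i, ] <- wa
        dof_point[i, ] <- pc
        Rc <- Rc %*% rot_axis(a, q[[co$name[i]]])
      }
    }
    R[[s$name]] <- Rc
    p[[s$name]] <- pc
  }
  list(R = R, p = p, dof_axis = dof_axis, dof_point = dof_point)
}

# Marker world positions for one resolved frame.
fk_markers <- function(skeleton, frame, markers = NULL) {
  mt <- skeleton$markers
  if (!is.null(markers)) mt <- mt[match(markers, mt$name), ]
  out <- matrix(0, nrow(mt), 3, dimnames = list(mt$name, c("x", "y", "z")))
  for (i in seq_len(nrow(mt))) {
    sg <- mt$segment[i]
    out[i, ] <- frame$R[[sg]] %*% c(mt$ox[i], mt$oy[i], mt$oz[i]) +
      frame$p[[sg]]
  }
  out
}

#' Forward kinematics of a joint trajectory
#'
#' Computes world positions of all skeleton markers for each frame of a joint
#' trajectory. Markers attached to the same segment keep constant pairwise
#' distances across frames (rigid-body property).
#'
#' @param skeleton a `skeleton_model`.
#' @param traj a [joint_trajectory()] whose coordinates match the skeleton's.
#' @param movement_class movement label carried into the output sequence.
#' @return a [motion_sequence()] with all 63 markers.
#' @export
forward_kinematics <- function(skeleton, traj, movement_class = "freestyle") {
  if (!identical(traj$coordinates, skeleton$coordinates$name))
    stopf("trajectory coordinates do not match skeleton coordinates")
  n <- nrow(traj$values)
  mnames <- skeleton$markers$name
  pos <- array(0, dim = c(n, length(mnames), 3),
               dimnames = list(NULL, mnames, c("x", "y", "z")))
  for (fidx in seq_len(n)) {
    q <- stats::setNames(traj$values[fidx, ], traj$coordinates)
    fr <- fk_frame(skeleton, q)
    pos[fidx, , ] <- fk_markers(skeleton, fr)
  }
  motion_sequence(rate = traj$rate, positions = pos, meta = skeleton$meta,
                  movement_class = movement_class)
}

#' Joint trajectory container
#'
#' @param rate sampling rate in Hz.
#' @param coordinates character vector of coordinate names.
#' @param values frames x coordinates numeric matrix (radians / metres).
#' @return an object of class `joint_trajectory`.
#' @export
joint_trajectory <- function(rate, coordinates, values) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stopf("joint trajectory has non-finite values")
  if (ncol(values) != length(coordinates))
    stopf("values/coordinates dimension mismatch")
  colnames(values) <- coordinates
  structure(list(rate = rate, coordinates = coordinates, values = values),
            class = "joint_trajectory")
}

#' Motion sequence container
#'
#' Time-stamped 3-D trajectories for a named marker set with subject metadata.
#'
#' @param rate sampling rate in Hz.
#' @param positions frames x markers x 3 array (metres) with marker dimnames.
#' @param meta a [subject_meta()].
#' @param movement_class one of gait, squat, sit_to_stand, jump, rolling,
#'   freestyle, static.
#' @return an object of class `motion_sequence`.
#' @export
motion_sequence <- function(rate, positions, meta,
                            movement_class = c("freestyle", "gait", "squat",
                                               "sit_to_stand", "jump",
                                               "rolling", "static")) {
  movement_class <- match.arg(movement_class)
  if (!all(is.finite(positions))) stopf("positions contain non-finite values")
  structure(list(rate = rate, marker_names = dimnames(positions)[[2]],
                 positions = positions, meta = meta,
                 movement_class = movement_class),
            class = "motion_sequence")
}

#' @exportS3Method base::print
print.motion_sequence <- function(x, ...) {
  cat(sprintf("<motion_sequence> %d frames @ %g Hz, %d markers, class=%s, subject=%s\n",
              dim(x$positions)[1], x$rate, dim(x$positions)[2],
              x$movement_class, x$meta$subject_id %||% "?"))
  invisible(x)
}

#' @exportS3Method base::print
print.skeleton_model <- function(x, ...) {
  cat(sprintf("<skeleton_model> %d segments, %d coordinates, %d markers (stature %.3f m)\n",
              length(x$segments), nrow(x$coordinates), nrow(x$markers),
              skeleton_stature(x)))
  invisible(x)
}
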