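# Joint-angle conventions and frame-wise kinematic metrics.
#
# Conventions (all angles in degrees, 0 at anatomical neutral):
#   * hip flexion   : 180 minus the angle between the trunk vector
#                     (spine_base -> spine_shoulder) and the thigh vector
#                     (hip -> knee), folded to [0, 180]. Standing straight
#                     gives 0; thigh perpendicular to the trunk gives 90.
#   * knee flexion  : 180 minus the interior angle at the knee between
#                     (hip - knee) and (foot - knee).
#   * hip ab/adduction: frontal-plane (x-y) angle between the thigh and the
#                     downward trunk axis; abduction is movement away from
#                     the midline, adduction toward it.
#   * trunk lean    : frontal-plane angle between the trunk vector and the
#                     vertical (y) axis; pure sagittal tilt projects to 0.

.joint_idx <- function(name) match(name, joint_names())

#' @keywords internal
frame_xyz <- function(sequence, frame, joint) {
  v <- sequence$xyz[frame, .joint_idx(joint), ]
  if (any(is.na(v))) {
    abort_exergauge(
      sprintf("marker '%s' missing at frame %d", joint, frame),
      "exergauge_missing_data_error")
  }
  v
}

#' Joint angle at a single frame
#'
#' Computes a named joint angle from the marker positions of one frame,
#' using the package's angle conventions (see Details). Supported names
#' are `hip_flexion_l`/`_r`, `knee_flexion_l`/`_r`, `hip_abduction_l`/`_r`
#' and `hip_adduction_l`/`_r`.
#'
#' @details Flexion angles are 0 degrees at anatomical neutral (standing
#' straight) and grow as the segment moves away from neutral; hip
#' abduction/adduction are measured in the frontal plane relative to the
#' trunk axis, so sagittal movement does not register.
#'
#' @param sequence A [skeleton_sequence].
#' @param frame Frame index.
#' @param angle_name One of the supported angle labels.
#' @return Angle in degrees.
#' @export
#' @examples
#' seq <- simulate_skeleton(motion_profile("squat", n_reps = 1,
#'                                         peak_angle = 90, seed = 1))
#' joint_angle(seq, which.max(compute_metric(seq, "chest_drop")),
#'             "knee_flexion_l")
joint_angle <- function(sequence, frame, angle_name) {
  stopifnot(inherits(sequence, "skeleton_sequence"))
  side <- sub(".*_(l|r)$", "\\1", angle_name)
  base <- sub("_(l|r)$", "", angle_name)
  if (!side %in% c("l", "r") || !base %in%
      c("hip_flexion", "knee_flexion", "hip_abduction", "hip_adduction")) {
    abort_exergauge(sprintf("unknown angle name: %s", angle_name),
                    "exergauge_config_error")
  }
  hip <- frame_xyz(sequence, frame, paste0("hip_", side))
  knee <- frame_xyz(sequence, frame, paste0("knee_", side))
  trunk <- frame_xyz(sequence, frame, "spine_shoulder") -
    frame_xyz(sequence, frame, "spine_base")
  thigh <- knee - hip
  if (base == "hip_flexion") {
    ang <- 180 - vector_angle_deg(trunk, thigh)
    return(abs(ang))
  }
  if (base == "knee_flexion") {
    foot <- frame_xyz(sequence, frame, paste0("foot_", side))
    return(180 - vector_angle_deg(hip - knee, foot - knee))
  }
  # frontal-plane thigh angle, relative to the downward trunk axis
  down <- -trunk
  thigh_f <- c(thigh[1], thigh[2])
  down_f <- c(down[1], down[2])
  ang <- vector_angle_deg(c(thigh_f, 0), c(down_f, 0))
  if (is.na(ang)) return(0)
  # sign: abduction moves the knee laterally outward from the hip
  outward <- if (side == "l") -1 else 1
  lateral <- (thigh[1] - down[1] * sum(thigh_f * down_f) /
                max(sum(down_f^2), 1e-12)) * outward
  if (base == "hip_abduction") {
    if (lateral >= 0) ang else 0
  } else {
    if (lateral < 0) ang else 0
  }
}

#' Lateral trunk lean at a single frame
#'
#' Angle between the spine vector (spine_base to spine_shoulder) and the
#' vertical axis after projecting onto the frontal (x-y) plane. A purely
#' sagittal (forward/backward) tilt therefore reads as 0.
#'
#' @inheritParams joint_angle
#' @return Lean angle in degrees, non-negative.
#' @export
trunk_lean <- function(sequence, frame) {
  trunk <- frame_xyz(sequence, frame, "spine_shoulder") -
    frame_xyz(sequence, frame, "spine_base")
  vector_angle_deg(c(trunk[1], trunk[2], 0), c(0, 1, 0))
}

# -- frame-wise metric series -------------------------------------------------

#' @keywords internal
.col <- function(sequence, joint, axis) {
  sequence$xyz[, .joint_idx(joint), axis]
}

# Baseline posture value: median over the first up-to-10 non-missing frames.
#' @keywords internal
.baseline <- function(v, n = 10L) {
  ok <- which(!is.na(v))
  if (length(ok) == 0) return(NA_real_)
  stats::median(v[ok[seq_len(min(n, length(ok)))]])
}

#' Frame-wise kinematic metric series
#'
#' Computes one of the named kinematic metrics used by the attempt and
#' quality rules, as a numeric vector with one value per frame (`NA` where
#' required markers are missing). Angle metrics are in degrees,
#' displacement metrics in meters. Available metrics:
#'
#' * `hip_flexion_l/r/max/min`, `knee_flexion_l/r/max/min`,
#'   `hip_abduction_l/r/max`, `hip_adduction_l/r/max`: joint angles per
#'   [joint_angle()], `max`/`min` taken across sides.
#' * `trunk_lean`: lateral trunk lean per [trunk_lean()].
#' * `chest_drop`: downward vertical displacement of the spine_shoulder
#'   marker from its baseline posture.
#' * `chest_anterior`: displacement of spine_shoulder toward the camera
#'   from baseline.
#' * `foot_offset_z`: anterior-posterior separation of the two feet
#'   (staggered-stance magnitude).
#' * `foot_beyond_shoulder`: largest lateral excess of a foot beyond the
#'   same-side shoulder.
#' * `foot_lift`: largest rise of a foot above its baseline height.
#' * `foot_separation_x`, `shoulder_separation_x`: lateral separations.
#' * `star_excursion`: the smaller of the best arm and best foot lateral
#'   excursion from baseline (both an arm and a foot must move).
#' * `foot_anterior`: largest anterior lead of a foot relative to the
#'   pelvis (spine_base).
#'
#' @param sequence A [skeleton_sequence].
#' @param metric Metric name.
#' @return Numeric vector, one value per frame.
#' @export
compute_metric <- function(sequence, metric) {
  stopifnot(inherits(sequence, "skeleton_sequence"))
  n <- length(sequence$frame_times)
  per_frame_angle <- function(name) {
    vapply(seq_len(n), function(f) {
      tryCatch(joint_angle(sequence, f, name),
               exergauge_missing_data_error = function(e) NA_real_)
    }, numeric(1))
  }
  pair <- function(base, agg) {
    l <- per_frame_angle(paste0(base, "_l"))
    r <- per_frame_angle(paste0(base, "_r"))
    agg(l, r)
  }
  pmax2 <- function(a, b) pmax(a, b)
  pmin2 <- function(a, b) pmin(a, b)
  switch(
    metric,
    hip_flexion_l = per_frame_angle("hip_flexion_l"),
    hip_flexion_r = per_frame_angle("hip_flexion_r"),
    hip_flexion_max = pair("hip_flexion", pmax2),
    hip_flexion_min = pair("hip_flexion", pmin2),
    knee_flexion_l = per_frame_angle("knee_flexion_l"),
    knee_flexion_r = per_frame_angle("knee_flexion_r"),
    knee_flexion_max = pair("knee_flexion", pmax2),
    knee_flexion_min = pair("knee_flexion", pmin2),
    hip_abduction_l = per_frame_angle("hip_abduction_l"),
    hip_abduction_r = per_frame_angle("hip_abduction_r"),
    hip_abduction_max = pair("hip_abduction", pmax2),
    hip_adduction_l = per_frame_angle("hip_adduction_l"),
    hip_adduction_r = per_frame_angle("hip_adduction_r"),
    hip_adduction_max = pair("hip_adduction", pmax2),
    trunk_lean = vapply(seq_len(n), function(f) {
      tryCatch(trunk_lean(sequence, f),
               exergauge_missing_data_error = function(e) NA_real_)
    }, numeric(1)),
    chest_drop = {
      y <- .col(sequence, "spine_shoulder", "y")
      .baseline(y) - y
    },
    chest_anterior = {
      z <- .col(sequence, "spine_shoulder", "z")
      .baseline(z) - z
    },
    foot_offset_z = abs(.col(sequence, "foot_l", "z") -
                          .col(sequence, "foot_r", "z")),
    foot_beyond_shoulder = {
      l <- .col(sequence, "shoulder_l", "x") - .col(sequence, "foot_l", "x")
      r <- .col(sequence, "foot_r", "x") - .col(sequence, "shoulder_r", "x")
      pmax(l, r)
    },
    foot_lift = {
      yl <- .col(sequence, "foot_l", "y"); yr <- .col(sequence, "foot_r", "y")
      pmax(yl - .baseline(yl), yr - .baseline(yr))
    },
    foot_separation_x = abs(.col(sequence, "foot_l", "x") -
                              .col(sequence, "foot_r", "x")),
    shoulder_separation_x = abs(.col(sequence, "shoulder_l", "x") -
                                  .col(sequence, "shoulder_r", "x")),
    star_excursion = {
      arm <- pmax(abs(.col(sequence, "wrist_l", "x") -
                        .baseline(.col(sequence, "wrist_l", "x"))),
                  abs(.col(sequence, "wrist_r", "x") -
                        .baseline(.col(sequence, "wrist_r", "x"))))
      foot <- pmax(abs(.col(sequence, "foot_l", "x") -
                         .baseline(.col(sequence, "foot_l", "x"))),
                   abs(.col(sequence, "foot_r", "x") -
                         .baseline(.col(sequence, "foot_r", "x"))))
      pmin(arm, foot)
    },
    foot_anterior = {
      zb <- .col(sequence, "spine_base", "z")
      pmax(zb - .col(sequence, "foot_l", "z"),
           zb - .col(sequence, "foot_r", "z"))
    },
    abort_exergauge(sprintf("unknown metric: %s", metric),
                    "exergauge_config_error")
  )
}
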