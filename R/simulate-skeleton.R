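# Synthetic skeleton streams.
#
# Each exercise is generated by driving one or two "driver" joint angles
# with a raised-cosine pulse per repetition and solving segment positions
# on a fixed-length kinematic chain (trunk 0.45 m, thigh 0.40 m, shank
# 0.40 m by default, child-scaled configurable). Camera noise is additive
# isotropic Gaussian on joint positions (meters); tracking dropouts are
# whole-frame missing markers.

#' Motion profile for a synthetic exercise bout
#'
#' Parameters of one simulated exercise stream: which exercise, how many
#' repetitions, their period, the peak and baseline driver angles, camera
#' noise, dropout rate and the RNG seed. Identical profiles (including
#' seed) always produce bit-identical streams.
#'
#' @param exercise_name One of [supported_exercises()].
#' @param n_reps Number of repetitions to generate (0 gives a constant
#'   standing/seated posture).
#' @param rep_period Duration of one repetition in seconds (> 0).
#' @param peak_angle Peak driver angle in degrees reached mid-repetition.
#' @param baseline_angle Driver angle in degrees between repetitions
#'   (must be below `peak_angle` when `n_reps > 0`).
#' @param noise_sd Isotropic Gaussian position noise SD in meters.
#' @param dropout_rate Per-frame probability that the whole frame's
#'   markers are missing, in [0, 1].
#' @param hold_s For timed exercises: plateau duration in seconds held at
#'   the peak posture within each repetition (0 = pure pulse).
#' @param seed Integer RNG seed.
#' @param fps Frame rate (frames/second), default 30.
#' @param segment_lengths Named list overriding the default body segment
#'   lengths in meters (`trunk`, `thigh`, `shank`, `upper_arm`,
#'   `forearm`, `hip_half_width`, `shoulder_half_width`).
#' @return An object of class `motion_profile`.
#' @export
#' @examples
#' motion_profile("hip_flexion", n_reps = 3, peak_angle = 45, seed = 7)
motion_profile <- function(exercise_name, n_reps = 5L, rep_period = 3,
                           peak_angle = 45, baseline_angle = 0,
                           noise_sd = 0, dropout_rate = 0, hold_s = 0,
                           seed = 1L, fps = 30,
                           segment_lengths = list()) {
  get_exercise(exercise_name)  # validates the name
  stopifnot(is_count(n_reps), rep_period > 0, noise_sd >= 0,
            dropout_rate >= 0, dropout_rate <= 1, hold_s >= 0, fps > 0)
  if (n_reps > 0 && peak_angle <= baseline_angle) {
    abort_exergauge("peak_angle must exceed baseline_angle for dynamic reps",
                    "exergauge_config_error")
  }
  seg <- utils::modifyList(
    list(trunk = 0.45, thigh = 0.40, shank = 0.40,
         upper_arm = 0.26, forearm = 0.24,
         hip_half_width = 0.10, shoulder_half_width = 0.18),
    segment_lengths)
  structure(
    list(exercise_name = exercise_name, n_reps = as.integer(n_reps),
         rep_period = rep_period, peak_angle = peak_angle,
         baseline_angle = baseline_angle, noise_sd = noise_sd,
         dropout_rate = dropout_rate, hold_s = hold_s,
         seed = as.integer(seed), fps = fps, seg = seg),
    class = "motion_profile")
}

# Standing base pose for the given segment lengths. Camera at the origin
# looking down +z; the child stands at z = 2.5 m facing the camera, so
# anterior movement decreases z. `stance_half` widens the feet/knees/hips
# (squat-family exercises start feet shoulder width apart).
#' @keywords internal
base_pose <- function(seg, stance_half = seg$hip_half_width, z0 = 2.5) {
  leg <- seg$thigh + seg$shank
  hy <- leg                      # hip height
  p <- matrix(NA_real_, 19, 3, dimnames = list(joint_names(), c("x", "y", "z")))
  sw <- seg$shoulder_half_width
  p["spine_base", ] <- c(0, hy, z0)
  p["spine_mid", ] <- c(0, hy + seg$trunk / 2, z0)
  p["spine_shoulder", ] <- c(0, hy + seg$trunk, z0)
  p["neck", ] <- c(0, hy + seg$trunk + 0.05, z0)
  p["head", ] <- c(0, hy + seg$trunk + 0.20, z0)
  p["shoulder_l", ] <- c(-sw, hy + seg$trunk, z0)
  p["shoulder_r", ] <- c(sw, hy + seg$trunk, z0)
  for (s in c("l", "r")) {
    sgn <- if (s == "l") -1 else 1
    sh <- p[paste0("shoulder_", s), ]
    p[paste0("elbow_", s), ] <- sh + c(0, -seg$upper_arm, 0)
    p[paste0("wrist_", s), ] <- sh + c(0, -seg$upper_arm - seg$forearm, 0)
    p[paste0("hand_", s), ] <- sh + c(0, -seg$upper_arm - seg$forearm - 0.08, 0)
    p[paste0("hip_", s), ] <- c(sgn * stance_half, hy, z0)
    p[paste0("knee_", s), ] <- c(sgn * stance_half, seg$shank, z0)
    p[paste0("foot_", s), ] <- c(sgn * stance_half, 0, z0)
  }
  p
}

# Rotate a full (straight) leg of `side` about its hip. `theta_deg` is the
# sagittal rotation (positive = anterior, negative = posterior);
# `frontal_deg` the frontal-plane rotation (positive = abduction outward,
# negative = adduction toward the midline).
#' @keywords internal
rotate_leg <- function(pose, seg, side, theta_deg = 0, frontal_deg = 0) {
  sgn <- if (side == "l") -1 else 1   # outward x direction
  th <- deg2rad(theta_deg); fr <- deg2rad(frontal_deg)
  dir <- c(sgn * tan(fr) * cos(th), -cos(th), -sin(th))
  dir <- dir / sqrt(sum(dir^2))
  hip <- pose[paste0("hip_", side), ]
  pose[paste0("knee_", side), ] <- hip + dir * seg$thigh
  pose[paste0("foot_", side), ] <- hip + dir * (seg$thigh + seg$shank)
  pose
}

# Symmetric crouch (squat / sit-to-stand): both knees and hips flex by
# `gamma_deg` with the trunk kept vertical, shanks vertical over fixed
# feet, and the pelvis translating down and backward.
#' @keywords internal
crouch_pose <- function(pose, seg, gamma_deg) {
  g <- deg2rad(gamma_deg)
  drop <- seg$thigh * (1 - cos(g))
  back <- seg$thigh * sin(g)
  upper <- c("head", "neck", "spine_shoulder", "spine_mid", "spine_base",
             "shoulder_l", "elbow_l", "wrist_l", "hand_l",
             "shoulder_r", "elbow_r", "wrist_r", "hand_r",
             "hip_l", "hip_r")
  pose[upper, 2] <- pose[upper, 2] - drop
  pose[upper, 3] <- pose[upper, 3] + back
  pose
}

# Forward trunk pitch about spine_base (hamstring stretch reach).
#' @keywords internal
trunk_pitch_pose <- function(pose, seg, phi_deg) {
  phi <- deg2rad(phi_deg)
  base <- pose["spine_base", ]
  upper <- c("head", "neck", "spine_shoulder", "spine_mid",
             "shoulder_l", "elbow_l", "wrist_l", "hand_l",
             "shoulder_r", "elbow_r", "wrist_r", "hand_r")
  rel <- sweep(pose[upper, , drop = FALSE], 2, base)
  out <- rel
  # rigid rotation about the x axis, tipping the trunk toward the camera
  out[, 2] <- rel[, 2] * cos(phi) + rel[, 3] * sin(phi)
  out[, 3] <- -rel[, 2] * sin(phi) + rel[, 3] * cos(phi)
  pose[upper, ] <- sweep(out, 2, base, `+`)
  pose
}

# Lateral arm raise (seated star jump upper limb component).
#' @keywords internal
raise_arm_pose <- function(pose, seg, side, theta_deg) {
  sgn <- if (side == "l") -1 else 1
  th <- deg2rad(theta_deg)
  sh <- pose[paste0("shoulder_", side), ]
  dir <- c(sgn * sin(th), -cos(th), 0)
  pose[paste0("elbow_", side), ] <- sh + dir * seg$upper_arm
  pose[paste0("wrist_", side), ] <- sh + dir * (seg$upper_arm + seg$forearm)
  pose[paste0("hand_", side), ] <- sh + dir * (seg$upper_arm + seg$forearm + 0.08)
  pose
}

# Pose for one exercise at driver angle `theta` (degrees) on `side`.
#' @keywords internal
exercise_pose <- function(exercise_name, seg, theta, side) {
  stance <- if (exercise_name %in% c("squat", "sit_to_stand"))
    seg$shoulder_half_width else seg$hip_half_width
  pose <- base_pose(seg, stance_half = stance)
  switch(
    exercise_name,
    hip_flexion = rotate_leg(pose, seg, side, theta_deg = theta),
    kick = rotate_leg(pose, seg, side, theta_deg = theta),
    forward_step = rotate_leg(pose, seg, side, theta_deg = theta),
    single_leg_stance = rotate_leg(pose, seg, side, theta_deg = theta),
    backward_step = rotate_leg(pose, seg, side, theta_deg = -theta),
    calf_stretch = rotate_leg(pose, seg, side, theta_deg = -theta),
    hip_abduction = rotate_leg(pose, seg, side, frontal_deg = theta),
    lateral_step = rotate_leg(pose, seg, side, frontal_deg = theta),
    tandem_stance = rotate_leg(pose, seg, side, theta_deg = theta,
                               frontal_deg = -7),
    squat = crouch_pose(pose, seg, theta),
    sit_to_stand = crouch_pose(pose, seg, theta),
    hamstring_stretch = trunk_pitch_pose(pose, seg, theta),
    seated_star_jump = {
      pose <- raise_arm_pose(pose, seg, side, theta)
      rotate_leg(pose, seg, side, frontal_deg = theta)
    },
    abort_exergauge(sprintf("unsupported exercise: %s", exercise_name),
                    "exergauge_unsupported_exercise_error")
  )
}

#' Simulate a skeleton stream for one exercise bout
#'
#' Generates a 30 frames/s (configurable) stream whose noiseless driver
#' angle trace rises from `baseline_angle` to `peak_angle` exactly
#' `n_reps` times (raised-cosine pulse per repetition, optional plateau
#' for timed exercises) and returns to baseline between repetitions.
#' Additive Gaussian noise and whole-frame dropouts are applied after the
#' noiseless geometry is solved.
#'
#' @param profile A [motion_profile].
#' @return A [skeleton_sequence].
#' @export
#' @examples
#' prof <- motion_profile("hip_flexion", n_reps = 3, peak_angle = 45, seed = 1)
#' sk <- simulate_skeleton(prof)
#' length(detect_attempts(sk, "hip_flexion"))
simulate_skeleton <- function(profile) {
  stopifnot(inherits(profile, "motion_profile"))
  fps <- profile$fps
  pad <- 0.5                                     # rest pads either side
  rep_dur <- profile$rep_period + profile$hold_s
  dur <- max(1, profile$n_reps * rep_dur + 2 * pad)
  t <- seq(0, dur, by = 1 / fps)
  n <- length(t)
  bilateral <- get_exercise(profile$exercise_name)$laterality == "bilateral"

  theta <- rep(profile$baseline_angle, n)
  side <- rep("l", n)
  if (profile$n_reps > 0) {
    for (k in seq_len(profile$n_reps)) {
      t0 <- pad + (k - 1) * rep_dur
      in_up <- t >= t0 & t < t0 + profile$rep_period / 2
      in_hold <- t >= t0 + profile$rep_period / 2 &
        t < t0 + profile$rep_period / 2 + profile$hold_s
      in_down <- t >= t0 + profile$rep_period / 2 + profile$hold_s &
        t <= t0 + rep_dur
      u_up <- (t[in_up] - t0) / profile$rep_period
      u_dn <- (t[in_down] - t0 - profile$hold_s) / profile$rep_period
      amp <- function(u) 0.5 * (1 - cos(2 * pi * u))
      rng <- profile$peak_angle - profile$baseline_angle
      theta[in_up] <- profile$baseline_angle + rng * amp(u_up)
      theta[in_hold] <- profile$peak_angle
      theta[in_down] <- profile$baseline_angle + rng * amp(u_dn)
      rep_frames <- in_up | in_hold | in_down
      side[rep_frames] <- if (bilateral && k %% 2 == 0) "r" else "l"
    }
  }

  xyz <- array(NA_real_, c(n, 19, 3))
  for (f in seq_len(n)) {
    xyz[f, , ] <- exercise_pose(profile$exercise_name, profile$seg,
                                theta[f], side[f])
  }

  with_seed(profile$seed, {
    if (profile$noise_sd > 0) {
      xyz <- xyz + stats::rnorm(length(xyz), sd = profile$noise_sd)
    }
    if (profile$dropout_rate > 0) {
      drop <- stats::runif(n) < profile$dropout_rate
      xyz[drop, , ] <- NA_real_
    }
  })
  skeleton_sequence(t, xyz)
}
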