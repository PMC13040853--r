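# Joint angles, repetition detection, quality rules, hold timing and
# speed warnings.

test_that("standing straight gives zero hip flexion and trunk lean", {
  sk <- static_skeleton(standing_coords())
  expect_equal(joint_angle(sk, 1, "hip_flexion_l"), 0, tolerance = 1e-8)
  expect_equal(joint_angle(sk, 1, "knee_flexion_r"), 0, tolerance = 1e-8)
  expect_equal(trunk_lean(sk, 1), 0, tolerance = 1e-8)
})

test_that("a thigh perpendicular to the trunk reads 90 degrees hip flexion", {
  coords <- standing_coords()
  # move the left knee (and foot) straight anterior at hip height
  hip <- coords["hip_l", ]
  coords["knee_l", ] <- hip + c(0, 0, -0.40)
  coords["foot_l", ] <- hip + c(0, -0.40, -0.40)
  sk <- static_skeleton(coords)
  expect_equal(joint_angle(sk, 1, "hip_flexion_l"), 90, tolerance = 1e-8)
})

test_that("joint angles match a direct dot-product/arccos oracle", {
  coords <- standing_coords()
  set.seed(31)
  for (i in 1:10) {
    # random (but leg-like) marker placements
    coords["knee_l", ] <- coords["hip_l", ] +
      0.4 * rnorm(3) / sqrt(sum(rnorm(3)^2))  # random direction
    coords["foot_l", ] <- coords["knee_l", ] + 0.4 * rnorm(3)
    sk <- static_skeleton(coords)
    trunk <- coords["spine_shoulder", ] - coords["spine_base", ]
    thigh <- coords["knee_l", ] - coords["hip_l", ]
    oracle <- 180 - acos(sum(trunk * thigh) /
                           sqrt(sum(trunk^2) * sum(thigh^2))) * 180 / pi
    expect_equal(joint_angle(sk, 1, "hip_flexion_l"), abs(oracle),
                 tolerance = 1e-8)
    shank <- coords["foot_l", ] - coords["knee_l", ]
    oracle_knee <- 180 - acos(sum(-thigh * shank) /
                                sqrt(sum(thigh^2) * sum(shank^2))) * 180 / pi
    expect_equal(joint_angle(sk, 1, "knee_flexion_l"), oracle_knee,
                 tolerance = 1e-8)
  }
})

test_that("trunk lean measures frontal-plane tilt only", {
  coords <- standing_coords()
  base <- coords["spine_base", ]
  trunk_len <- coords["spine_shoulder", "y"] - base["y"]
  # 15 degrees lateral tilt
  coords["spine_shoulder", ] <- base +
    c(sin(15 * pi / 180), cos(15 * pi / 180), 0) * trunk_len
  expect_equal(trunk_lean(static_skeleton(coords), 1), 15, tolerance = 1e-8)
  # pure sagittal (forward) tilt projects to zero lateral lean
  coords["spine_shoulder", ] <- base +
    c(0, cos(20 * pi / 180), -sin(20 * pi / 180)) * trunk_len
  expect_equal(trunk_lean(static_skeleton(coords), 1), 0, tolerance = 1e-8)
})

test_that("noiseless streams recover the constructed repetition count", {
  for (ex in supported_exercises()) {
    peak <- if (ex %in% c("squat", "sit_to_stand")) 90 else 45
    for (reps in c(1L, 3L)) {
      sk <- simulate_skeleton(motion_profile(ex, n_reps = reps,
                                             peak_angle = peak, seed = 1))
      expect_length(detect_attempts(sk, ex), reps)
    }
  }
})

test_that("excursions below the attempt threshold are not counted", {
  sk <- simulate_skeleton(motion_profile("hip_flexion", n_reps = 3,
                                         peak_angle = 19.5, seed = 1))
  expect_length(detect_attempts(sk, "hip_flexion"), 0)
})

test_that("raising the attempt threshold never increases the count", {
  sk <- simulate_skeleton(motion_profile("hip_flexion", n_reps = 4,
                                         peak_angle = 45, noise_sd = 0.005,
                                         seed = 7))
  counts <- vapply(c(20, 30, 40, 44, 50), function(thr) {
    ex <- exercise_library()$hip_flexion
    ex$attempt_rules[[1]]$threshold <- thr
    length(detect_attempts(sk, ex))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("small dropout rates do not change noiseless attempt counts", {
  for (ex in c("hip_flexion", "squat", "kick")) {
    peak <- if (ex == "squat") 90 else 45
    sk <- simulate_skeleton(motion_profile(ex, n_reps = 4, peak_angle = peak,
                                           dropout_rate = 0.05, seed = 13))
    expect_length(detect_attempts(sk, ex), 4)
  }
})

test_that("deep well-formed squats pass all quality rules", {
  sk <- simulate_skeleton(motion_profile("squat", n_reps = 3,
                                         peak_angle = 90, seed = 1))
  ev <- detect_attempts(sk, "squat")
  q <- lapply(ev, assess_quality, sequence = sk, exercise = "squat")
  expect_true(all(vapply(q, `[[`, logical(1), "quality")))
  expect_true(all(lengths(lapply(q, `[[`, "failed_criteria")) == 0))
})

test_that("shallow squats fail the depth rules and only those", {
  sk <- simulate_skeleton(motion_profile("squat", n_reps = 2,
                                         peak_angle = 55, seed = 1))
  ev <- detect_attempts(sk, "squat")
  expect_length(ev, 2)  # 55 degrees is still an attempt
  q <- assess_quality(ev[[1]], sk, "squat")
  expect_false(q$quality)
  expect_setequal(q$failed_criteria, c("squat_depth_hip", "squat_depth_knee"))
})

test_that("quality repetitions are a subset of attempts", {
  sk <- simulate_skeleton(motion_profile("squat", n_reps = 3,
                                         peak_angle = 80, noise_sd = 0.005,
                                         seed = 5))
  ev <- detect_attempts(sk, "squat")
  q <- vapply(ev, function(e) assess_quality(e, sk, "squat")$quality,
              logical(1))
  expect_lte(sum(q), length(ev))
})

test_that("a held tandem stance meeting the front-leg criteria is high quality", {
  lib <- exercise_library(prescribed_time = 10)
  sk <- simulate_skeleton(motion_profile("tandem_stance", n_reps = 1,
                                         rep_period = 2, peak_angle = 25,
                                         hold_s = 12, seed = 2))
  ev <- detect_attempts(sk, lib$tandem_stance)
  q <- assess_quality(ev[[1]], sk, lib$tandem_stance)
  expect_true(q$quality)
  expect_gte(q$peak_values[["front_hip_flexion"]], 15)
  expect_gte(q$peak_values[["front_hip_adduction"]], 5)
})

test_that("exercises without quality rules raise a configuration error", {
  sk <- simulate_skeleton(motion_profile("kick", n_reps = 1,
                                         peak_angle = 45, seed = 1))
  ev <- detect_attempts(sk, "kick")
  expect_error(assess_quality(ev[[1]], sk, "kick"),
               class = "exergauge_config_error")
})

test_that("hold timing returns the best of at most three attempts", {
  # build a stream whose staggered-stance driver toggles through spans of
  # 5, 12, 9 and then 20 seconds; only the first three attempts count
  coords <- standing_coords()
  fps <- 30
  spans <- list(c(5, 5 + 5), c(15, 15 + 12), c(32, 32 + 9), c(45, 45 + 20))
  total <- 70
  t <- seq(0, total, by = 1 / fps)
  xyz <- array(NA_real_, c(length(t), 19, 3))
  for (f in seq_along(t)) {
    fr <- coords
    if (any(vapply(spans, function(s) t[f] >= s[1] && t[f] <= s[2],
                   logical(1)))) {
      fr["foot_l", 3] <- fr["foot_l", 3] - 0.4   # step forward
    }
    xyz[f, , ] <- fr
  }
  sk <- skeleton_sequence(t, xyz)
  lib <- exercise_library(prescribed_time = 30)
  hr <- time_hold(sk, lib$tandem_stance)
  expect_length(hr$attempt_times, 3)
  expect_equal(hr$best_time, 12, tolerance = 0.1)
  expect_lte(hr$window_used, 120)
})

test_that("hold timing rejects repetition-mode exercises", {
  sk <- simulate_skeleton(motion_profile("squat", n_reps = 1,
                                         peak_angle = 90, seed = 1))
  expect_error(time_hold(sk, "squat"), class = "exergauge_mode_error")
})

test_that("speed warnings fire on sustained fast motion only", {
  coords <- standing_coords()
  fps <- 30
  t <- seq(0, 4, by = 1 / fps)
  xyz <- array(NA_real_, c(length(t), 19, 3))
  for (f in seq_along(t)) {
    fr <- coords
    if (t[f] >= 1 && t[f] <= 2) {
      fr["wrist_l", 1] <- fr["wrist_l", 1] + 3 * (t[f] - 1)  # 3 m/s
    } else if (t[f] > 2) {
      fr["wrist_l", 1] <- fr["wrist_l", 1] + 3
    }
    xyz[f, , ] <- fr
  }
  sk <- skeleton_sequence(t, xyz)
  w <- speed_warnings(sk, threshold = 2, min_duration = 0.2)
  expect_equal(nrow(w), 1)
  expect_equal(w$end - w$start, 1, tolerance = 0.15)
  # static stream: nothing
  expect_equal(nrow(speed_warnings(static_skeleton(coords))), 0)
  # a brief spike shorter than min_duration is ignored
  xyz2 <- array(NA_real_, c(length(t), 19, 3))
  for (f in seq_along(t)) xyz2[f, , ] <- coords
  i <- which.min(abs(t - 2))
  xyz2[i, 8, 1] <- coords[8, 1] + 0.2  # one-frame jump
  sk2 <- skeleton_sequence(t, xyz2)
  expect_equal(nrow(speed_warnings(sk2, threshold = 2, min_duration = 0.2)), 0)
})

test_that("fully missing streams and short streams are rejected", {
  t <- seq(0, 2, by = 1 / 30)
  xyz <- array(NA_real_, c(length(t), 19, 3))
  sk <- skeleton_sequence(t, xyz)
  expect_error(detect_attempts(sk, "squat"),
               class = "exergauge_missing_data_error")
  short <- static_skeleton(standing_coords(), n_frames = 10)
  expect_error(detect_attempts(short, "squat"),
               class = "exergauge_insufficient_data_error")
})
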