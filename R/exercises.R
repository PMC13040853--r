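# Exercise definitions: prescription plus movement-acceptability rules.
#
# Each exercise is described by (i) a primary "driver" metric whose
# excursions segment the stream into candidate repetitions, (ii) attempt
# rules that must ALL hold at the repetition peak for the movement to count
# as an attempt, and (iii) optional quality rules that decide whether an
# attempt is a high-quality repetition. Metrics are named kinematic series
# computed frame-by-frame from the skeleton (see compute_metric()).

# Rule types understood by the rule engine:
#   min         : max of metric within the event >= threshold
#   max_lt      : max of metric within the event <  threshold
#   band        : max of metric within the event in [lo, hi]
#   stance_ratio: mean foot separation / mean shoulder separation in [lo, hi]
#   travel_lt   : per-foot positional travel within the event < threshold (m)
#   duration_ge : event duration >= prescribed_time (timed exercises)
rule <- function(name, metric = NULL, type = "min",
                 threshold = NA_real_, lo = NA_real_, hi = NA_real_) {
  list(name = name, metric = metric, type = type,
       threshold = threshold, lo = lo, hi = hi)
}

#' Construct an exercise definition
#'
#' Bundles one exercise's prescription (repetitions x sets, or a timed
#' duration) with the kinematic rules that define an attempted and a
#' high-quality repetition. Definitions for the thirteen supported
#' exercises, with their default movement-acceptability thresholds, are
#' available through [exercise_library()].
#'
#' @param name Exercise label (e.g. `"squat"`).
#' @param mode `"reps"` for repetition-based exercises, `"timed"` for held
#'   (stretch/balance) exercises.
#' @param prescribed_reps Repetitions prescribed per set (repetition mode).
#' @param prescribed_time Hold duration prescribed in seconds (timed mode).
#' @param sets Number of sets prescribed.
#' @param supported Whether the exercise is performed with hand-hold
#'   support (a chair or walker); informational.
#' @param laterality `"left"`, `"right"` or `"bilateral"`. Bilateral
#'   exercises alternate sides, and each side's movement counts as a
#'   separate attempt.
#' @param primary_metric Name of the driver metric used to segment
#'   repetitions.
#' @param attempt_rules List of rules that must all pass for an attempt.
#' @param quality_rules Optional list of rules defining a high-quality
#'   repetition; `NULL` when quality criteria are not configured.
#' @return An object of class `exercise_definition`.
#' @export
exercise_definition <- function(name, mode = c("reps", "timed"),
                                prescribed_reps = NULL,
                                prescribed_time = NULL,
                                sets = 1L, supported = FALSE,
                                laterality = "bilateral",
                                primary_metric, attempt_rules,
                                quality_rules = NULL) {
  mode <- match.arg(mode)
  if (mode == "reps") {
    if (is.null(prescribed_reps) || !is.null(prescribed_time)) {
      abort_exergauge(
        sprintf("exercise '%s': repetition mode requires prescribed_reps only",
                name), "exergauge_config_error")
    }
  } else {
    if (is.null(prescribed_time) || !is.null(prescribed_reps)) {
      abort_exergauge(
        sprintf("exercise '%s': timed mode requires prescribed_time only",
                name), "exergauge_config_error")
    }
  }
  thr <- vapply(attempt_rules, function(r) {
    if (r$type %in% c("min", "max_lt")) r$threshold else NA_real_
  }, numeric(1))
  ang <- grepl("_deg$|flexion|abduction|adduction|lean",
               vapply(attempt_rules, `[[`, character(1), "name"))
  if (any(!is.na(thr[ang]) & (thr[ang] <= 0 | thr[ang] >= 180))) {
    abort_exergauge(
      sprintf("exercise '%s': angle thresholds must lie in (0, 180)", name),
      "exergauge_config_error")
  }
  structure(
    list(name = name, mode = mode,
         prescribed_reps = prescribed_reps,
         prescribed_time = prescribed_time,
         sets = as.integer(sets), supported = isTRUE(supported),
         laterality = laterality,
         primary_metric = primary_metric,
         attempt_rules = attempt_rules,
         quality_rules = quality_rules),
    class = "exercise_definition"
  )
}

#' @export
print.exercise_definition <- function(x, ...) {
  presc <- if (x$mode == "reps") {
    sprintf("%d reps x %d sets", x$prescribed_reps, x$sets)
  } else {
    sprintf("%.0f s x %d sets", x$prescribed_time, x$sets)
  }
  cat(sprintf("<exercise_definition> %s (%s, %s): %d attempt rule(s), %s\n",
              x$name, x$mode, presc, length(x$attempt_rules),
              if (is.null(x$quality_rules)) "no quality rules"
              else sprintf("%d quality rule(s)", length(x$quality_rules))))
  invisible(x)
}

#' Built-in exercise library
#'
#' Returns the default definitions of the thirteen supported lower-limb
#' exercises. Attempt rules operationalize each exercise's attempted-
#' repetition metric (e.g. hip flexion of at least 20 degrees for the leg
#' lift; a staggered stance for stepping exercises; vertical chest
#' displacement for sit-to-stand and squat). Quality-rule sets are
#' provided for the squat (depth 90 degrees within a configurable
#' acceptance band, lateral trunk lean under 10 degrees, feet shoulder
#' width apart and unmoving) and the tandem stance (front-leg hip flexion
#' of at least 15 degrees and hip adduction of at least 5 degrees, held
#' for the prescribed time); other exercises accept quality rules through
#' the same pluggable rule framework when they are known.
#'
#' @param prescribed_reps,sets,prescribed_time Default prescription used
#'   for every returned definition (individual prescriptions normally come
#'   from the trial configuration).
#' @param squat_depth_band Half-width in degrees of the squat depth
#'   acceptance band around 90 degrees; the default 20 accepts peak
#'   flexion in [70, 110].
#' @return Named list of [exercise_definition] objects.
#' @export
#' @examples
#' names(exercise_library())
#' exercise_library()$squat
exercise_library <- function(prescribed_reps = 10L, sets = 1L,
                             prescribed_time = 30, squat_depth_band = 20) {
  rp <- as.integer(prescribed_reps)
  lib <- list(
    hip_flexion = exercise_definition(
      "hip_flexion", "reps", prescribed_reps = rp, sets = sets,
      laterality = "bilateral", primary_metric = "hip_flexion_max",
      attempt_rules = list(
        rule("min_hip_flexion", "hip_flexion_max", "min", threshold = 20))),
    hip_abduction = exercise_definition(
      "hip_abduction", "reps", prescribed_reps = rp, sets = sets,
      laterality = "bilateral", primary_metric = "hip_abduction_max",
      attempt_rules = list(
        rule("min_hip_abduction", "hip_abduction_max", "min", threshold = 20))),
    forward_step = exercise_definition(
      "forward_step", "reps", prescribed_reps = rp, sets = sets,
      primary_metric = "foot_offset_z",
      attempt_rules = list(
        rule("staggered_stance", "foot_offset_z", "min", threshold = 0.15))),
    lateral_step = exercise_definition(
      "lateral_step", "reps", prescribed_reps = rp, sets = sets,
      primary_metric = "foot_beyond_shoulder",
      attempt_rules = list(
        rule("foot_beyond_shoulder", "foot_beyond_shoulder", "min",
             threshold = 0.05))),
    backward_step = exercise_definition(
      "backward_step", "reps", prescribed_reps = rp, sets = sets,
      primary_metric = "foot_offset_z",
      attempt_rules = list(
        rule("foot_length_back", "foot_offset_z", "min", threshold = 0.20))),
    tandem_stance = exercise_definition(
      "tandem_stance", "timed", prescribed_time = prescribed_time,
      sets = sets, primary_metric = "foot_offset_z",
      attempt_rules = list(
        rule("staggered_stance", "foot_offset_z", "min", threshold = 0.20)),
      quality_rules = list(
        rule("front_hip_flexion", "hip_flexion_max", "min", threshold = 15),
        rule("front_hip_adduction", "hip_adduction_max", "min", threshold = 5),
        rule("held_prescribed_time", type = "duration_ge"))),
    single_leg_stance = exercise_definition(
      "single_leg_stance", "timed", prescribed_time = prescribed_time,
      sets = sets, primary_metric = "foot_lift",
      attempt_rules = list(
        rule("foot_off_ground", "foot_lift", "min", threshold = 0.05))),
    sit_to_stand = exercise_definition(
      "sit_to_stand", "reps", prescribed_reps = rp, sets = sets,
      primary_metric = "chest_drop",
      attempt_rules = list(
        rule("chest_displaces_vertically", "chest_drop", "min",
             threshold = 0.10))),
    calf_stretch = exercise_definition(
      "calf_stretch", "timed", prescribed_time = prescribed_time,
      sets = sets, supported = TRUE, primary_metric = "foot_offset_z",
      attempt_rules = list(
        rule("staggered_stance", "foot_offset_z", "min", threshold = 0.15))),
    hamstring_stretch = exercise_definition(
      "hamstring_stretch", "timed", prescribed_time = prescribed_time,
      sets = sets, primary_metric = "chest_anterior",
      attempt_rules = list(
        rule("chest_displaces_anteriorly", "chest_anterior", "min",
             threshold = 0.10))),
    squat = exercise_definition(
      "squat", "reps", prescribed_reps = rp, sets = sets,
      primary_metric = "hip_flexion_min",
      attempt_rules = list(
        rule("min_hip_flexion", "hip_flexion_min", "min", threshold = 20),
        rule("min_knee_flexion", "knee_flexion_min", "min", threshold = 20),
        rule("chest_displaces_vertically", "chest_drop", "min",
             threshold = 0.10)),
      quality_rules = list(
        rule("squat_depth_hip", "hip_flexion_min", "band",
             lo = 90 - squat_depth_band, hi = 90 + squat_depth_band),
        rule("squat_depth_knee", "knee_flexion_min", "band",
             lo = 90 - squat_depth_band, hi = 90 + squat_depth_band),
        rule("trunk_lean", "trunk_lean", "max_lt", threshold = 10),
        rule("feet_shoulder_width", type = "stance_ratio",
             lo = 0.75, hi = 1.25),
        rule("feet_unmoving", type = "travel_lt", threshold = 0.05))),
    seated_star_jump = exercise_definition(
      "seated_star_jump", "reps", prescribed_reps = rp, sets = sets,
      primary_metric = "star_excursion",
      attempt_rules = list(
        rule("arm_and_foot_lateral", "star_excursion", "min",
             threshold = 0.10))),
    kick = exercise_definition(
      "kick", "reps", prescribed_reps = rp, sets = sets,
      primary_metric = "foot_anterior",
      attempt_rules = list(
        rule("foot_in_front", "foot_anterior", "min", threshold = 0.15)))
  )
  lib
}

#' Names of the supported exercises
#' @return Character vector of the 13 exercise names.
#' @export
supported_exercises <- function() names(exercise_library())

#' @keywords internal
get_exercise <- function(exercise) {
  if (inherits(exercise, "exercise_definition")) return(exercise)
  lib <- exercise_library()
  if (!is.character(exercise) || length(exercise) != 1 ||
      !exercise %in% names(lib)) {
    abort_exergauge(
      sprintf("unsupported exercise: %s (supported: %s)",
              paste(format(exercise), collapse = ","),
              paste(names(lib), collapse = ", ")),
      "exergauge_unsupported_exercise_error")
  }
  lib[[exercise]]
}
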