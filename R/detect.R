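# Rule-based repetition detection and movement-quality assessment.

#' @keywords internal
new_event <- function(start_time, peak_time, end_time, attempt,
                      peak_values, quality = NA,
                      failed_criteria = character(0)) {
  structure(
    list(start_time = start_time, peak_time = peak_time,
         end_time = end_time, attempt = attempt, quality = quality,
         failed_criteria = failed_criteria, peak_values = peak_values),
    class = "repetition_event")
}

#' @export
print.repetition_event <- function(x, ...) {
  cat(sprintf(
    "<repetition_event> %.2f-%.2f s (peak %.2f s), attempt=%s, quality=%s\n",
    x$start_time, x$end_time, x$peak_time, x$attempt,
    if (is.na(x$quality)) "unassessed" else x$quality))
  invisible(x)
}

# Evaluate one rule over an event's frame window; returns list(pass, value).
#' @keywords internal
eval_rule <- function(r, sequence, idx, exercise, metrics_cache) {
  met <- function(name) {
    if (is.null(metrics_cache[[name]])) {
      metrics_cache[[name]] <<- compute_metric(sequence, name)
    }
    metrics_cache[[name]]
  }
  win_max <- function(name) {
    v <- met(name)[idx]
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  }
  t <- sequence$frame_times
  switch(
    r$type,
    min = {
      v <- win_max(r$metric)
      list(pass = !is.na(v) && v >= r$threshold, value = v)
    },
    max_lt = {
      v <- win_max(r$metric)
      list(pass = !is.na(v) && v < r$threshold, value = v)
    },
    band = {
      v <- win_max(r$metric)
      list(pass = !is.na(v) && v >= r$lo && v <= r$hi, value = v)
    },
    stance_ratio = {
      fs <- mean(met("foot_separation_x")[idx], na.rm = TRUE)
      ss <- mean(met("shoulder_separation_x")[idx], na.rm = TRUE)
      ratio <- fs / ss
      list(pass = is.finite(ratio) && ratio >= r$lo && ratio <= r$hi,
           value = ratio)
    },
    travel_lt = {
      travel <- vapply(c("foot_l", "foot_r"), function(j) {
        p <- sequence$xyz[idx, .joint_idx(j), , drop = FALSE]
        ref <- p[1, 1, ]
        d <- sqrt((p[, 1, 1] - ref[1])^2 + (p[, 1, 2] - ref[2])^2 +
                    (p[, 1, 3] - ref[3])^2)
        if (all(is.na(d))) NA_real_ else max(d, na.rm = TRUE)
      }, numeric(1))
      v <- max(travel)
      list(pass = !is.na(v) && v < r$threshold, value = v)
    },
    duration_ge = {
      dur <- t[idx[length(idx)]] - t[idx[1]]
      need <- exercise$prescribed_time
      list(pass = !is.null(need) && dur >= need, value = dur)
    },
    abort_exergauge(sprintf("unknown rule type: %s", r$type),
                    "exergauge_config_error")
  )
}

#' Detect attempted repetitions in a skeleton stream
#'
#' Segments the stream into candidate repetitions by hysteresis on the
#' exercise's driver metric (an event opens when the driver crosses the
#' attempt threshold upward and closes when it falls below 50% of the
#' threshold; events closer than `min_gap` seconds are merged), then keeps
#' the maximal non-overlapping events at which every attempt rule for the
#' exercise is satisfied. Short tracking dropouts are linearly
#' interpolated first; frames inside longer outages cannot form events.
#'
#' @param sequence A [skeleton_sequence] covering at least 1 s.
#' @param exercise An [exercise_definition] or the name of a supported
#'   exercise (default thresholds from [exercise_library()]).
#' @param min_gap Minimum inter-event gap in seconds (default 0.25);
#'   closer events are merged to prevent chatter double-counts.
#' @return List of `repetition_event` objects ordered by start time, each
#'   with `attempt = TRUE`, peak timing and the measured peak values of
#'   every attempt rule. Quality fields are unset until
#'   [assess_quality()].
#' @export
#' @examples
#' sk <- simulate_skeleton(motion_profile("hip_flexion", n_reps = 3,
#'                                        peak_angle = 45, seed = 1))
#' length(detect_attempts(sk, "hip_flexion"))
detect_attempts <- function(sequence, exercise, min_gap = 0.25) {
  ex <- get_exercise(exercise)
  stopifnot(inherits(sequence, "skeleton_sequence"))
  t <- sequence$frame_times
  if (t[length(t)] - t[1] < 1) {
    abort_exergauge("sequence must cover at least 1 s",
                    "exergauge_insufficient_data_error")
  }
  if (all(sequence$missing)) {
    abort_exergauge("all markers missing from stream",
                    "exergauge_missing_data_error")
  }
  sequence <- interpolate_dropouts(sequence)
  driver <- compute_metric(sequence, ex$primary_metric)
  driver[is.na(driver)] <- -Inf
  prim <- Filter(function(r) identical(r$metric, ex$primary_metric),
                 ex$attempt_rules)[[1]]
  thr <- prim$threshold
  close_thr <- 0.5 * thr

  # hysteresis segmentation
  spans <- list()
  open <- FALSE; s <- NA_integer_
  for (f in seq_along(driver)) {
    if (!open && driver[f] >= thr) {
      open <- TRUE; s <- f
    } else if (open && driver[f] < close_thr) {
      spans[[length(spans) + 1]] <- c(s, f)
      open <- FALSE
    }
  }
  if (open) spans[[length(spans) + 1]] <- c(s, length(driver))

  # merge events separated by less than min_gap
  if (length(spans) > 1) {
    merged <- list(spans[[1]])
    for (k in 2:length(spans)) {
      prev <- merged[[length(merged)]]
      if (t[spans[[k]][1]] - t[prev[2]] < min_gap) {
        merged[[length(merged)]] <- c(prev[1], spans[[k]][2])
      } else {
        merged[[length(merged) + 1]] <- spans[[k]]
      }
    }
    spans <- merged
  }

  metrics_cache <- new.env(parent = emptyenv())
  events <- list()
  for (sp in spans) {
    idx <- sp[1]:sp[2]
    checks <- lapply(ex$attempt_rules, eval_rule, sequence = sequence,
                     idx = idx, exercise = ex, metrics_cache = metrics_cache)
    if (!all(vapply(checks, `[[`, logical(1), "pass"))) next
    pk <- idx[which.max(driver[idx])]
    peak_values <- stats::setNames(
      vapply(checks, `[[`, numeric(1), "value"),
      vapply(ex$attempt_rules, `[[`, character(1), "name"))
    events[[length(events) + 1]] <- new_event(
      start_time = t[sp[1]], peak_time = t[pk], end_time = t[sp[2]],
      attempt = TRUE, peak_values = peak_values)
  }
  events
}

#' Assess whether an attempted repetition is high quality
#'
#' Evaluates the exercise's quality rules over the event's frame window
#' and fills the event's `quality`, `failed_criteria` and `peak_values`
#' fields. A repetition is high quality iff every quality rule passes.
#'
#' @param event A `repetition_event` with `attempt = TRUE`, as returned
#'   by [detect_attempts()].
#' @param sequence The [skeleton_sequence] the event was detected in.
#' @param exercise The [exercise_definition] (must carry quality rules).
#' @return The event with quality fields filled.
#' @export
assess_quality <- function(event, sequence, exercise) {
  ex <- get_exercise(exercise)
  stopifnot(inherits(event, "repetition_event"))
  if (!isTRUE(event$attempt)) {
    abort_exergauge("quality is only assessed for attempted repetitions",
                    "exergauge_config_error")
  }
  if (is.null(ex$quality_rules)) {
    abort_exergauge(
      sprintf("exercise '%s' has no configured quality rules", ex$name),
      "exergauge_config_error")
  }
  sequence <- interpolate_dropouts(sequence)
  t <- sequence$frame_times
  idx <- which(t >= event$start_time & t <= event$end_time)
  metrics_cache <- new.env(parent = emptyenv())
  failed <- character(0)
  vals <- event$peak_values
  for (r in ex$quality_rules) {
    res <- eval_rule(r, sequence, idx, ex, metrics_cache)
    vals[r$name] <- res$value
    if (!res$pass) failed <- c(failed, r$name)
  }
  event$quality <- length(failed) == 0
  event$failed_criteria <- failed
  event$peak_values <- vals
  event
}

#' Time a held (timed) exercise
#'
#' For static exercises (stretches, balance holds) the hold duration is
#' the longest contiguous span over which every attempt rule is satisfied
#' frame-by-frame. At most three attempts are counted within a 2-minute
#' window; the best (longest) time is returned.
#'
#' @param sequence A [skeleton_sequence].
#' @param exercise A timed-mode [exercise_definition] or exercise name.
#' @param window Attempt window in seconds (default 120).
#' @param max_attempts Maximum number of attempts counted (default 3).
#' @return An object of class `hold_result` with `attempt_times` (up to
#'   three hold durations in seconds), `best_time` and `window_used`.
#' @export
time_hold <- function(sequence, exercise, window = 120, max_attempts = 3L) {
  ex <- get_exercise(exercise)
  if (ex$mode != "timed") {
    abort_exergauge(
      sprintf("'%s' is a repetition-mode exercise; time_hold applies to timed exercises",
              ex$name), "exergauge_mode_error")
  }
  stopifnot(inherits(sequence, "skeleton_sequence"))
  sequence <- interpolate_dropouts(sequence)
  t <- sequence$frame_times
  in_window <- t - t[1] <= window
  ok <- rep(TRUE, length(t))
  for (r in ex$attempt_rules) {
    v <- compute_metric(sequence, r$metric)
    ok <- ok & !is.na(v) & v >= r$threshold
  }
  ok <- ok & in_window
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  durations <- t[ends[keep]] - t[starts[keep]]
  durations <- durations[seq_len(min(length(durations), max_attempts))]
  structure(
    list(attempt_times = durations,
         best_time = if (length(durations)) max(durations) else 0,
         window_used = min(window, t[length(t)] - t[1])),
    class = "hold_result")
}

#' Detect over-speed intervals
#'
#' Flags intervals where the fastest joint (central-difference speed)
#' exceeds a speed threshold for at least a minimum duration; these are
#' the intervals at which a slow-down warning would be issued to the
#' player.
#'
#' @param sequence A [skeleton_sequence].
#' @param threshold Speed threshold in m/s (default 2).
#' @param min_duration Minimum over-speed duration in seconds to warrant
#'   a warning (default 0.2); brief spikes are ignored.
#' @return Data frame with columns `start`, `end` (seconds); zero rows
#'   when no warning is triggered.
#' @export
speed_warnings <- function(sequence, threshold = 2, min_duration = 0.2) {
  stopifnot(inherits(sequence, "skeleton_sequence"), threshold > 0)
  t <- sequence$frame_times
  n <- length(t)
  if (n < 3) return(data.frame(start = numeric(0), end = numeric(0)))
  speed <- rep(0, n)
  dt <- t[3:n] - t[1:(n - 2)]
  for (j in seq_len(19)) {
    p <- sequence$xyz[, j, ]
    v <- sqrt(rowSums((p[3:n, , drop = FALSE] -
                         p[1:(n - 2), , drop = FALSE])^2)) / dt
    v[is.na(v)] <- 0
    speed[2:(n - 1)] <- pmax(speed[2:(n - 1)], v)
  }
  over <- speed > threshold
  runs <- rle(over)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  out <- data.frame(start = t[starts[keep]], end = t[ends[keep]])
  out[out$end - out$start >= min_duration, , drop = FALSE]
}
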