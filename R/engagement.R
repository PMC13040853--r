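# Engagement outcomes: adherence, fidelity, star ratings, session summaries.

#' Exercise adherence
#'
#' Adherence is the number of repetitions attempted (or, for timed
#' exercises, the duration of attempts in seconds) divided by the number
#' or time prescribed. A child attempting more than prescribed yields a
#' value greater than 1.0.
#'
#' @param attempted Attempted repetitions (count) or attempt duration
#'   (seconds).
#' @param prescribed Prescribed repetitions or time; must be positive.
#' @return Adherence proportion (>= 0, may exceed 1).
#' @export
#' @examples
#' adherence(13, 10)  # 1.3
adherence <- function(attempted, prescribed) {
  stopifnot(is.numeric(attempted), is.numeric(prescribed),
            all(attempted >= 0))
  if (any(prescribed <= 0)) {
    abort_exergauge("prescribed count/time must be positive",
                    "exergauge_division_error")
  }
  attempted / prescribed
}

#' Exercise fidelity
#'
#' Fidelity is the number of high-quality repetitions divided by the
#' number prescribed; for timed exercises, the best held time over three
#' attempts divided by the time prescribed. Like adherence, it can exceed
#' 1.0.
#'
#' @param quality High-quality repetitions (count) or best hold time
#'   (seconds).
#' @param prescribed Prescribed repetitions or time; must be positive.
#' @param attempted Optional attempted count for the same exercise; when
#'   supplied, `quality > attempted` raises a consistency error.
#' @return Fidelity proportion (>= 0, may exceed 1).
#' @export
fidelity <- function(quality, prescribed, attempted = NULL) {
  stopifnot(is.numeric(quality), all(quality >= 0))
  if (any(prescribed <= 0)) {
    abort_exergauge("prescribed count/time must be positive",
                    "exergauge_division_error")
  }
  if (!is.null(attempted) && any(quality > attempted)) {
    abort_exergauge("quality repetitions cannot exceed attempted repetitions",
                    "exergauge_consistency_error")
  }
  quality / prescribed
}

#' Three-star movement-quality rating
#'
#' Converts the fraction of repetitions performed with appropriate form
#' into the in-game star award: 1 star below 50%, 2 stars from 50% to
#' 75%, and 3 stars above 75%. The boundaries 0.50 and 0.75 both award 2
#' stars (the 1- and 3-star bands are read strictly). One star is always
#' awarded, even for suboptimal performance, so the image of the rule is
#' exactly \{1, 2, 3\}.
#'
#' @param quality_fraction Fraction of repetitions with appropriate form
#'   (>= 0; values above 1 are treated as 1-equivalent, i.e. 3 stars).
#' @return Integer vector of stars in \{1, 2, 3\}.
#' @export
#' @examples
#' star_rating(c(0.40, 0.60, 0.80))  # 1 2 3
star_rating <- function(quality_fraction) {
  if (!is.numeric(quality_fraction) || any(is.na(quality_fraction)) ||
      any(quality_fraction < 0)) {
    abort_exergauge("quality_fraction must be non-negative",
                    "exergauge_argument_error")
  }
  ifelse(quality_fraction > 0.75, 3L,
         ifelse(quality_fraction >= 0.50, 2L, 1L))
}

#' Summarize one exercise session
#'
#' Aggregates per-exercise detection results into a session record with
#' the session-level engagement outcomes. Counts are aggregated across
#' sets. In the feedback condition the game caps attempts at three extra
#' repetitions beyond what was prescribed (the `feedback_caps` flag);
#' the no-feedback condition has no cap because the child counts their
#' own repetitions. Session adherence and fidelity are unweighted means
#' of the per-exercise proportions (a pooled total-attempts /
#' total-prescribed mode is available via `aggregate = "pooled"`).
#'
#' @param counts Data frame with one row per exercise and columns
#'   `exercise`, `attempted`, `quality` (counts for repetition-mode
#'   exercises; for timed exercises, attempt duration and best time in
#'   seconds).
#' @param definitions Named list of [exercise_definition] objects covering
#'   every exercise in `counts`.
#' @param condition `"feedback"` or `"no_feedback"`.
#' @param session_index Ordinal session number.
#' @param feedback_caps Apply the prescribed+3 attempt cap in the
#'   feedback condition (default TRUE).
#' @param aggregate `"mean"` (default) or `"pooled"` session aggregation.
#' @param fun_rating,helpful_rating Optional 1-5 smiley-face ratings.
#' @return An object of class `session_record`: the per-exercise table
#'   augmented with adherence/fidelity/stars, plus session-level fields.
#' @export
summarize_session <- function(counts, definitions, condition,
                              session_index = 1L, feedback_caps = TRUE,
                              aggregate = c("mean", "pooled"),
                              fun_rating = NA_integer_,
                              helpful_rating = NA_integer_) {
  aggregate <- match.arg(aggregate)
  check_condition(condition)
  for (r in c(fun_rating, helpful_rating)) {
    if (!is.na(r) && !(is_count(r) && r >= 1 && r <= 5)) {
      abort_exergauge("ratings must be integers 1-5 or missing",
                      "exergauge_argument_error")
    }
  }
  stopifnot(is.data.frame(counts),
            all(c("exercise", "attempted", "quality") %in% names(counts)))
  missing_def <- setdiff(counts$exercise, names(definitions))
  if (length(missing_def) > 0) {
    abort_exergauge(
      sprintf("no definition for exercise(s): %s",
              paste(missing_def, collapse = ", ")),
      "exergauge_config_error")
  }
  per <- counts
  per$prescribed <- vapply(per$exercise, function(e) {
    d <- definitions[[e]]
    if (d$mode == "reps") d$prescribed_reps * d$sets
    else d$prescribed_time * d$sets
  }, numeric(1))
  if (feedback_caps && condition == "feedback") {
    is_reps <- vapply(per$exercise,
                      function(e) definitions[[e]]$mode == "reps",
                      logical(1))
    cap <- per$prescribed + 3 * vapply(per$exercise,
                                       function(e) definitions[[e]]$sets,
                                       numeric(1))
    per$attempted[is_reps] <- pmin(per$attempted[is_reps], cap[is_reps])
  }
  per$adherence <- adherence(per$attempted, per$prescribed)
  per$fidelity <- mapply(fidelity, per$quality, per$prescribed,
                         per$attempted)
  per$quality_fraction <- ifelse(per$attempted > 0,
                                 pmin(per$quality / per$attempted, 1), 0)
  per$stars <- if (condition == "feedback") {
    star_rating(per$quality_fraction)
  } else NA_integer_
  if (aggregate == "mean") {
    sess_adh <- mean(per$adherence)
    sess_fid <- mean(per$fidelity)
  } else {
    sess_adh <- sum(per$attempted) / sum(per$prescribed)
    sess_fid <- sum(per$quality) / sum(per$prescribed)
  }
  structure(
    list(session_index = as.integer(session_index), condition = condition,
         per_exercise = per, adherence = sess_adh, fidelity = sess_fid,
         fun_rating = fun_rating, helpful_rating = helpful_rating),
    class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf(
    "<session_record> #%d (%s): adherence %.2f, fidelity %.2f, %d exercise(s)\n",
    x$session_index, x$condition, x$adherence, x$fidelity,
    nrow(x$per_exercise)))
  invisible(x)
}
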