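# Delimited-text file formats for skeleton streams, session logs and
# agreement tables.
#
# Skeleton schema (long format, one row per joint per frame):
#   time_s, joint, x_m, y_m, z_m, confidence
# confidence 0 flags a missing marker; coordinates are then empty.

#' Write a skeleton stream to delimited text
#'
#' @param sequence A [skeleton_sequence].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_skeleton <- function(sequence, path) {
  stopifnot(inherits(sequence, "skeleton_sequence"))
  n <- length(sequence$frame_times)
  jn <- joint_names()
  df <- data.frame(
    time_s = rep(sequence$frame_times, each = 19),
    joint = rep(jn, times = n),
    x_m = as.vector(t(sequence$xyz[, , 1])),
    y_m = as.vector(t(sequence$xyz[, , 2])),
    z_m = as.vector(t(sequence$xyz[, , 3])),
    confidence = as.integer(!as.vector(t(sequence$missing)))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a skeleton stream from delimited text
#'
#' Validates the schema: joint names must belong to the canonical
#' vocabulary (schema error naming the joint and line number otherwise)
#' and frame times must be strictly increasing. Rows with confidence 0
#' or absent joints are flagged as missing markers.
#'
#' @param path Input file path.
#' @return A [skeleton_sequence].
#' @export
read_skeleton <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "joint", "x_m", "y_m", "z_m", "confidence")
  if (!all(need %in% names(df))) {
    abort_exergauge(
      sprintf("skeleton file lacks columns: %s",
              paste(setdiff(need, names(df)), collapse = ", ")),
      "exergauge_schema_error")
  }
  jn <- joint_names()
  bad <- which(!df$joint %in% jn)
  if (length(bad) > 0) {
    abort_exergauge(
      sprintf("unknown joint '%s' at line %d", df$joint[bad[1]],
              bad[1] + 1L),  # +1 for the header line
      "exergauge_schema_error")
  }
  times <- unique(df$time_s)
  if (any(diff(times) <= 0)) {
    abort_exergauge("frame times are not strictly increasing",
                    "exergauge_ordering_error")
  }
  n <- length(times)
  xyz <- array(NA_real_, c(n, 19, 3))
  fi <- match(df$time_s, times)
  ji <- match(df$joint, jn)
  ok <- df$confidence > 0
  xyz[cbind(fi[ok], ji[ok], 1L)] <- df$x_m[ok]
  xyz[cbind(fi[ok], ji[ok], 2L)] <- df$y_m[ok]
  xyz[cbind(fi[ok], ji[ok], 3L)] <- df$z_m[ok]
  skeleton_sequence(times, xyz)
}

#' Write a session log
#'
#' Session logs are delimited text with the fixed header `session_index,
#' condition, exercise, set, attempted, quality, prescribed, best_time_s,
#' fun_rating, helpful_rating`.
#'
#' @param sessions Data frame with (a subset of) the log columns;
#'   absent columns are filled with NA.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(sessions, path) {
  cols <- c("session_index", "condition", "exercise", "set", "attempted",
            "quality", "prescribed", "best_time_s", "fun_rating",
            "helpful_rating")
  for (c_ in setdiff(cols, names(sessions))) sessions[[c_]] <- NA
  utils::write.csv(sessions[, cols], path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Read a session log
#' @param path Input file path.
#' @return Data frame in the session-log schema.
#' @export
read_session_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("session_index", "condition", "exercise", "attempted")
           %in% names(df))) {
    abort_exergauge("session log lacks required columns",
                    "exergauge_schema_error")
  }
  check_condition(df$condition)
  df
}

#' Write an agreement table
#' @param table Data frame with `video_id`, `manual`, `system` and
#'   optionally `exercise` and `rater2` columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_agreement_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read an agreement table
#' @param path Input file path.
#' @return Data frame with at least `manual` and `system` columns.
#' @export
read_agreement_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("manual", "system") %in% names(df))) {
    abort_exergauge("agreement table lacks manual/system columns",
                    "exergauge_schema_error")
  }
  df
}
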