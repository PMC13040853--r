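# Skeleton stream container: timestamped 3D positions of 19 body joints.

#' Canonical 19-joint marker vocabulary
#'
#' Names of the 19 tracked body joints used throughout the package, in the
#' fixed order in which they are stored in a [skeleton_sequence]. The
#' vocabulary covers the axial skeleton (head, neck, three spine markers)
#' plus left/right shoulder, elbow, wrist, hand, hip, knee and foot.
#'
#' @return Character vector of length 19.
#' @export
#' @examples
#' joint_names()
joint_names <- function() {
  c("head", "neck", "spine_shoulder", "spine_mid", "spine_base",
    "shoulder_l", "elbow_l", "wrist_l", "hand_l",
    "shoulder_r", "elbow_r", "wrist_r", "hand_r",
    "hip_l", "knee_l", "foot_l",
    "hip_r", "knee_r", "foot_r")
}

#' Construct a skeleton sequence
#'
#' A `skeleton_sequence` holds one exercise bout's motion-capture stream:
#' per-frame timestamps and the x (horizontal), y (vertical), z (depth)
#' position in meters of each of the 19 canonical joints. Missing markers
#' (tracking dropouts) are carried as `NA` coordinates with a logical
#' missing flag per joint per frame.
#'
#' @param frame_times Numeric vector of frame timestamps in seconds,
#'   strictly increasing (nominally 30 frames/s).
#' @param xyz Numeric array `n_frames x 19 x 3` of joint positions in
#'   meters; dimension 2 must be ordered as [joint_names()], dimension 3 as
#'   x, y, z. `NA` marks a missing marker.
#' @return An object of class `skeleton_sequence` with elements
#'   `frame_times`, `xyz` and `missing` (frames x joints logical matrix).
#' @export
skeleton_sequence <- function(frame_times, xyz) {
  frame_times <- as.numeric(frame_times)
  if (length(frame_times) < 1 || any(diff(frame_times) <= 0)) {
    abort_exergauge("frame_times must be non-empty and strictly increasing",
                    "exergauge_ordering_error")
  }
  if (!is.array(xyz) || length(dim(xyz)) != 3 ||
      dim(xyz)[1] != length(frame_times) || dim(xyz)[2] != 19 ||
      dim(xyz)[3] != 3) {
    abort_exergauge("xyz must be an n_frames x 19 x 3 array",
                    "exergauge_schema_error")
  }
  dimnames(xyz) <- list(NULL, joint_names(), c("x", "y", "z"))
  missing <- apply(is.na(xyz), c(1, 2), any)
  structure(
    list(frame_times = frame_times, xyz = xyz, missing = missing),
    class = "skeleton_sequence"
  )
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  n <- length(x$frame_times)
  dur <- diff(range(x$frame_times))
  pmiss <- mean(x$missing)
  cat(sprintf(
    "<skeleton_sequence> %d frames, %.2f s, 19 joints, %.1f%% markers missing\n",
    n, dur, 100 * pmiss))
  invisible(x)
}

#' @export
length.skeleton_sequence <- function(x) length(x$frame_times)

#' Interpolate short tracking dropouts
#'
#' Fills missing-marker gaps by per-joint, per-coordinate linear
#' interpolation over time, but only for gaps of at most `max_gap` frames;
#' longer outages are left missing so that downstream event formation can
#' exclude the affected frames.
#'
#' @param sequence A [skeleton_sequence].
#' @param max_gap Longest run of consecutive missing frames (per joint)
#'   that is interpolated; default 5 frames (~0.17 s at 30 frames/s).
#' @return A [skeleton_sequence] with short gaps filled.
#' @export
interpolate_dropouts <- function(sequence, max_gap = 5L) {
  stopifnot(inherits(sequence, "skeleton_sequence"))
  xyz <- sequence$xyz
  t <- sequence$frame_times
  n <- length(t)
  for (j in seq_len(19)) {
    miss <- sequence$missing[, j]
    if (!any(miss) || all(miss)) next
    runs <- rle(miss)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (r in seq_along(runs$lengths)) {
      if (!runs$values[r]) next
      if (runs$lengths[r] > max_gap) next
      lo <- starts[r]; hi <- ends[r]
      # need an observed frame on both sides to interpolate
      if (lo == 1 || hi == n) next
      idx <- lo:hi
      for (k in 1:3) {
        xyz[idx, j, k] <- stats::approx(
          x = t[c(lo - 1, hi + 1)],
          y = xyz[c(lo - 1, hi + 1), j, k],
          xout = t[idx]
        )$y
      }
    }
  }
  skeleton_sequence(t, xyz)
}
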