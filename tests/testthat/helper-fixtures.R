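# Shared fixture builders for the test suite.

# A strictly alternating ATD series with `k` between-condition
# comparisons, of which `favourable` have the feedback value above the
# neighbouring no-feedback value.
alternating_series <- function(k, favourable, base = 0.8, gap = 0.2) {
  stopifnot(favourable <= k)
  f_vals <- ifelse(seq_len(k) <= favourable, base + gap, base - gap)
  n_vals <- rep(base, k)
  atd_series(condition = rep(c("feedback", "no_feedback"), k),
             outcome = as.vector(rbind(f_vals, n_vals)))
}

# A skeleton whose joints sit at given fixed coordinates in every frame
# (two frames so it is a valid stream).
static_skeleton <- function(coords, n_frames = 31, fps = 30) {
  xyz <- array(NA_real_, c(n_frames, 19, 3))
  for (f in seq_len(n_frames)) xyz[f, , ] <- coords
  skeleton_sequence(seq(0, by = 1 / fps, length.out = n_frames), xyz)
}

# Base standing coordinates with easy-to-reason geometry.
standing_coords <- function() {
  prof <- motion_profile("hip_flexion", n_reps = 0, seed = 1)
  sk <- simulate_skeleton(prof)
  sk$xyz[1, , ]
}
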