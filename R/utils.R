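# Internal helpers shared across modules.

#' @keywords internal
abort_exergauge <- function(message, class, ...) {
  stop(structure(
    class = c(class, "exergauge_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never perturb user
# simulations.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Angle between two 3-vectors in degrees, in [0, 180].
#' @keywords internal
vector_angle_deg <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' @keywords internal
deg2rad <- function(x) x * pi / 180

#' @keywords internal
is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == round(x)
}

#' @keywords internal
is_proportionish <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

# Conditions used throughout: canonical labels for the two treatment arms.
#' @keywords internal
.conditions <- c("feedback", "no_feedback")

#' @keywords internal
check_condition <- function(x) {
  bad <- setdiff(unique(x), .conditions)
  if (length(bad) > 0) {
    abort_exergauge(
      sprintf("unknown condition label(s): %s (expected %s)",
              paste(bad, collapse = ", "), paste(.conditions, collapse = "/")),
      "exergauge_schedule_error"
    )
  }
  invisible(x)
}
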