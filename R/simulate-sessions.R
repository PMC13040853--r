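# Synthetic ATD session series and rater count tables.

#' Effect specification for simulated session series
#'
#' Parameters of the session-level adherence model used to generate
#' alternating-treatments series: a baseline adherence, an additive
#' feedback effect, between-session noise, an optional linear trend, and
#' optional self-counting noise applied in the no-feedback condition
#' (where the child counts their own repetitions). `feedback_delta = 0`
#' with zero miscount noise defines the exchangeable null used for
#' type-I-error studies.
#'
#' @param baseline_adherence Mean adherence without feedback.
#' @param feedback_delta Additive mean shift in the feedback condition.
#' @param session_sd Between-session SD of adherence (>= 0).
#' @param trend_per_session Linear drift per session (signed).
#' @param miscount_sd_no_feedback Extra SD applied to no-feedback
#'   sessions from self-counted repetitions (>= 0).
#' @param seed Integer RNG seed.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(baseline_adherence = 0.85, feedback_delta = 0,
                        session_sd = 0.15, trend_per_session = 0,
                        miscount_sd_no_feedback = 0, seed = 1L) {
  stopifnot(session_sd >= 0, miscount_sd_no_feedback >= 0)
  structure(
    list(baseline_adherence = baseline_adherence,
         feedback_delta = feedback_delta, session_sd = session_sd,
         trend_per_session = trend_per_session,
         miscount_sd_no_feedback = miscount_sd_no_feedback,
         seed = as.integer(seed)),
    class = "effect_spec")
}

#' Simulate an alternating-treatments session series
#'
#' Generates one adherence value per schedule entry:
#' `baseline + delta * [feedback] + trend * (i - 1) + noise`, with extra
#' self-counting noise on no-feedback sessions and values clipped at 0.
#' Identical spec and schedule always reproduce the same series.
#'
#' @param spec An [effect_spec].
#' @param schedule Character vector of condition labels (non-empty).
#' @return An [atd_series] with the adherence outcome.
#' @export
#' @examples
#' sp <- enumerate_schedules(8)
#' sched <- draw_schedule(sp, seed = 3)
#' simulate_atd_sessions(effect_spec(feedback_delta = 0.3, seed = 3), sched)
simulate_atd_sessions <- function(spec, schedule) {
  stopifnot(inherits(spec, "effect_spec"))
  if (length(schedule) == 0) {
    abort_exergauge("schedule must be non-empty", "exergauge_schedule_error")
  }
  check_condition(schedule)
  n <- length(schedule)
  is_f <- schedule == "feedback"
  y <- with_seed(spec$seed, {
    mu <- spec$baseline_adherence + spec$feedback_delta * is_f +
      spec$trend_per_session * (seq_len(n) - 1)
    noise <- stats::rnorm(n, sd = spec$session_sd)
    miscount <- ifelse(is_f, 0,
                       stats::rnorm(n, sd = spec$miscount_sd_no_feedback))
    pmax(mu + noise + miscount, 0)
  })
  atd_series(condition = schedule, outcome = y)
}

#' Simulate paired manual and system repetition counts
#'
#' Generates an agreement table of integer counts per video: the manual
#' rater observes the true count plus rating noise, the system observes
#' the true count plus a systematic bias and tracking noise; both are
#' rounded and clipped at zero.
#'
#' @param n_videos Number of videos (must equal `length(true_counts)`).
#' @param true_counts Non-negative true repetition counts.
#' @param rater_sd Manual rater noise SD (counts).
#' @param system_bias Systematic system miscount (signed counts).
#' @param system_sd System noise SD (counts).
#' @param seed Integer RNG seed.
#' @return Data frame with columns `video_id`, `manual`, `system`.
#' @export
#' @examples
#' simulate_rater_counts(3, c(10, 10, 12), seed = 1)
simulate_rater_counts <- function(n_videos, true_counts, rater_sd = 0,
                                  system_bias = 0, system_sd = 0,
                                  seed = 1L) {
  if (!is_count(n_videos)) {
    abort_exergauge("n_videos must be a non-negative integer",
                    "exergauge_argument_error")
  }
  stopifnot(length(true_counts) == n_videos, all(true_counts >= 0),
            rater_sd >= 0, system_sd >= 0)
  with_seed(seed, {
    manual <- pmax(0, round(true_counts + stats::rnorm(n_videos,
                                                       sd = rater_sd)))
    system <- pmax(0, round(true_counts + system_bias +
                              stats::rnorm(n_videos, sd = system_sd)))
    data.frame(video_id = seq_len(n_videos),
               manual = as.integer(manual), system = as.integer(system))
  })
}
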