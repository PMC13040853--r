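# Single-case alternating-treatments analyses: PND, visual-analysis
# quantification, and the single-case randomization test (SCRT).

#' Construct an alternating-treatments series
#'
#' An `atd_series` is the unit of single-case analysis: ordered sessions,
#' each with a condition label and one outcome value (adherence,
#' fidelity, or a 1-5 rating), optionally tagged with the study phase.
#'
#' @param condition Character vector of `"feedback"`/`"no_feedback"`
#'   labels, in session order.
#' @param outcome Numeric outcome values, same length.
#' @param session_index Optional session ordinals (default 1..n), must be
#'   strictly increasing.
#' @param outcome_name Label of the outcome (e.g. `"adherence"`).
#' @param phase Optional per-session phase labels
#'   (`"comparison"`/`"best_alone"`).
#' @return An object of class `atd_series` (also a data.frame).
#' @export
#' @examples
#' atd_series(c("feedback", "no_feedback", "feedback"), c(1, .8, 1.1))
atd_series <- function(condition, outcome,
                       session_index = seq_along(condition),
                       outcome_name = "adherence", phase = "comparison") {
  check_condition(condition)
  stopifnot(length(condition) == length(outcome),
            is.numeric(outcome))
  if (any(diff(session_index) <= 0)) {
    abort_exergauge("session_index must be strictly increasing",
                    "exergauge_ordering_error")
  }
  out <- data.frame(session_index = session_index, condition = condition,
                    outcome = outcome,
                    phase = rep_len(phase, length(condition)),
                    stringsAsFactors = FALSE)
  attr(out, "outcome_name") <- outcome_name
  class(out) <- c("atd_series", "data.frame")
  out
}

#' Percentage of non-overlapping data (PND)
#'
#' For an alternating-treatments series, comparisons are formed from
#' adjacent condition transitions in session order: walking through the
#' sessions, each transition between two not-yet-compared neighbouring
#' sessions of opposite conditions contributes one between-session
#' comparison, so every session enters at most one comparison. PND is
#' 100 times the fraction of comparisons in which the favoured
#' condition's value strictly exceeds the other's (exact ties count as
#' overlap).
#'
#' @param series An [atd_series].
#' @param favoured The condition whose superiority is being assessed
#'   (default `"feedback"`).
#' @return PND as a percentage in [0, 100].
#' @export
#' @examples
#' s <- atd_series(rep(c("feedback", "no_feedback"), 5),
#'                 c(1.0, .8, 1.1, .9, 1.2, .95, 1.0, 1.1, 1.3, .9))
#' pnd(s)  # 4 favourable of 5 comparisons = 80
pnd <- function(series, favoured = "feedback") {
  stopifnot(inherits(series, "atd_series"))
  check_condition(favoured)
  cond <- series$condition
  y <- series$outcome
  n <- length(cond)
  used <- rep(FALSE, n)
  favourable <- 0L; comparisons <- 0L
  i <- 1L
  while (i < n) {
    if (!used[i] && !used[i + 1] && cond[i] != cond[i + 1]) {
      comparisons <- comparisons + 1L
      fav_val <- if (cond[i] == favoured) y[i] else y[i + 1]
      oth_val <- if (cond[i] == favoured) y[i + 1] else y[i]
      if (fav_val > oth_val) favourable <- favourable + 1L
      used[i] <- used[i + 1] <- TRUE
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  if (comparisons == 0) {
    abort_exergauge("no between-condition comparisons can be formed",
                    "exergauge_insufficient_data_error")
  }
  100 * favourable / comparisons
}

#' Quantified visual analysis of a session series
#'
#' Produces the level / trend / variability labels of structured visual
#' analysis from simple, configurable numeric bands: level compares the
#' series mean with the tertiles of the outcome scale; trend classifies
#' the least-squares slope (normalized to scale ranges per session) into
#' zero-celerating, gradual or steep acceleration/deceleration; and
#' variability classifies the coefficient of variation.
#'
#' @param series An [atd_series] with at least 2 sessions (a single
#'   condition's sub-series is typical).
#' @param scale Numeric length-2 outcome range, e.g. `c(1, 5)` for
#'   smiley ratings or `c(0, 1.25)` for adherence.
#' @param trend_bands Slope thresholds (scale-ranges/session) separating
#'   zero from gradual and gradual from steep trends.
#' @param cv_bands CV thresholds separating stable / somewhat variable /
#'   highly variable.
#' @return List with `level`, `trend`, `variability`, plus the
#'   underlying `mean`, `slope` and `cv`.
#' @export
visual_summary <- function(series, scale,
                           trend_bands = c(zero = 0.01, gradual = 0.05),
                           cv_bands = c(stable = 0.10, somewhat = 0.25)) {
  stopifnot(inherits(series, "atd_series"), length(scale) == 2)
  rng <- diff(sort(scale))
  if (rng <= 0) {
    abort_exergauge("outcome scale must have positive range",
                    "exergauge_scale_error")
  }
  y <- series$outcome
  if (length(y) < 2) {
    abort_exergauge("visual summary needs at least 2 sessions",
                    "exergauge_insufficient_data_error")
  }
  m <- mean(y)
  tert <- sort(scale)[1] + rng * c(1, 2) / 3
  level <- if (m < tert[1]) "low" else if (m < tert[2]) "moderate" else "high"
  slope <- unname(stats::coef(stats::lm(y ~ seq_along(y)))[2]) / rng
  trend <- if (abs(slope) < trend_bands[["zero"]]) {
    "zero-celerating"
  } else {
    mag <- if (abs(slope) < trend_bands[["gradual"]]) "gradual" else "steep"
    dir <- if (slope > 0) "accelerating" else "decelerating"
    paste(mag, dir)
  }
  cv <- if (m == 0) {
    if (stats::sd(y) == 0) 0 else Inf
  } else {
    stats::sd(y) / abs(m)
  }
  variability <- if (cv < cv_bands[["stable"]]) "stable"
  else if (cv < cv_bands[["somewhat"]]) "somewhat variable"
  else "highly variable"
  list(level = level, trend = trend, variability = variability,
       mean = m, slope = slope, cv = cv)
}

#' @keywords internal
new_test_result <- function(method, statistic, p_value = NA_real_,
                            bayes_factor = NA_real_, n_resamples = NA_integer_,
                            seed = NA_integer_, alternative = NA_character_,
                            exhaustive = NA) {
  structure(
    list(method = method, statistic = statistic, p_value = p_value,
         bayes_factor = bayes_factor, n_resamples = n_resamples,
         seed = seed, alternative = alternative, exhaustive = exhaustive),
    class = "exergauge_test")
}

#' @export
print.exergauge_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g", x$method, x$statistic))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.4g", x$p_value))
  if (!is.na(x$bayes_factor)) cat(sprintf(", BF10 = %.4g", x$bayes_factor))
  if (!is.na(x$n_resamples)) {
    cat(sprintf(" (%s, %d resamples)",
                if (isTRUE(x$exhaustive)) "exhaustive" else "Monte-Carlo",
                x$n_resamples))
  }
  cat("\n")
  invisible(x)
}

#' Single-case randomization test
#'
#' Tests whether the observed difference in condition means could have
#' arisen by chance under the design's randomization scheme. The test
#' statistic is the feedback-minus-no-feedback difference in means under
#' the observed schedule; the null distribution recomputes the statistic
#' under every admissible schedule of the restricted randomization space
#' (exhaustive when the space has at most `n_mc` members, otherwise a
#' seeded Monte-Carlo sample that always includes the observed schedule).
#' The one-tailed p-value counts null statistics at least as extreme as
#' the observed one, ties included, so p is always positive.
#'
#' @param series An [atd_series] whose condition labels form the observed
#'   schedule.
#' @param space The `schedule_space` the schedule was drawn from.
#' @param alternative `"greater"` (feedback higher; default, the a priori
#'   hypothesis) or `"less"`.
#' @param n_mc Resampling budget (default 10000).
#' @param seed Seed for the Monte-Carlo branch.
#' @param method `"auto"` (exhaustive when the space fits in `n_mc`,
#'   Monte-Carlo otherwise), `"exhaustive"` or `"monte_carlo"`.
#' @return An `exergauge_test` with the statistic, p-value and
#'   resampling metadata.
#' @export
scrt <- function(series, space, alternative = c("greater", "less"),
                 n_mc = 10000L, seed = 1L,
                 method = c("auto", "exhaustive", "monte_carlo")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  stopifnot(inherits(series, "atd_series"), inherits(space, "schedule_space"))
  obs_sched <- series$condition
  if (length(obs_sched) != space$n_sessions) {
    abort_exergauge("series length does not match the schedule space",
                    "exergauge_design_violation_error")
  }
  sched_strings <- apply(space$schedules, 1, paste, collapse = "|")
  if (!paste(obs_sched, collapse = "|") %in% sched_strings) {
    abort_exergauge("observed schedule is not admissible in the space",
                    "exergauge_design_violation_error")
  }
  y <- series$outcome
  stat_for <- function(sched_is_f) {
    mean(y[sched_is_f]) - mean(y[!sched_is_f])
  }
  obs_stat <- stat_for(obs_sched == "feedback")
  is_f <- space$schedules == "feedback"   # matrix n_schedules x n
  use_exhaustive <- switch(method,
                           auto = space$n_schedules <= n_mc,
                           exhaustive = TRUE, monte_carlo = FALSE)
  if (use_exhaustive) {
    rows <- seq_len(space$n_schedules)
    exhaustive <- TRUE
  } else {
    rows <- with_seed(seed, sample.int(space$n_schedules, n_mc - 1,
                                       replace = TRUE))
    rows <- c(match(paste(obs_sched, collapse = "|"), sched_strings), rows)
    exhaustive <- FALSE
  }
  nf <- rowSums(is_f[rows, , drop = FALSE])
  sums_f <- as.vector(is_f[rows, , drop = FALSE] %*% y)
  null_stats <- sums_f / nf - (sum(y) - sums_f) / (length(y) - nf)
  eps <- 1e-12
  p <- if (alternative == "greater") {
    mean(null_stats >= obs_stat - eps)
  } else {
    mean(null_stats <= obs_stat + eps)
  }
  new_test_result("scrt", obs_stat, p_value = p,
                  n_resamples = length(rows), seed = as.integer(seed),
                  alternative = alternative, exhaustive = exhaustive)
}
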