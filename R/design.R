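# Restricted-randomization alternating-treatments schedules.

#' Enumerate admissible treatment schedules
#'
#' Exhaustively enumerates the condition sequences admissible under the
#' alternating-treatments design's restricted randomization: no more than
#' `max_run` consecutive sessions of the same condition (default 2) and,
#' when `balance` is on, condition counts differing by at most one
#' (equal when `n_sessions` is even).
#'
#' @param n_sessions Number of sessions (>= 1).
#' @param max_run Longest admissible run of identical conditions
#'   (default 2).
#' @param balance Require (near-)equal condition counts (default TRUE).
#' @param enumeration_cap Refuse exhaustive enumeration beyond this many
#'   sessions (default 24); larger designs should be sampled.
#' @return An object of class `schedule_space` with the admissible
#'   schedules as a character matrix (one row per schedule, deterministic
#'   lexicographic order with feedback < no_feedback).
#' @export
#' @examples
#' enumerate_schedules(4)$n_schedules  # 6 balanced max-run-2 sequences
enumerate_schedules <- function(n_sessions, max_run = 2L, balance = TRUE,
                                enumeration_cap = 24L) {
  stopifnot(is_count(n_sessions), n_sessions >= 1,
            is_count(max_run), max_run >= 1)
  if (n_sessions > enumeration_cap) {
    abort_exergauge(
      sprintf("n_sessions = %d exceeds the enumeration cap (%d); sample schedules instead",
              n_sessions, enumeration_cap),
      "exergauge_size_error")
  }
  n <- as.integer(n_sessions)
  # grow prefixes, pruning runs > max_run (and imbalance when required)
  prefixes <- matrix(c(0L, 1L), ncol = 1)
  if (n > 1) {
    for (k in 2:n) {
      ext <- rbind(cbind(prefixes, 0L), cbind(prefixes, 1L))
      keep <- apply(ext, 1, function(s) {
        r <- rle(s)
        if (max(r$lengths) > max_run) return(FALSE)
        if (balance) {
          ones <- sum(s)
          # feasibility: remaining slots must be able to restore balance
          left <- n - length(s)
          lo <- floor(n / 2); hi <- ceiling(n / 2)
          if (ones > hi || (length(s) - ones) > hi) return(FALSE)
        }
        TRUE
      })
      prefixes <- ext[keep, , drop = FALSE]
    }
  }
  if (balance) {
    ones <- rowSums(prefixes)
    keep <- abs(ones - (n - ones)) <= 1
    prefixes <- prefixes[keep, , drop = FALSE]
  }
  # deterministic ordering: lexicographic, feedback (0) first
  ord <- do.call(order, as.data.frame(prefixes))
  prefixes <- prefixes[ord, , drop = FALSE]
  schedules <- matrix(.conditions[prefixes + 1L], nrow = nrow(prefixes))
  structure(
    list(n_sessions = n, max_run = as.integer(max_run),
         balance = isTRUE(balance), schedules = schedules,
         n_schedules = nrow(schedules)),
    class = "schedule_space")
}

#' @export
print.schedule_space <- function(x, ...) {
  cat(sprintf(
    "<schedule_space> %d admissible schedule(s) of %d sessions (max run %d%s)\n",
    x$n_schedules, x$n_sessions, x$max_run,
    if (x$balance) ", balanced" else ""))
  invisible(x)
}

#' Serialize a schedule to its compact single-line form
#'
#' @param schedule Character vector of condition labels.
#' @return Single string of F/N letters (e.g. `"FNFFNN"`).
#' @export
format_schedule <- function(schedule) {
  check_condition(schedule)
  paste(c(feedback = "F", no_feedback = "N")[schedule], collapse = "")
}

#' Parse a compact schedule string
#'
#' @param x String of F/N letters.
#' @return Character vector of condition labels.
#' @export
parse_schedule <- function(x) {
  letters_ <- strsplit(toupper(x), "")[[1]]
  bad <- setdiff(letters_, c("F", "N"))
  if (length(bad) > 0) {
    abort_exergauge(sprintf("unknown schedule letter(s): %s",
                            paste(bad, collapse = ",")),
                    "exergauge_schedule_error")
  }
  unname(c(F = "feedback", N = "no_feedback")[letters_])
}

#' Draw one schedule uniformly from a schedule space
#'
#' @param space A `schedule_space` from [enumerate_schedules()].
#' @param seed Integer seed; the draw is reproducible and does not
#'   disturb the caller's RNG state.
#' @return Character vector of condition labels, one per session.
#' @export
draw_schedule <- function(space, seed) {
  stopifnot(inherits(space, "schedule_space"))
  if (space$n_schedules == 0) {
    abort_exergauge("schedule space is empty", "exergauge_config_error")
  }
  i <- with_seed(seed, sample.int(space$n_schedules, 1))
  space$schedules[i, ]
}

#' Select the condition for the best-alone phase
#'
#' Applies the two-step decision rule used at the end of the comparison
#' phase: if the percentage of non-overlapping data in the adherence
#' series reaches 90% in favour of one condition, that condition is
#' superior; otherwise the condition with the higher mean adherence is
#' carried forward. An exact tie in means is surfaced as `undetermined`
#' rather than silently broken.
#'
#' @param series An [atd_series] of the adherence outcome with at least
#'   one session per condition.
#' @param pnd_threshold PND percentage establishing superiority
#'   (default 90).
#' @return List with `condition` (`"feedback"`, `"no_feedback"` or
#'   `"undetermined"`), `rule` (`"pnd"`, `"mean"` or `"tie"`), the PND
#'   values and condition means considered.
#' @export
select_best_alone <- function(series, pnd_threshold = 90) {
  stopifnot(inherits(series, "atd_series"))
  tab <- table(factor(series$condition, levels = .conditions))
  if (any(tab == 0)) {
    abort_exergauge("each condition needs at least one session",
                    "exergauge_insufficient_data_error")
  }
  pnds <- vapply(.conditions, function(cond) pnd(series, favoured = cond),
                 numeric(1))
  means <- vapply(.conditions, function(cond) {
    mean(series$outcome[series$condition == cond])
  }, numeric(1))
  winner_pnd <- names(pnds)[pnds >= pnd_threshold]
  if (length(winner_pnd) == 1) {
    return(list(condition = winner_pnd, rule = "pnd",
                pnd = pnds, means = means))
  }
  if (means[1] == means[2]) {
    return(list(condition = "undetermined", rule = "tie",
                pnd = pnds, means = means))
  }
  list(condition = names(means)[which.max(means)], rule = "mean",
       pnd = pnds, means = means)
}
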