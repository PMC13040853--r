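# End-to-end trial analysis: session scoring -> design -> statistics ->
# agreement, under one reproducible configuration.

#' Trial configuration
#'
#' Bundles everything a reproducible trial analysis needs: the exercise
#' definitions/prescriptions, the randomization schedule parameters, the
#' analysis settings and the feedback-condition attempt cap.
#'
#' @param participant Participant identifier.
#' @param definitions Named list of [exercise_definition] objects.
#' @param n_sessions,max_run,balance,schedule_seed Restricted-
#'   randomization schedule parameters (see [enumerate_schedules()]).
#' @param alternative One-tailed direction for the condition comparison
#'   (default `"greater"`: feedback higher, the a priori hypothesis).
#' @param n_mc Resampling budget for the randomization/permutation tests.
#' @param alpha Significance level (default 0.05).
#' @param feedback_caps Apply the prescribed+3 attempt cap in feedback
#'   sessions.
#' @param adherence_scale,rating_scale Outcome scales for the visual
#'   summaries.
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(participant = "P01", definitions = exercise_library(),
                         n_sessions = 16L, max_run = 2L, balance = TRUE,
                         schedule_seed = 1L,
                         alternative = c("greater", "less"),
                         n_mc = 10000L, alpha = 0.05, feedback_caps = TRUE,
                         adherence_scale = c(0, 1.5),
                         rating_scale = c(1, 5)) {
  alternative <- match.arg(alternative)
  stopifnot(alpha > 0, alpha < 1)
  if (!all(vapply(definitions, inherits, logical(1),
                  "exercise_definition"))) {
    abort_exergauge("definitions must be exercise_definition objects",
                    "exergauge_config_error")
  }
  structure(
    list(participant = participant, definitions = definitions,
         n_sessions = as.integer(n_sessions), max_run = as.integer(max_run),
         balance = isTRUE(balance), schedule_seed = as.integer(schedule_seed),
         alternative = alternative, n_mc = as.integer(n_mc), alpha = alpha,
         feedback_caps = isTRUE(feedback_caps),
         adherence_scale = adherence_scale, rating_scale = rating_scale),
    class = "trial_config")
}

#' Read a trial configuration from a YAML file
#'
#' Exercise definitions are looked up in [exercise_library()] by name,
#' with `prescribed_reps` / `prescribed_time` / `sets` overridden from
#' the file's `exercises` section.
#'
#' @param path YAML file path.
#' @return A [trial_config].
#' @export
read_trial_config <- function(path) {
  y <- yaml::read_yaml(path)
  lib <- exercise_library()
  defs <- list()
  for (e in y$exercises) {
    d <- get_exercise(e$name)
    if (!is.null(e$reps)) d$prescribed_reps <- as.integer(e$reps)
    if (!is.null(e$time_s)) d$prescribed_time <- as.numeric(e$time_s)
    if (!is.null(e$sets)) d$sets <- as.integer(e$sets)
    if (!is.null(e$supported)) d$supported <- isTRUE(e$supported)
    defs[[d$name]] <- d
  }
  sched <- y$schedule
  ana <- if (is.null(y$analysis)) list() else y$analysis
  trial_config(
    participant = if (is.null(y$participant)) "P01" else y$participant,
    definitions = if (length(defs)) defs else exercise_library(),
    n_sessions = if (is.null(sched$n_sessions)) 16L else sched$n_sessions,
    max_run = if (is.null(sched$max_run)) 2L else sched$max_run,
    balance = if (is.null(sched$balance)) TRUE else sched$balance,
    schedule_seed = if (is.null(sched$seed)) 1L else sched$seed,
    alternative = if (is.null(ana$alternative)) "greater" else ana$alternative,
    n_mc = if (is.null(ana$n_mc)) 10000L else ana$n_mc,
    alpha = if (is.null(ana$alpha)) 0.05 else ana$alpha,
    feedback_caps = if (is.null(y$feedback_caps)) TRUE else y$feedback_caps)
}

# Build an atd_series for one outcome from scored session records.
#' @keywords internal
series_from_records <- function(records, outcome) {
  vals <- vapply(records, function(r) {
    v <- r[[outcome]]
    if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v)
  }, numeric(1))
  keep <- !is.na(vals)
  atd_series(
    condition = vapply(records, `[[`, character(1), "condition")[keep],
    outcome = vals[keep],
    session_index = vapply(records, `[[`, integer(1), "session_index")[keep],
    outcome_name = outcome)
}

# Choose and run the condition-comparison test for one outcome series,
# mirroring the analysis plan: SCRT for adherence when both conditions
# have at least `min_scrt` sessions (else a JZS Bayes factor); for other
# outcomes Fisher-Pitman when the groups are unpaired (unequal sizes),
# Wilcoxon-Pratt when paired.
#' @keywords internal
compare_conditions <- function(series, config, outcome, space = NULL,
                               min_scrt = 5L) {
  f <- series$outcome[series$condition == "feedback"]
  n_ <- series$outcome[series$condition == "no_feedback"]
  if (length(f) == 0 || length(n_) == 0) return(NULL)
  if (outcome == "adherence") {
    if (min(length(f), length(n_)) >= min_scrt && !is.null(space) &&
        length(series$condition) == space$n_sessions) {
      res <- try(scrt(series, space, alternative = config$alternative,
                      n_mc = config$n_mc), silent = TRUE)
      if (!inherits(res, "try-error")) return(res)
    }
    res <- try(bayes_factor_t(f, n_), silent = TRUE)
    return(if (inherits(res, "try-error")) NULL else res)
  }
  if (stats::sd(c(f, n_)) == 0) return(NULL)  # no variance: not testable
  if (length(f) == length(n_)) {
    wilcoxon_pratt(f, n_, alternative = config$alternative,
                   n_mc = config$n_mc)
  } else {
    fisher_pitman(f, n_, alternative = config$alternative,
                  n_mc = config$n_mc)
  }
}

#' Run a full trial analysis
#'
#' Chains the pipeline end to end: scores each comparison-phase session
#' (with the feedback attempt cap), builds the per-outcome series,
#' quantifies the visual analysis (level/trend/variability + PND),
#' applies the best-alone selection rule to adherence, runs the
#' configured condition-comparison tests, and (when manual counts are
#' supplied) the manual-vs-system agreement analyses. All seeds and
#' settings are echoed in the report.
#'
#' @param config A [trial_config].
#' @param session_counts Long data frame with one row per exercise per
#'   session: columns `session_index`, `condition`, `exercise`,
#'   `attempted`, `quality`, and optionally `fun_rating`,
#'   `helpful_rating` (constant within session).
#' @param agreement_table Optional data frame with `manual` and `system`
#'   columns (and optionally `rater2`) for the agreement section.
#' @return An object of class `trial_report`.
#' @export
run_trial <- function(config, session_counts, agreement_table = NULL) {
  stopifnot(inherits(config, "trial_config"))
  check_condition(session_counts$condition)
  space <- enumerate_schedules(config$n_sessions, config$max_run,
                               config$balance)

  records <- list()
  failures <- list()
  for (si in sort(unique(session_counts$session_index))) {
    rows <- session_counts[session_counts$session_index == si, ]
    rec <- tryCatch(
      summarize_session(
        rows[, c("exercise", "attempted", "quality")],
        definitions = config$definitions,
        condition = rows$condition[1], session_index = si,
        feedback_caps = config$feedback_caps,
        fun_rating = if ("fun_rating" %in% names(rows))
          rows$fun_rating[1] else NA_integer_,
        helpful_rating = if ("helpful_rating" %in% names(rows))
          rows$helpful_rating[1] else NA_integer_),
      exergauge_error = function(e) e)
    if (inherits(rec, "error")) {
      failures[[length(failures) + 1]] <-
        list(stage = "scoring", session = si, message = conditionMessage(rec))
    } else {
      records[[length(records) + 1]] <- rec
    }
  }
  if (length(records) == 0) {
    abort_exergauge("no session could be scored", "exergauge_config_error")
  }

  outcomes <- c(adherence = "adherence", fidelity = "fidelity",
                fun = "fun_rating", helpful = "helpful_rating")
  scales <- list(adherence = config$adherence_scale,
                 fidelity = config$adherence_scale,
                 fun = config$rating_scale, helpful = config$rating_scale)
  analysis <- list()
  for (oc in names(outcomes)) {
    series <- try(series_from_records(records, outcomes[[oc]]),
                  silent = TRUE)
    if (inherits(series, "try-error") || nrow(series) < 2) next
    pnd_val <- tryCatch(pnd(series, favoured = "feedback"),
                        exergauge_error = function(e) NA_real_)
    vis <- lapply(stats::setNames(.conditions, .conditions), function(cond) {
      sub <- series[series$condition == cond, , drop = FALSE]
      class(sub) <- class(series)
      if (nrow(sub) < 2) return(NULL)
      visual_summary(sub, scale = scales[[oc]])
    })
    test <- compare_conditions(series, config, oc, space = space)
    analysis[[oc]] <- list(series = series, pnd = pnd_val,
                           visual = vis, test = test)
  }

  best_alone <- tryCatch(
    select_best_alone(analysis$adherence$series),
    exergauge_error = function(e) list(condition = NA_character_,
                                       rule = "insufficient_data"))

  agreement <- NULL
  if (!is.null(agreement_table)) {
    agreement <- list(
      wmre = wmre(agreement_table),
      bland_altman = bland_altman(agreement_table))
    if ("rater2" %in% names(agreement_table)) {
      agreement$icc <- icc_2_1(agreement_table[, c("manual", "rater2")])
    }
  }

  structure(
    list(participant = config$participant, config = config,
         records = records, failures = failures, analysis = analysis,
         best_alone = best_alone, agreement = agreement),
    class = "trial_report")
}

#' @export
print.trial_report <- function(x, ...) {
  cat(sprintf("<trial_report> %s: %d session(s) scored, %d failure(s)\n",
              x$participant, length(x$records), length(x$failures)))
  for (oc in names(x$analysis)) {
    a <- x$analysis[[oc]]
    cat(sprintf("  %-10s PND %.1f%%", oc,
                if (is.na(a$pnd)) NA else a$pnd))
    if (!is.null(a$test)) {
      if (!is.na(a$test$p_value)) cat(sprintf(", %s p = %.3g",
                                              a$test$method, a$test$p_value))
      if (!is.na(a$test$bayes_factor)) cat(sprintf(", BF10 = %.3g",
                                                   a$test$bayes_factor))
    }
    cat("\n")
  }
  cat(sprintf("  best-alone: %s (%s rule)\n",
              x$best_alone$condition, x$best_alone$rule))
  invisible(x)
}

#' Write a trial report to disk
#'
#' Emits a machine-readable results table (`<stem>_results.csv`, one row
#' per outcome with PND, test method, statistic and p/BF, numbers at
#' full precision so a round-trip read reproduces them exactly) and a
#' human-readable summary (`<stem>_summary.txt`). The agreement section
#' is omitted when the report has none.
#'
#' @param report A `trial_report`.
#' @param stem Output path stem (directory must exist).
#' @param pnd_digits Decimal places for PND in the human-readable
#'   summary (default 1).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(report, stem, pnd_digits = 1) {
  stopifnot(inherits(report, "trial_report"))
  rows <- lapply(names(report$analysis), function(oc) {
    a <- report$analysis[[oc]]
    data.frame(
      outcome = oc,
      n_sessions = nrow(a$series),
      pnd = a$pnd,
      method = if (is.null(a$test)) NA_character_ else a$test$method,
      statistic = if (is.null(a$test)) NA_real_ else a$test$statistic,
      p_value = if (is.null(a$test)) NA_real_ else a$test$p_value,
      bayes_factor = if (is.null(a$test)) NA_real_ else a$test$bayes_factor)
  })
  results <- do.call(rbind, rows)
  csv <- paste0(stem, "_results.csv")
  txt <- paste0(stem, "_summary.txt")
  # full precision so the round trip is lossless
  utils::write.csv(format(results, digits = 17, trim = TRUE, scientific = FALSE),
                   csv, row.names = FALSE, quote = FALSE, na = "")
  lines <- c(sprintf("Trial report: %s", report$participant),
             sprintf("Sessions scored: %d (failures: %d)",
                     length(report$records), length(report$failures)))
  for (oc in names(report$analysis)) {
    a <- report$analysis[[oc]]
    lines <- c(lines, sprintf("%s: PND %.*f%%", oc, pnd_digits, a$pnd))
  }
  lines <- c(lines, sprintf("Best-alone condition: %s (rule: %s)",
                            report$best_alone$condition,
                            report$best_alone$rule))
  if (!is.null(report$agreement)) {
    lines <- c(lines, sprintf(
      "Agreement: WMRE %.1f%% (%s); Bland-Altman bias %.2f [%.2f, %.2f]",
      report$agreement$wmre$wmre,
      if (report$agreement$wmre$acceptable) "acceptable" else "not acceptable",
      report$agreement$bland_altman$bias,
      report$agreement$bland_altman$loa[1],
      report$agreement$bland_altman$loa[2]))
  }
  writeLines(lines, txt)
  invisible(c(csv, txt))
}
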