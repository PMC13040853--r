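# End-to-end trial runs: orchestration, determinism, stage isolation.

# simulate session counts for a full comparison phase
make_session_counts <- function(schedule, defs, delta = 0.3, sd = 0.02,
                                seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_along(schedule)) {
    for (ex in names(defs)) {
      presc <- if (defs[[ex]]$mode == "reps") defs[[ex]]$prescribed_reps
      else defs[[ex]]$prescribed_time
      adh <- 0.8 + delta * (schedule[i] == "feedback") + rnorm(1, sd = sd)
      att <- max(0, round(presc * adh))
      rows[[length(rows) + 1]] <- data.frame(
        session_index = i, condition = schedule[i], exercise = ex,
        attempted = att, quality = round(att * 0.5),
        fun_rating = sample(3:5, 1), helpful_rating = sample(3:5, 1))
    }
  }
  do.call(rbind, rows)
}

test_that("a strong feedback effect is detected end to end via the PND rule", {
  defs <- exercise_library(prescribed_reps = 10L)[c("squat", "kick")]
  cfg <- trial_config(participant = "sim01", definitions = defs,
                      n_sessions = 8L)
  space <- enumerate_schedules(8)
  sched <- draw_schedule(space, seed = 31)
  counts <- make_session_counts(sched, defs, delta = 0.3, sd = 0.01)
  rep_ <- run_trial(cfg, counts)
  expect_equal(rep_$best_alone$condition, "feedback")
  expect_equal(rep_$best_alone$rule, "pnd")
  expect_gte(rep_$analysis$adherence$pnd, 90)
  expect_length(rep_$records, 8)
})

test_that("trial reports are byte-identical across reruns", {
  defs <- exercise_library(prescribed_reps = 10L)[c("squat", "forward_step")]
  cfg <- trial_config(participant = "sim02", definitions = defs,
                      n_sessions = 8L)
  sched <- draw_schedule(enumerate_schedules(8), seed = 7)
  counts <- make_session_counts(sched, defs, delta = 0.1, sd = 0.1, seed = 3)
  tab <- simulate_rater_counts(6, rep(10, 6), rater_sd = 1, system_sd = 2,
                               seed = 4)
  tab$rater2 <- tab$manual + c(0L, 1L, -1L, 0L, 2L, 0L)
  dir <- withr::local_tempdir()
  r1 <- run_trial(cfg, counts, agreement_table = tab)
  f1 <- write_report(r1, file.path(dir, "a"))
  r2 <- run_trial(cfg, counts, agreement_table = tab)
  f2 <- write_report(r2, file.path(dir, "b"))
  expect_identical(readLines(f1[1]), readLines(f2[1]))
  expect_identical(readLines(f1[2]), readLines(f2[2]))
  # results table round-trips numerically
  res <- utils::read.csv(f1[1])
  expect_equal(res$pnd[res$outcome == "adherence"],
               r1$analysis$adherence$pnd, tolerance = 1e-12)
  # agreement section present in the summary
  expect_true(any(grepl("WMRE", readLines(f1[2]))))
})

test_that("the agreement section is omitted when no counts are supplied", {
  defs <- exercise_library(prescribed_reps = 10L)["squat"]
  cfg <- trial_config(definitions = defs, n_sessions = 8L)
  sched <- draw_schedule(enumerate_schedules(8), seed = 2)
  counts <- make_session_counts(sched, defs, seed = 5)
  rep_ <- run_trial(cfg, counts)
  expect_null(rep_$agreement)
  dir <- withr::local_tempdir()
  files <- write_report(rep_, file.path(dir, "r"))
  expect_false(any(grepl("WMRE", readLines(files[2]))))
})

test_that("one failing session does not poison the others", {
  defs <- exercise_library(prescribed_reps = 10L)["squat"]
  cfg <- trial_config(definitions = defs, n_sessions = 8L)
  sched <- draw_schedule(enumerate_schedules(8), seed = 9)
  counts <- make_session_counts(sched, defs, seed = 6)
  counts$exercise[counts$session_index == 3] <- "not_an_exercise"
  rep_ <- run_trial(cfg, counts)
  expect_length(rep_$records, 7)
  expect_length(rep_$failures, 1)
  expect_equal(rep_$failures[[1]]$session, 3)
  expect_equal(rep_$failures[[1]]$stage, "scoring")
})

test_that("trial configs load from YAML with per-exercise overrides", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "participant: C01",
    "feedback_caps: true",
    "schedule:",
    "  n_sessions: 8",
    "  max_run: 2",
    "  seed: 5",
    "analysis:",
    "  alternative: greater",
    "  n_mc: 2000",
    "exercises:",
    "  - name: squat",
    "    reps: 6",
    "    sets: 2",
    "  - name: calf_stretch",
    "    time_s: 20",
    "    supported: true"), path)
  cfg <- read_trial_config(path)
  expect_equal(cfg$participant, "C01")
  expect_equal(cfg$n_sessions, 8L)
  expect_equal(cfg$definitions$squat$prescribed_reps, 6L)
  expect_equal(cfg$definitions$squat$sets, 2L)
  expect_equal(cfg$definitions$calf_stretch$prescribed_time, 20)
  expect_true(cfg$definitions$calf_stretch$supported)
  expect_equal(cfg$n_mc, 2000L)
})
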