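# Restricted-randomization schedules and the best-alone selection rule.

# brute-force oracle: all 2^n sequences, filtered
brute_force_space <- function(n, max_run, balance) {
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  keep <- apply(grid, 1, function(s) {
    if (max(rle(s)$lengths) > max_run) return(FALSE)
    if (balance && abs(sum(s) - (n - sum(s))) > 1) return(FALSE)
    TRUE
  })
  grid[keep, , drop = FALSE]
}

test_that("schedule enumeration matches the exhaustive filter oracle", {
  for (case in list(c(4, 2, TRUE), c(6, 2, TRUE), c(6, 2, FALSE),
                    c(5, 3, TRUE), c(7, 1, FALSE))) {
    sp <- enumerate_schedules(case[1], case[2], as.logical(case[3]))
    oracle <- brute_force_space(case[1], case[2], as.logical(case[3]))
    expect_equal(sp$n_schedules, nrow(oracle))
    # same membership
    got <- sort(apply(sp$schedules, 1, function(r) {
      paste(as.integer(r == "no_feedback"), collapse = "")
    }))
    want <- sort(apply(oracle, 1, paste, collapse = ""))
    expect_identical(got, want)
  }
})

test_that("n=4 balanced max-run-2 admits all six two-of-each sequences", {
  expect_equal(enumerate_schedules(4)$n_schedules, 6)
})

test_that("strict alternation is the only max-run-1 design", {
  sp <- enumerate_schedules(3, max_run = 1, balance = FALSE)
  expect_setequal(apply(sp$schedules, 1, format_schedule), c("FNF", "NFN"))
})

test_that("all members satisfy the run-length and balance invariants", {
  sp <- enumerate_schedules(10, max_run = 2, balance = TRUE)
  for (i in seq_len(sp$n_schedules)) {
    s <- sp$schedules[i, ]
    expect_lte(max(rle(s)$lengths), 2)
    expect_equal(sum(s == "feedback"), 5)
  }
})

test_that("oversized designs are refused with a size error", {
  expect_error(enumerate_schedules(25), class = "exergauge_size_error")
})

test_that("schedule draws are uniform, reproducible and members of the space", {
  sp <- enumerate_schedules(4)
  expect_identical(draw_schedule(sp, seed = 42), draw_schedule(sp, seed = 42))
  draws <- vapply(1:6000, function(s) format_schedule(draw_schedule(sp, s)),
                  character(1))
  freqs <- table(draws)
  expect_length(freqs, 6)
  se <- sqrt((1 / 6) * (5 / 6) / 6000)
  expect_true(all(abs(freqs / 6000 - 1 / 6) < 3 * se + 1e-9))
  all_scheds <- apply(sp$schedules, 1, format_schedule)
  expect_true(all(draws %in% all_scheds))
})

test_that("schedule strings round-trip", {
  s <- c("feedback", "no_feedback", "feedback", "feedback")
  expect_identical(parse_schedule(format_schedule(s)), s)
  expect_error(parse_schedule("FXN"), class = "exergauge_schedule_error")
})

test_that("best-alone selection fires the PND rule at 90% non-overlap", {
  s <- alternating_series(5, 5)  # PND 100 favouring feedback
  res <- select_best_alone(s)
  expect_equal(res$condition, "feedback")
  expect_equal(res$rule, "pnd")
})

test_that("below 90% PND the higher mean decides, in either direction", {
  s <- alternating_series(5, 4)  # PND 80
  # feedback mean is higher by construction
  res <- select_best_alone(s)
  expect_equal(res$rule, "mean")
  expect_equal(res$condition, "feedback")
  # flip the labels: no_feedback should now win via the mean rule
  flipped <- atd_series(
    condition = ifelse(s$condition == "feedback", "no_feedback", "feedback"),
    outcome = s$outcome)
  res2 <- select_best_alone(flipped)
  expect_equal(res2$rule, "mean")
  expect_equal(res2$condition, "no_feedback")
})

test_that("an exact mean tie is surfaced as undetermined", {
  s <- atd_series(c("feedback", "no_feedback", "no_feedback", "feedback"),
                  c(1, 0.5, 1, 0.5))
  res <- select_best_alone(s)
  expect_equal(res$condition, "undetermined")
  expect_equal(res$rule, "tie")
})

test_that("selection needs at least one session per condition", {
  s <- atd_series(rep("feedback", 3), c(1, 1, 1))
  expect_error(select_best_alone(s),
               class = "exergauge_insufficient_data_error")
})
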