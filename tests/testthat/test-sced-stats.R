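# PND, visual-analysis quantification, and the single-case
# randomization test.

test_that("pnd reproduces favourable/total comparison ratios", {
  expect_equal(pnd(alternating_series(5, 4)), 80)
  expect_equal(pnd(alternating_series(4, 1)), 25)
  expect_equal(pnd(alternating_series(4, 2)), 50)
  expect_equal(pnd(alternating_series(2, 0)), 0)
  expect_equal(pnd(alternating_series(6, 5)), 100 * 5 / 6)
})

test_that("exact ties count as overlap and pnd stays in [0, 100]", {
  s <- atd_series(c("feedback", "no_feedback"), c(0.8, 0.8))
  expect_equal(pnd(s), 0)
  set.seed(202)
  for (i in 1:25) {
    n <- sample(2:12, 1)
    s <- atd_series(sample(c("feedback", "no_feedback"), n, replace = TRUE),
                    runif(n))
    p <- tryCatch(pnd(s), exergauge_insufficient_data_error = function(e) NA)
    if (!is.na(p)) {
      expect_gte(p, 0); expect_lte(p, 100)
      # invariant to adding a constant to every outcome
      s2 <- atd_series(s$condition, s$outcome + 3.7)
      expect_equal(pnd(s2), p)
    }
  }
})

test_that("each session enters at most one adjacent-transition comparison", {
  # 2 feedback vs 3 no-feedback in a run: only two transitions usable
  s <- atd_series(c("no_feedback", "feedback", "no_feedback", "no_feedback",
                    "feedback"),
                  c(0.5, 1.0, 0.6, 0.7, 1.1))
  expect_equal(pnd(s), 100)  # comparisons: (1,2) and (3 or 4, 5)
  s_single <- atd_series(rep("feedback", 2), c(1, 1))
  expect_error(pnd(s_single), class = "exergauge_insufficient_data_error")
})

test_that("visual summaries label level, trend and variability", {
  const <- atd_series(rep(c("feedback", "no_feedback"), 3), rep(1, 6))
  v <- visual_summary(const, scale = c(0, 1.25))
  expect_equal(v$trend, "zero-celerating")
  expect_equal(v$variability, "stable")

  rising <- atd_series(rep("feedback", 5), c(0.90, 0.92, 0.94, 0.96, 0.98))
  v2 <- visual_summary(rising, scale = c(0, 1.25))
  expect_equal(v2$level, "high")
  expect_equal(v2$trend, "gradual accelerating")

  top_ratings <- atd_series(rep("feedback", 4), rep(5, 4))
  v3 <- visual_summary(top_ratings, scale = c(1, 5))
  expect_equal(v3$level, "high")
  expect_equal(v3$trend, "zero-celerating")
  expect_equal(v3$variability, "stable")

  falling <- atd_series(rep("feedback", 5), c(5, 4, 3, 2, 1))
  expect_equal(visual_summary(falling, scale = c(1, 5))$trend,
               "steep decelerating")
  expect_error(visual_summary(const, scale = c(2, 2)),
               class = "exergauge_scale_error")
})

test_that("constant outcomes give an SCRT p of exactly 1", {
  sp <- enumerate_schedules(8)
  sched <- draw_schedule(sp, seed = 1)
  s <- atd_series(sched, rep(0.9, 8))
  expect_equal(scrt(s, sp)$p_value, 1)
})

test_that("Monte-Carlo SCRT agrees with exhaustive enumeration", {
  sp <- enumerate_schedules(8)
  sched <- draw_schedule(sp, seed = 4)
  s <- simulate_atd_sessions(effect_spec(feedback_delta = 0.15, seed = 8),
                             sched)
  p_ex <- scrt(s, sp, method = "exhaustive")$p_value
  p_mc <- scrt(s, sp, method = "monte_carlo", n_mc = 10000)$p_value
  expect_lt(abs(p_ex - p_mc), 0.01)
})

test_that("the SCRT null set is exactly the restricted schedule space", {
  sp <- enumerate_schedules(8)
  sched <- draw_schedule(sp, seed = 2)
  s <- simulate_atd_sessions(effect_spec(seed = 3), sched)
  res <- scrt(s, sp)
  expect_true(res$exhaustive)
  expect_equal(res$n_resamples, sp$n_schedules)
  expect_gte(res$p_value, 1 / sp$n_schedules)
  # an inadmissible observed schedule (run of 3) violates the design
  bad <- atd_series(c(rep("feedback", 3), rep("no_feedback", 3),
                      "feedback", "no_feedback"),
                    runif(8))
  expect_error(scrt(bad, sp), class = "exergauge_design_violation_error")
})

test_that("SCRT power grows with the feedback effect", {
  sp <- enumerate_schedules(12)
  deltas <- c(0, 0.1, 0.2, 0.3)
  rates <- vapply(deltas, function(d) {
    rej <- 0L
    for (i in 1:120) {
      sched <- draw_schedule(sp, seed = 1000 + i)
      s <- simulate_atd_sessions(
        effect_spec(feedback_delta = d, session_sd = 0.15,
                    seed = 5000 + i), sched)
      if (scrt(s, sp)$p_value <= 0.05) rej <- rej + 1L
    }
    rej / 120
  }, numeric(1))
  # monotone up to Monte-Carlo wiggle
  expect_true(all(diff(rates) > -0.05))
  expect_gt(rates[4], rates[1])
})
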