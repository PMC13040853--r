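# WMRE, ICC(2,1) and Bland-Altman statistics.

test_that("WMRE is exact on its boundary and hand-computed cases", {
  expect_equal(wmre(data.frame(manual = c(10, 5), system = c(10, 5)))$wmre, 0)
  full_miss <- wmre(data.frame(manual = c(10, 8), system = c(0, 0)))
  expect_equal(full_miss$wmre, 100)
  expect_false(full_miss$acceptable)
  hand <- wmre(data.frame(manual = c(10, 20), system = c(8, 25)))
  expect_equal(hand$wmre, 100 * (2 + 5) / 30)
  expect_true(hand$acceptable)  # 23.33% < 25%
  expect_error(wmre(data.frame(manual = c(0, 0), system = c(1, 2))),
               class = "exergauge_undefined_denominator_error")
})

test_that("WMRE is invariant to count rescaling and weights by manual", {
  tab <- data.frame(manual = c(12, 6, 20), system = c(10, 8, 18))
  expect_equal(wmre(tab)$wmre,
               wmre(transform(tab, manual = 2 * manual,
                              system = 2 * system))$wmre)
  # unweighted per-video mean differs when errors are uneven
  expect_false(isTRUE(all.equal(wmre(tab)$wmre,
                                wmre(tab, aggregation = "mean")$wmre)))
})

test_that("identical raters give ICC exactly 1 with excellent grade", {
  x <- cbind(c(3, 7, 5, 9, 4, 6), c(3, 7, 5, 9, 4, 6))
  res <- icc_2_1(x)
  expect_equal(res$icc, 1)
  expect_equal(res$grade, "excellent")
  expect_equal(res$ci, c(1, 1))
})

test_that("a constant rater offset pulls ICC below 1 (absolute agreement)", {
  x <- cbind(c(3, 7, 5, 9, 4, 6), c(3, 7, 5, 9, 4, 6) + 5)
  expect_lt(icc_2_1(x)$icc, 1)
})

test_that("ICC estimate and CI match the mean-squares hand oracle", {
  x <- cbind(r1 = c(9, 6, 8, 7, 10, 6), r2 = c(2, 1, 4, 1, 5, 2))
  n <- nrow(x); k <- ncol(x)
  # hand computation of the two-way mean squares
  grand <- mean(x)
  msr <- k * sum((rowMeans(x) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(x) - grand)^2) / (k - 1)
  mse <- (sum((x - grand)^2) - (n - 1) * msr - (k - 1) * msc) /
    ((n - 1) * (k - 1))
  icc_hand <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  res <- icc_2_1(x)
  expect_equal(res$icc, icc_hand, tolerance = 1e-10)
  # F-based CI (two-way random, absolute agreement, single measure)
  a <- k * icc_hand / (n * (1 - icc_hand))
  b <- 1 + k * icc_hand * (n - 1) / (n * (1 - icc_hand))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- qf(0.975, n - 1, v)
  fu <- qf(0.975, v, n - 1)
  lo <- n * (msr - fl * mse) / (fl * (k * msc + (k * n - k - n) * mse) +
                                  n * msr)
  hi <- n * (fu * msr - mse) / (k * msc + (k * n - k - n) * mse +
                                  n * fu * msr)
  expect_equal(res$ci, c(lo, hi), tolerance = 1e-10)
})

test_that("ICC input contracts are enforced", {
  expect_error(icc_2_1(cbind(1:2, 1:2)),
               class = "exergauge_insufficient_data_error")
  expect_error(icc_2_1(cbind(c(1, NA, 3), c(1, 2, 3))),
               class = "exergauge_completeness_error")
})

test_that("simulation with known variance components recovers the ICC", {
  # two-way random model: subject, rater and error variances
  var_s <- 4; var_r <- 0.5; var_e <- 1
  icc_true <- var_s / (var_s + var_r + var_e)
  n <- 30; k <- 3
  set.seed(91)
  covered <- 0L; reps <- 500L
  est <- numeric(reps)
  for (i in seq_len(reps)) {
    subj <- rnorm(n, sd = sqrt(var_s))
    rater <- rnorm(k, sd = sqrt(var_r))
    x <- outer(subj, rater, `+`) + matrix(rnorm(n * k, sd = sqrt(var_e)),
                                          n, k)
    res <- icc_2_1(x)
    est[i] <- res$icc
    if (res$ci[1] <= icc_true && icc_true <= res$ci[2]) covered <- covered + 1L
  }
  expect_lt(abs(mean(est) - icc_true), 0.03)
  expect_gt(covered / reps, 0.90)   # approximately 95% coverage
  expect_lt(covered / reps, 0.99)
})

test_that("Bland-Altman bias and limits match the sample-SD oracle", {
  d <- c(1, -1, 2, -2)
  tab <- data.frame(manual = rep(10, 4), system = 10 + d)
  res <- bland_altman(tab)
  expect_equal(res$bias, 0)
  expect_equal(res$loa, c(-1.96, 1.96) * sd(d))
  # identical columns degenerate to zero-width limits
  same <- bland_altman(data.frame(manual = c(4, 7, 5), system = c(4, 7, 5)))
  expect_equal(same$bias, 0)
  expect_equal(same$loa, c(0, 0))
  # translation invariance
  shifted <- bland_altman(transform(tab, manual = manual + 3,
                                    system = system + 3))
  expect_equal(shifted$bias, res$bias)
  expect_equal(shifted$loa, res$loa)
  expect_error(bland_altman(data.frame(manual = 1, system = 2)),
               class = "exergauge_insufficient_data_error")
})

test_that("Bland-Altman limits cover about 95% of Gaussian differences", {
  set.seed(92)
  n <- 20000
  tab <- data.frame(manual = rnorm(n, 10, 1), system = rnorm(n, 10.5, 1))
  res <- bland_altman(tab)
  inside <- mean(res$pairs$difference >= res$loa[1] &
                   res$pairs$difference <= res$loa[2])
  expect_lt(abs(inside - 0.95), 0.01)
})
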