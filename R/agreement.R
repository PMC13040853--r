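# Manual-vs-system and rater-vs-rater agreement statistics.

#' Weighted mean relative error (WMRE)
#'
#' Aggregate relative error of system repetition counts against manual
#' counts treated as ground truth:
#' `100 * sum(|system - manual|) / sum(manual)`. This is the mean of the
#' per-video relative errors weighted by the manual counts, so a system
#' that records nothing scores exactly 100%. A WMRE below 25% is graded
#' acceptable; larger errors would push a child into the wrong
#' movement-quality star band regardless of actual performance. An
#' unweighted per-video mean is available via `aggregation = "mean"`.
#'
#' @param table Data frame with columns `manual` and `system` (counts or
#'   times, one row per video).
#' @param aggregation `"ratio_of_sums"` (default) or `"mean"`.
#' @param threshold Acceptability threshold in percent (default 25).
#' @return List with `wmre` (percent) and `acceptable` (flag).
#' @export
#' @examples
#' wmre(data.frame(manual = c(10, 20), system = c(8, 25)))  # 23.33%
wmre <- function(table, aggregation = c("ratio_of_sums", "mean"),
                 threshold = 25) {
  aggregation <- match.arg(aggregation)
  stopifnot(is.data.frame(table),
            all(c("manual", "system") %in% names(table)))
  m <- table$manual; s <- table$system
  stopifnot(all(m >= 0), all(s >= 0), nrow(table) >= 1)
  if (sum(m) == 0) {
    abort_exergauge("all manual counts are zero: WMRE undefined",
                    "exergauge_undefined_denominator_error")
  }
  value <- if (aggregation == "ratio_of_sums") {
    100 * sum(abs(s - m)) / sum(m)
  } else {
    keep <- m > 0
    100 * mean(abs(s[keep] - m[keep]) / m[keep])
  }
  list(wmre = value, acceptable = value < threshold)
}

#' ICC(2,1): two-way random effects, absolute agreement, single measure
#'
#' Intraclass correlation for agreement between raters drawn from a
#' larger population of raters, estimated from the mean squares of the
#' two-way (subjects x raters) decomposition with the 95% confidence
#' interval from exact F-distribution bounds. Reliability is graded
#' `excellent` at 0.90 or above, `good` from 0.75 to 0.90, `moderate`
#' from 0.50 to 0.75 and `poor` below 0.50.
#'
#' @param ratings Numeric matrix or data frame, subjects in rows (>= 3),
#'   raters in columns (>= 2), no missing cells.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `icc`, `ci` (lower, upper), `grade`, `p_value` (for
#'   the test of ICC = 0) and the mean squares.
#' @export
#' @examples
#' x <- cbind(r1 = c(9, 6, 8, 7, 10, 6), r2 = c(2, 1, 4, 1, 5, 2))
#' icc_2_1(x)$icc
icc_2_1 <- function(ratings, conf_level = 0.95) {
  x <- as.matrix(ratings)
  if (any(is.na(x))) {
    abort_exergauge("ratings table has missing cells",
                    "exergauge_completeness_error")
  }
  n <- nrow(x); k <- ncol(x)
  if (n < 3 || k < 2) {
    abort_exergauge("need at least 3 subjects and 2 raters",
                    "exergauge_insufficient_data_error")
  }
  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((x - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)       # subjects
  msc <- ss_cols / (k - 1)       # raters
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  alpha <- 1 - conf_level
  if (mse == 0 && msc == 0) {
    # perfect agreement: the interval degenerates at 1
    ci <- c(1, 1)
    p <- 0
  } else {
    fj <- msc / mse
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lower, upper)
    f0 <- msr / mse
    p <- stats::pf(f0, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  }
  grade <- if (icc >= 0.90) "excellent" else if (icc >= 0.75) "good"
  else if (icc >= 0.50) "moderate" else "poor"
  list(icc = icc, ci = ci, grade = grade, p_value = p,
       ms = c(subjects = msr, raters = msc, error = mse),
       n_subjects = n, n_raters = k)
}

#' Bland-Altman agreement statistics
#'
#' Bias (mean system-minus-manual difference) and 95% limits of
#' agreement (`bias +/- 1.96 * SD(differences)`) between two measurement
#' methods, with the per-row (mean, difference) pairs exposed for
#' plotting.
#'
#' @param table Data frame with columns `manual` and `system`.
#' @return List with `bias`, `loa` (lower, upper), `sd_diff` and a
#'   `pairs` data frame (`mean`, `difference`).
#' @export
bland_altman <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("manual", "system") %in% names(table)))
  if (nrow(table) < 2) {
    abort_exergauge("Bland-Altman needs at least 2 paired measurements",
                    "exergauge_insufficient_data_error")
  }
  d <- table$system - table$manual
  bias <- mean(d)
  sd_d <- stats::sd(d)
  list(bias = bias,
       loa = c(bias - 1.96 * sd_d, bias + 1.96 * sd_d),
       sd_diff = sd_d,
       pairs = data.frame(mean = (table$system + table$manual) / 2,
                          difference = d))
}
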