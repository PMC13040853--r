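# Permutation tests: Fisher-Pitman (unpaired) and Wilcoxon-Pratt signed
# rank (paired), both with exhaustive enumeration when feasible.

#' Fisher-Pitman permutation test
#'
#' Compares two independent groups by permuting group labels. The
#' statistic is `mean(a) - mean(b)`; the null distribution reassigns the
#' pooled values to groups of the observed sizes, exhaustively when the
#' number of assignments is within `n_mc`, otherwise by a seeded
#' Monte-Carlo sample that includes the observed assignment. One-tailed
#' p-values count ties as extreme.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param alternative `"greater"` (mean of `a` higher) or `"less"`.
#' @param n_mc Resampling budget (default 10000).
#' @param seed Seed for the Monte-Carlo branch.
#' @param method `"auto"` (exhaustive when feasible within `n_mc`),
#'   `"exhaustive"` or `"monte_carlo"`.
#' @return An `exergauge_test`.
#' @export
#' @examples
#' fisher_pitman(c(3, 4), c(1, 2))$p_value  # 1/6
fisher_pitman <- function(a, b, alternative = c("greater", "less"),
                          n_mc = 10000L, seed = 1L,
                          method = c("auto", "exhaustive", "monte_carlo")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (length(a) == 0 || length(b) == 0) {
    abort_exergauge("both groups must be non-empty",
                    "exergauge_insufficient_data_error")
  }
  pooled <- c(a, b)
  na <- length(a); n <- length(pooled)
  obs <- mean(a) - mean(b)
  n_comb <- choose(n, na)
  stat_from_idx <- function(idx) {
    sa <- sum(pooled[idx])
    sa / na - (sum(pooled) - sa) / (n - na)
  }
  use_exhaustive <- switch(method, auto = n_comb <= n_mc,
                           exhaustive = TRUE, monte_carlo = FALSE)
  if (use_exhaustive) {
    combs <- utils::combn(n, na)
    null_stats <- apply(combs, 2, stat_from_idx)
    exhaustive <- TRUE
  } else {
    null_stats <- with_seed(seed, {
      vapply(seq_len(n_mc - 1),
             function(i) stat_from_idx(sample.int(n, na)), numeric(1))
    })
    null_stats <- c(obs, null_stats)
    exhaustive <- FALSE
  }
  eps <- 1e-12
  p <- if (alternative == "greater") mean(null_stats >= obs - eps)
  else mean(null_stats <= obs + eps)
  new_test_result("fisher_pitman", obs, p_value = p,
                  n_resamples = length(null_stats), seed = as.integer(seed),
                  alternative = alternative, exhaustive = exhaustive)
}

#' Wilcoxon-Pratt signed-rank permutation test
#'
#' Paired-sample signed-rank test with Pratt's treatment of zero
#' differences: zeros are ranked together with all absolute differences,
#' then discarded, so they still displace the ranks of the non-zero
#' differences. The statistic is the sum of ranks of the positive
#' differences; the null distribution flips the signs of the non-zero
#' differences (exhaustively over all 2^m flips when feasible, Monte
#' Carlo otherwise). With no non-zero differences the test degenerates
#' and p = 1.
#'
#' @param a,b Paired numeric vectors of equal length (>= 1).
#' @param alternative `"greater"` (`a` tends to exceed `b`) or `"less"`.
#' @param n_mc Resampling budget (default 10000).
#' @param seed Seed for the Monte-Carlo branch.
#' @param method `"auto"` (exhaustive when feasible within `n_mc`),
#'   `"exhaustive"` or `"monte_carlo"`.
#' @return An `exergauge_test` whose statistic is the positive-rank sum.
#' @export
wilcoxon_pratt <- function(a, b, alternative = c("greater", "less"),
                           n_mc = 10000L, seed = 1L,
                           method = c("auto", "exhaustive", "monte_carlo")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (length(a) != length(b)) {
    abort_exergauge("paired samples must have equal length",
                    "exergauge_pairing_error")
  }
  if (length(a) == 0) {
    abort_exergauge("paired samples must be non-empty",
                    "exergauge_insufficient_data_error")
  }
  d <- a - b
  r <- rank(abs(d))          # zeros ranked with everything (Pratt)
  nz <- d != 0
  m <- sum(nz)
  if (m == 0) {
    return(new_test_result("wilcoxon_pratt", 0, p_value = 1,
                           n_resamples = 1L, seed = as.integer(seed),
                           alternative = alternative, exhaustive = TRUE))
  }
  rnz <- r[nz]
  signs <- sign(d[nz])
  wpos <- sum(rnz[signs > 0])
  use_exhaustive <- switch(method, auto = 2^m <= n_mc,
                           exhaustive = TRUE, monte_carlo = FALSE)
  if (use_exhaustive) {
    # exhaustive sign flips
    grid <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    null_stats <- as.vector(grid %*% rnz)
    exhaustive <- TRUE
  } else {
    null_stats <- with_seed(seed, {
      vapply(seq_len(n_mc - 1), function(i) {
        sum(rnz[stats::runif(m) < 0.5])
      }, numeric(1))
    })
    null_stats <- c(wpos, null_stats)
    exhaustive <- FALSE
  }
  eps <- 1e-12
  p <- if (alternative == "greater") mean(null_stats >= wpos - eps)
  else mean(null_stats <= wpos + eps)
  new_test_result("wilcoxon_pratt", wpos, p_value = p,
                  n_resamples = length(null_stats), seed = as.integer(seed),
                  alternative = alternative, exhaustive = exhaustive)
}
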