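# Independent enumeration oracles shared across test files.

# Oracle: one-tailed Fisher-Pitman p by direct enumeration of every
# assignment of the pooled values to a group of size na.
fp_oracle <- function(a, b, alternative = "greater") {
  pooled <- c(a, b)
  na <- length(a)
  obs <- mean(a) - mean(b)
  idx <- utils::combn(length(pooled), na)
  stats <- apply(idx, 2, function(i) mean(pooled[i]) - mean(pooled[-i]))
  if (alternative == "greater") mean(stats >= obs - 1e-12)
  else mean(stats <= obs + 1e-12)
}

# Oracle: Wilcoxon-Pratt p by enumerating all sign assignments of the
# non-zero differences, with zeros kept in the ranking then dropped.
wp_oracle <- function(a, b, alternative = "greater") {
  d <- a - b
  r <- rank(abs(d))
  rnz <- r[d != 0]
  if (length(rnz) == 0) return(1)
  wobs <- sum(rnz[d[d != 0] > 0])
  m <- length(rnz)
  stats <- numeric(2^m)
  for (code in 0:(2^m - 1)) {
    bits <- as.integer(intToBits(code))[1:m]
    stats[code + 1] <- sum(rnz[bits == 1])
  }
  if (alternative == "greater") mean(stats >= wobs - 1e-12)
  else mean(stats <= wobs + 1e-12)
}

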