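# independent oracles used by several test files

# textbook fixed-effect meta-analysis
fe_meta_oracle <- function(z, se) {
  w <- se^-2
  zbar <- sum(w * z) / sum(w)
  Q <- sum(w * (z - zbar)^2)
  list(Q = Q, p = stats::pchisq(Q, length(z) - 1, lower.tail = FALSE))
}

# brute-force IQR outlier rule: explicit interpolation arithmetic, no
# quantile() call; same boundary-tie convention (exact ties are inside)
brute_iqr_rule <- function(e, k = 2) {
  b <- sort(e)
  q1 <- b[1] + 0.75 * (b[2] - b[1])
  q3 <- b[3] + 0.25 * (b[4] - b[3])
  iqr <- q3 - q1
  lo_bound <- q1 - k * iqr
  hi_bound <- q3 + k * iqr
  tol <- 1e-8 * max(1, abs(lo_bound), abs(hi_bound))
  low <- b[1] < lo_bound - tol
  high <- b[4] > hi_bound + tol
  list(specific = (low + high) == 1, low = low, high = high)
}
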