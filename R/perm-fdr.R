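#' Permutation p-values and plug-in permutation FDR
#'
#' Given one observed statistic per edge and a permutations x edges matrix of
#' null statistics, computes per-edge permutation p-values with the exact-test
#' floor p = (1 + k) / (n_perm + 1), and the ratio-of-expected-discoveries FDR:
#' at the threshold t equal to each edge's own statistic,
#' FDR(t) = mean permuted discovery count at t / observed discovery count at t,
#' then monotonized (each edge's q is the minimum estimated FDR over all
#' weaker-or-equal thresholds, as in Benjamini-Hochberg) and capped at 1.
#' Larger statistics are treated as more extreme.
#'
#' @param stat_obs numeric vector (one statistic per edge).
#' @param stat_perm n_perm x n_edges matrix of permuted statistics.
#' @return data frame with columns `p_perm` and `q`.
#' @export
perm_fdr <- function(stat_obs, stat_perm) {
  stat_perm <- as.matrix(stat_perm)
  n_perm <- nrow(stat_perm)
  if (length(stat_obs) != ncol(stat_perm))
    stop("stat_perm must have one column per observed statistic")
  if (n_perm < 20)
    warning("fewer than 20 permutations; FDR resolution is coarse")
  # per-edge p against the edge's own permutation distribution
  p_perm <- (1 + colSums(stat_perm >= rep(stat_obs, each = n_perm))) / (n_perm + 1)
  # pooled discovery-count FDR
  S <- sort(as.vector(stat_perm))
  m <- length(stat_obs)
  obs_sorted <- sort(stat_obs)
  fdr_raw <- vapply(seq_len(m), function(e) {
    t <- stat_obs[e]
    n_perm_ge <- length(S) - findInterval(t, S, left.open = TRUE)
    n_obs_ge <- m - findInterval(t, obs_sorted, left.open = TRUE)
    (n_perm_ge / n_perm) / n_obs_ge
  }, numeric(1))
  # monotonize: q_e = min estimated FDR over all thresholds weaker or equal
  # (every rejection set containing edge e), so q is non-increasing in the stat
  ord <- order(stat_obs)          # weakest first
  q <- numeric(m)
  q[ord] <- cummin(pmin(fdr_raw[ord], 1))
  data.frame(p_perm = p_perm, q = q)
}

# Benjamini-Hochberg alternative on the permutation p-values, offered wherever
# the plug-in estimator is the default.
bh_from_perm <- function(p_perm) stats::p.adjust(p_perm, method = "BH")
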