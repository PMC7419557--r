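#' Presence/absence matrix
#'
#' A feature is "present" in a sample iff its abundance is strictly positive
#' (MetaPhlAn/HUMAnN2 report exact zeros for undetected features).
#'
#' @param table abundance (or count) feature x sample matrix.
#' @return integer 0/1 matrix of the same shape.
#' @export
presence_matrix <- function(table) {
  m <- (unclass(as.matrix(table)) > 0) * 1L
  m
}

chi2_closed_form <- function(a, b, c, d) {
  n <- a + b + c + d
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  ifelse(den > 0, n * (a * d - b * c)^2 / den, NA_real_)
}

#' Pairwise co-occurrence test for two presence vectors
#'
#' Pearson's chi-squared without continuity correction on the 2x2 table of
#' joint presence/absence; odds ratio `ad/bc` with the Haldane-Anscombe +0.5
#' correction applied to all four cells iff any cell is zero. Direction:
#' co-occurrence iff OR > 1, co-exclusion iff OR < 1, undefined at OR = 1.
#' A feature present or absent in every sample makes a margin degenerate and
#' the pair is skipped.
#'
#' @param pres_i,pres_j equal-length binary vectors (n >= 20).
#' @return one-row data frame: a, b, c, d, chi2, odds_ratio, direction, p,
#'   skipped, skip_reason.
#' @export
cooccurrence_test <- function(pres_i, pres_j) {
  stopifnot(length(pres_i) == length(pres_j))
  n <- length(pres_i)
  if (n < 20) stop("need at least 20 samples")
  a <- sum(pres_i == 1 & pres_j == 1)
  b <- sum(pres_i == 1 & pres_j == 0)
  c <- sum(pres_i == 0 & pres_j == 1)
  d <- sum(pres_i == 0 & pres_j == 0)
  rec <- data.frame(a = a, b = b, c = c, d = d, chi2 = NA_real_,
                    odds_ratio = NA_real_, direction = NA_character_,
                    p = NA_real_, skipped = FALSE,
                    skip_reason = NA_character_, stringsAsFactors = FALSE)
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
    rec$skipped <- TRUE
    rec$skip_reason <- "degenerate margin"
    return(rec)
  }
  rec$chi2 <- chi2_closed_form(a, b, c, d)
  rec$p <- stats::pchisq(rec$chi2, df = 1, lower.tail = FALSE)
  if (any(c(a, b, c, d) == 0)) {
    rec$odds_ratio <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    rec$odds_ratio <- (a * d) / (b * c)
  }
  rec$direction <- if (rec$odds_ratio > 1) "co-occurrence"
                   else if (rec$odds_ratio < 1) "co-exclusion"
                   else "undefined"
  rec
}

pairwise_cooccur_stats <- function(B) {
  # vectorized 2x2 cells for all feature pairs of a binary matrix B (p x n)
  n <- ncol(B)
  A <- tcrossprod(B)                     # both present
  r <- rowSums(B)
  bmat <- outer(r, rep(1, length(r))) - A  # i present, j absent
  cmat <- t(bmat)
  dmat <- n - A - bmat - cmat
  list(a = A, b = bmat, c = cmat, d = dmat, n = n)
}

#' Per-cohort co-occurrence network with permutation FDR
#'
#' Chi-squared statistics for all feature pairs; `n_perm` permutations each
#' independently shuffle every feature's presence vector across samples and
#' the chi-squared statistics are recomputed; p-values and plug-in permutation
#' FDR as in [perm_fdr()]. Pairs with a degenerate margin (a feature present
#' in all or no samples) are skipped and excluded from the FDR machinery.
#' A warning is emitted if any expected cell count is below 5 for some pair.
#'
#' @param presence 0/1 feature x sample matrix from [presence_matrix()].
#' @param n_perm number of permutations (default 100).
#' @param seed integer seed.
#' @param cohort label stored in the output.
#' @return data frame: feature_i, feature_j, cohort, a, b, c, d, chi2,
#'   odds_ratio, direction, p_perm, q, n.
#' @export
cooccurrence_network <- function(presence, n_perm = 100, seed = 1,
                                 cohort = NA_character_) {
  B <- unclass(as.matrix(presence))
  storage.mode(B) <- "double"
  p <- nrow(B); n <- ncol(B)
  set.seed(seed)
  ut <- upper.tri(diag(p))
  cells <- pairwise_cooccur_stats(B)
  a <- cells$a[ut]; b <- cells$b[ut]; c <- cells$c[ut]; d <- cells$d[ut]
  ok <- (a + b) > 0 & (c + d) > 0 & (a + c) > 0 & (b + d) > 0
  chi2 <- chi2_closed_form(a, b, c, d)
  expected_min <- pmin((a + b) * (a + c), (a + b) * (b + d),
                       (c + d) * (a + c), (c + d) * (b + d)) / n
  if (any(expected_min[ok] < 5))
    warning("some pairs have expected cell counts < 5; chi-squared ",
            "approximation is rough there (permutation p is still exact)")
  stat_perm <- matrix(NA_real_, n_perm, sum(ok))
  for (bb in seq_len(n_perm)) {
    S <- B
    for (i in seq_len(p)) S[i, ] <- S[i, sample.int(n)]
    pc <- pairwise_cooccur_stats(S)
    stat_perm[bb, ] <- chi2_closed_form(pc$a[ut][ok], pc$b[ut][ok],
                                        pc$c[ut][ok], pc$d[ut][ok])
  }
  fdr <- perm_fdr(chi2[ok], stat_perm)
  or <- ifelse(a * d * b * c == 0 | pmin(a, b, c, d) == 0,
               ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)),
               (a * d) / (b * c))
  out <- edge_pairs(rownames(B))[ok, , drop = FALSE]
  out$cohort <- cohort
  out$a <- a[ok]; out$b <- b[ok]; out$c <- c[ok]; out$d <- d[ok]
  out$chi2 <- chi2[ok]
  out$odds_ratio <- or[ok]
  out$direction <- ifelse(or[ok] > 1, "co-occurrence",
                          ifelse(or[ok] < 1, "co-exclusion", "undefined"))
  out$p_perm <- fdr$p_perm
  out$q <- fdr$q
  out$n <- n
  rownames(out) <- NULL
  out[, c("feature_i", "feature_j", "cohort", "a", "b", "c", "d", "chi2",
          "odds_ratio", "direction", "p_perm", "q", "n")]
}
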