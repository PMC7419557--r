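#' Smoothed fractions from counts
#'
#' Per sample (column), either the Dirichlet-posterior mean under a uniform
#' prior, `(count + 1) / (depth + p)` with `depth = sum(counts)` — strictly
#' positive, so log-ratios are always defined — or a random draw from the
#' Dirichlet(count + 1) posterior (used by [sparcc()] to average out the
#' smoothing).
#'
#' @param counts integer feature x sample matrix (a [count_table()] works).
#' @param method `"mean"` (deterministic posterior mean) or `"draw"` (one
#'   Dirichlet posterior draw; uses the current RNG state).
#' @return feature x sample matrix of strictly positive fractions; columns sum
#'   to 1.
#' @export
fractions_from_counts <- function(counts, method = c("mean", "draw")) {
  method <- match.arg(method)
  counts <- unclass(as.matrix(counts))
  p <- nrow(counts)
  if (method == "mean") {
    f <- counts + 1
  } else {
    f <- matrix(stats::rgamma(length(counts), shape = counts + 1),
                nrow = p, dimnames = dimnames(counts))
  }
  sweep(f, 2, colSums(f), `/`)
}

#' Log-ratio variance matrix
#'
#' `t_ij = var(log(f_i / f_j))` across samples (denominator n - 1), the
#' sufficient statistic of the SparCC estimator. Computed from the covariance
#' of the log fractions: `t_ij = V_ii + V_jj - 2 V_ij`.
#'
#' @param fractions strictly positive feature x sample matrix.
#' @return symmetric p x p matrix with zero diagonal.
#' @export
log_ratio_variances <- function(fractions) {
  if (any(fractions <= 0)) stop("fractions must be strictly positive")
  if (ncol(fractions) < 3) stop("need at least 3 samples")
  V <- stats::cov(t(log(fractions)))
  d <- diag(V)
  t_mat <- outer(d, d, `+`) - 2 * V
  t_mat[t_mat < 0] <- 0   # numerical guard; population t_ij >= 0
  diag(t_mat) <- 0
  t_mat
}

#' SparCC basis variances and correlations from a log-ratio variance matrix
#'
#' Solves the SparCC linear approximation for the basis variances: under
#' sparsity, row sums of t over the included pairs satisfy
#' `t_i ~ d_i w_i^2 + sum_{j in incl(i)} w_j^2`, a linear system in the basis
#' variances `w^2`. Basis correlations follow from
#' `rho_ij = (w_i^2 + w_j^2 - t_ij) / (2 w_i w_j)`, clamped to [-1, 1]. The
#' sparsity assumption is defended by iterative exclusion: the most strongly
#' correlated pair with |rho| above `exclusion_threshold` is removed from the
#' row sums and the system re-solved, up to `max_exclusions` rounds. Negative
#' solved variances are floored at machine epsilon and the feature flagged
#' degenerate; more than p/2 degenerate features is an error.
#'
#' @param t_mat log-ratio variance matrix from [log_ratio_variances()].
#' @param exclusion_threshold |rho| above which a pair may be excluded.
#' @param max_exclusions maximum number of excluded pairs.
#' @return list: `rho` (p x p basis correlation matrix), `omega2` (basis
#'   variances), `t` (input), `excluded` (k x 2 matrix of excluded pairs),
#'   `flagged` (logical, degenerate variance features).
#' @export
basis_correlations <- function(t_mat, exclusion_threshold = 0.1,
                               max_exclusions = 10) {
  p <- nrow(t_mat)
  if (p < 4) stop("need at least 4 features (system under-determined)")
  incl <- matrix(TRUE, p, p); diag(incl) <- FALSE
  excluded <- matrix(integer(0), ncol = 2)
  rho <- NULL; omega2 <- NULL; flagged <- logical(p)
  for (round in 0:max_exclusions) {
    M <- incl * 1
    diag(M) <- rowSums(incl)
    ti <- rowSums(t_mat * incl)
    omega2 <- drop(solve(M, ti))
    flagged <- omega2 <= 0
    omega2[flagged] <- .Machine$double.eps
    omega <- sqrt(omega2)
    rho <- (outer(omega2, omega2, `+`) - t_mat) / (2 * outer(omega, omega))
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    if (sum(flagged) > p / 2)
      stop("more than p/2 features have degenerate basis variances")
    if (round == max_exclusions) break
    cand <- abs(rho)
    cand[!incl] <- 0          # never re-exclude, never the diagonal
    cand[lower.tri(cand, diag = TRUE)] <- 0
    mx <- max(cand)
    if (mx <= exclusion_threshold) break
    ij <- which(cand == mx, arr.ind = TRUE)[1, ]
    incl[ij[1], ij[2]] <- incl[ij[2], ij[1]] <- FALSE
    excluded <- rbind(excluded, ij)
  }
  dimnames(rho) <- dimnames(t_mat)
  list(rho = rho, omega2 = omega2, t = t_mat, excluded = excluded,
       flagged = flagged)
}

#' SparCC correlation matrix from counts
#'
#' With `n_inner = 1`, the point estimate at the Dirichlet-posterior-mean
#' fractions. With `n_inner > 1`, the average of [basis_correlations()] over
#' `n_inner` independent Dirichlet-resampled fraction matrices (fractions per
#' sample drawn from Dirichlet(counts + 1)), which integrates out the
#' zero-replacement smoothing. Deterministic given `seed`.
#'
#' @param counts integer feature x sample matrix.
#' @param n_inner number of Dirichlet resampling iterations (default 20).
#' @param seed integer seed.
#' @inheritParams basis_correlations
#' @return p x p SparCC correlation matrix.
#' @export
sparcc <- function(counts, n_inner = 20, seed = 1,
                   exclusion_threshold = 0.1, max_exclusions = 10) {
  if (!is.null(seed)) set.seed(seed)
  counts <- unclass(as.matrix(counts))
  if (n_inner == 1) {
    f <- fractions_from_counts(counts, "mean")
    return(basis_correlations(log_ratio_variances(f),
                              exclusion_threshold, max_exclusions)$rho)
  }
  acc <- 0
  for (b in seq_len(n_inner)) {
    f <- fractions_from_counts(counts, "draw")
    acc <- acc + basis_correlations(log_ratio_variances(f),
                                    exclusion_threshold, max_exclusions)$rho
  }
  acc / n_inner
}

edge_pairs <- function(features) {
  idx <- which(upper.tri(diag(length(features))), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2],
             feature_i = features[idx[, 1]], feature_j = features[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Per-cohort SparCC edges with permutation p-values and permutation FDR
#'
#' Each of `n_perm` permutations independently shuffles every feature's counts
#' across samples (destroying all between-feature association while keeping
#' marginals) and recomputes the SparCC matrix. Per-edge p-values use the
#' exact-permutation floor; FDR is the plug-in ratio of expected permuted
#' discoveries to observed discoveries at each |rho| threshold, monotonized
#' (see [perm_fdr()]).
#'
#' @inheritParams sparcc
#' @param n_perm number of permutations (default 100; < 20 warns).
#' @param cohort cohort label stored in the output.
#' @return data frame, one row per feature pair: `feature_i`, `feature_j`,
#'   `cohort`, `rho`, `p_perm`, `q`, `n`.
#' @export
permutation_edge_test <- function(counts, n_perm = 100, seed = 1,
                                  n_inner = 20, cohort = NA_character_) {
  counts <- unclass(as.matrix(counts))
  p <- nrow(counts); n <- ncol(counts)
  set.seed(seed)
  rho_obs <- sparcc(counts, n_inner = n_inner, seed = NULL)
  ut <- upper.tri(rho_obs)
  stat_perm <- matrix(NA_real_, n_perm, sum(ut))
  for (b in seq_len(n_perm)) {
    shuf <- counts
    for (i in seq_len(p)) shuf[i, ] <- shuf[i, sample.int(n)]
    stat_perm[b, ] <- abs(sparcc(shuf, n_inner = n_inner, seed = NULL)[ut])
  }
  fdr <- perm_fdr(abs(rho_obs[ut]), stat_perm)
  out <- edge_pairs(rownames(counts))
  out$cohort <- cohort
  out$rho <- rho_obs[ut]
  out$p_perm <- fdr$p_perm
  out$q <- fdr$q
  out$n <- n
  out[, c("feature_i", "feature_j", "cohort", "rho", "p_perm", "q", "n")]
}
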