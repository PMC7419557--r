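#' Centered log-ratio transform
#'
#' Per sample: `log(f_i) - mean_k log(f_k)`. Counts are first smoothed to
#' strictly positive fractions with [fractions_from_counts()]; an
#' already-positive fraction matrix is used as is. Output rows (samples) sum
#' to zero.
#'
#' @param x feature x sample count or fraction matrix.
#' @return n x p matrix (samples as rows) of CLR coordinates.
#' @export
clr_transform <- function(x) {
  x <- unclass(as.matrix(x))
  f <- if (all(x > 0) && all(abs(colSums(x) - 1) < 1e-6)) x
       else fractions_from_counts(x, "mean")
  if (any(f <= 0)) stop("non-positive fraction")
  lf <- log(f)
  out <- t(lf - rep(colMeans(lf), each = nrow(lf)))
  colnames(out) <- rownames(x)
  out
}

lambda_max_clr <- function(X) {
  Xs <- scale(X)
  G <- abs(crossprod(Xs) / nrow(Xs))
  diag(G) <- 0
  max(G)
}

mb_adjacency_path <- function(X, lambda_path) {
  # per-node lasso on standardized columns over a decreasing lambda path;
  # returns a list of p x p OR-symmetrized adjacency matrices, one per lambda
  n <- nrow(X); p <- ncol(X)
  Xs <- scale(X)
  if (any(!is.finite(Xs))) stop("non-finite values after standardization")
  nl <- length(lambda_path)
  adj <- replicate(nl, matrix(FALSE, p, p), simplify = FALSE)
  for (j in seq_len(p)) {
    fit <- glmnet::glmnet(Xs[, -j, drop = FALSE], Xs[, j],
                          lambda = lambda_path, standardize = FALSE)
    B <- as.matrix(fit$beta) != 0      # (p-1) x n_lambda_fitted
    others <- seq_len(p)[-j]
    for (l in seq_len(min(nl, ncol(B)))) {
      nb <- others[B[, l]]
      adj[[l]][j, nb] <- adj[[l]][nb, j] <- TRUE
    }
  }
  adj
}

#' Lasso neighborhood-selection graph at a fixed penalty
#'
#' Meinshausen-Buehlmann style: each node's (standardized) CLR column is
#' lasso-regressed on all others at penalty `lambda`; edge (i, j) is present
#' iff either regression selects the other node (OR symmetrization).
#'
#' @param X n x p CLR matrix (samples as rows), e.g. from [clr_transform()].
#' @param lambda non-negative lasso penalty (glmnet scale, standardized data).
#' @return `sparse_graph`: list with `nodes`, `adjacency` (logical p x p),
#'   `lambda`.
#' @export
mb_neighborhood <- function(X, lambda) {
  stopifnot(lambda >= 0)
  if (any(!is.finite(X))) stop("non-finite values in input")
  # glmnet is unreliable when asked for a single lambda; fit a short
  # descending path ending at the target and read off the last column
  lmax <- max(lambda_max_clr(X), lambda * 1.01, 1e-3)
  path <- exp(seq(log(lmax), log(max(lambda, 1e-8)), length.out = 5))
  adj <- mb_adjacency_path(X, path)[[5]]
  nodes <- colnames(X)
  if (!is.null(nodes)) dimnames(adj) <- list(nodes, nodes)
  structure(list(nodes = nodes, adjacency = adj, lambda = lambda,
                 sel_freq = NULL), class = "sparse_graph")
}

#' StARS stability selection of the neighborhood graph
#'
#' Stability Approach to Regularization Selection: over `n_subsamples`
#' subsamples of size `min(floor(10 sqrt(n)), floor(0.8 n))`, edge selection
#' frequencies theta are computed along a 20-point log-spaced lambda path from
#' lambda_max (smallest penalty giving an empty graph, from the maximum
#' absolute inner product of standardized columns) down to
#' `lambda_min_ratio * lambda_max`. Instability
#' `D(lambda) = mean_edges 2 theta (1 - theta)` is monotonized from the sparse
#' end (running maximum as lambda decreases) and the selected `lambda*` is the
#' smallest (densest) lambda whose monotonized instability is at most `beta`.
#' The final graph is [mb_neighborhood()] at `lambda*` on the full data.
#'
#' @inheritParams mb_neighborhood
#' @param n_lambda path length (default 20).
#' @param lambda_min_ratio path lower end relative to lambda_max.
#' @param n_subsamples number of subsamples (default 50).
#' @param subsample_size override of the 10 sqrt(n) rule.
#' @param beta instability budget (default 0.05).
#' @param seed integer seed.
#' @return `sparse_graph` with additional fields `lambda_path`, `instability`
#'   (raw), `instability_mono`, `sel_freq` (selection frequencies at
#'   `lambda*`), `no_lambda_met` (TRUE if no path point met `beta`; the
#'   sparsest graph is then returned with a warning).
#' @export
stars_select <- function(X, n_lambda = 20, lambda_min_ratio = 0.01,
                         n_subsamples = 50, subsample_size = NULL,
                         beta = 0.05, seed = 1) {
  n <- nrow(X); p <- ncol(X)
  if (n < 20) stop("need at least 20 samples for stability selection")
  set.seed(seed)
  b <- if (is.null(subsample_size)) min(floor(10 * sqrt(n)), floor(0.8 * n))
       else subsample_size
  lmax <- lambda_max_clr(X)
  path <- exp(seq(log(lmax), log(lambda_min_ratio * lmax),
                  length.out = n_lambda))
  ut <- upper.tri(diag(p))
  freq <- matrix(0, n_lambda, sum(ut))
  for (s in seq_len(n_subsamples)) {
    idx <- sample.int(n, b)
    adj <- mb_adjacency_path(X[idx, , drop = FALSE], path)
    for (l in seq_len(n_lambda)) freq[l, ] <- freq[l, ] + adj[[l]][ut]
  }
  theta <- freq / n_subsamples
  D <- rowMeans(2 * theta * (1 - theta))
  D_mono <- cummax(D)   # path is sparse -> dense; instability monotonized
  ok <- which(D_mono <= beta)
  no_lambda_met <- length(ok) == 0
  if (no_lambda_met) {
    warning("no lambda met the instability budget; returning sparsest graph")
    pick <- 1L
  } else {
    pick <- max(ok)     # densest lambda still within budget
  }
  g <- mb_neighborhood(X, path[pick])
  g$lambda <- path[pick]
  g$lambda_path <- path
  g$instability <- D
  g$instability_mono <- D_mono
  sf <- matrix(0, p, p)
  sf[ut] <- theta[pick, ]
  g$sel_freq <- sf + t(sf)
  g$no_lambda_met <- no_lambda_met
  g
}

#' Intersect SparCC edges with the conditional-independence graph
#'
#' The final per-cohort co-abundance network: an edge is kept iff its SparCC
#' permutation FDR is below `alpha` and it is present in the sparsified graph.
#' Effect size and sign come from the SparCC correlation.
#'
#' @param edges data frame from [permutation_edge_test()].
#' @param graph `sparse_graph` on the same feature namespace.
#' @param alpha SparCC FDR threshold (default 0.05).
#' @return subset of `edges` with an added `sel_freq` column (if the graph
#'   carries selection frequencies).
#' @export
intersect_edges <- function(edges, graph, alpha = 0.05) {
  nodes <- graph$nodes
  if (is.null(nodes)) stop("graph carries no node names")
  if (!all(c(edges$feature_i, edges$feature_j) %in% nodes))
    stop("feature namespace mismatch between edges and graph")
  ii <- match(edges$feature_i, nodes)
  jj <- match(edges$feature_j, nodes)
  keep <- edges$q < alpha & graph$adjacency[cbind(ii, jj)]
  out <- edges[keep, , drop = FALSE]
  if (!is.null(graph$sel_freq))
    out$sel_freq <- graph$sel_freq[cbind(ii, jj)][keep]
  rownames(out) <- NULL
  out
}
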