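#' Fisher z transform of a correlation with its standard error
#'
#' `z = atanh(rho)`, `se = 1 / sqrt(n - 3)` — the standard normalizing
#' transform used to feed correlations into an inverse-variance meta-analysis.
#' Correlations at or beyond +/-1 are clamped to +/-0.999999 and flagged.
#'
#' @param rho correlation(s).
#' @param n sample size(s), > 3.
#' @return data frame with columns `z`, `se`, `clamped`.
#' @export
fisher_z <- function(rho, n) {
  stopifnot(all(n > 3))
  clamped <- abs(rho) >= 1
  rho <- pmin(pmax(rho, -0.999999), 0.999999)
  data.frame(z = atanh(rho), se = 1 / sqrt(n - 3), clamped = clamped)
}

#' Log odds ratio with standard error from 2x2 cells
#'
#' 0.5 is added to every cell iff any cell is zero (Haldane-Anscombe);
#' `se = sqrt(1/a + 1/b + 1/c + 1/d)` on the corrected cells.
#'
#' @param a,b,c,d 2x2 cell counts.
#' @return data frame with columns `z` (log OR) and `se`.
#' @export
log_odds_ratio <- function(a, b, c, d) {
  zero <- pmin(a, b, c, d) == 0
  a <- a + 0.5 * zero; b <- b + 0.5 * zero
  c <- c + 0.5 * zero; d <- d + 0.5 * zero
  data.frame(z = log(a * d / (b * c)), se = sqrt(1/a + 1/b + 1/c + 1/d))
}

#' Cochran-Q fixed-effect heterogeneity test
#'
#' Inverse-variance weights `w = 1/se^2`, pooled effect
#' `zbar = sum(w z)/sum(w)`, `Q = sum w (z - zbar)^2`, which is chi-squared
#' with `k - 1` degrees of freedom under homogeneity. Cohorts with a
#' non-finite effect or SE are dropped (df reduced); fewer than 2 usable
#' cohorts marks the record untestable.
#'
#' @param z per-cohort effects (Fisher z for correlations, log OR for
#'   co-occurrence).
#' @param se per-cohort standard errors (> 0).
#' @return list: `Q`, `df`, `p`, `pooled`, `k`, `untestable`.
#' @export
cochran_q <- function(z, se) {
  use <- is.finite(z) & is.finite(se) & se > 0
  z <- z[use]; se <- se[use]
  k <- length(z)
  if (k < 2)
    return(list(Q = NA_real_, df = NA_integer_, p = NA_real_,
                pooled = if (k == 1) z else NA_real_, k = k,
                untestable = TRUE))
  w <- 1 / se^2
  pooled <- sum(w * z) / sum(w)
  Q <- sum(w * (z - pooled)^2)
  df <- k - 1L
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE),
       pooled = pooled, k = k, untestable = FALSE)
}

cochran_q_rows <- function(Z, SE) {
  # row-wise Cochran-Q over an edges x cohorts effect matrix
  W <- 1 / SE^2
  W[!is.finite(Z) | !is.finite(SE) | SE <= 0] <- NA
  k <- rowSums(!is.na(W))
  sw <- rowSums(W, na.rm = TRUE)
  pooled <- rowSums(W * Z, na.rm = TRUE) / sw
  Q <- rowSums(W * (Z - pooled)^2, na.rm = TRUE)
  df <- pmax(k - 1L, 0L)
  p <- ifelse(k >= 2, stats::pchisq(Q, df, lower.tail = FALSE), NA_real_)
  data.frame(Q = ifelse(k >= 2, Q, NA_real_), df = ifelse(k >= 2, df, NA),
             p = p, pooled = pooled, k = k)
}

#' Per-cohort SparCC effects on a shared edge set
#'
#' Runs [sparcc()] in every cohort on the same feature set and returns
#' per-edge, per-cohort correlations with Fisher-z effects and SEs.
#'
#' @param counts_list named list of feature x sample count matrices sharing
#'   the same features in the same order.
#' @param n_inner,seed passed to [sparcc()] (one child seed per cohort).
#' @return list: `rho`, `z`, `se` (edges x cohorts matrices), `n` (per-cohort
#'   sample sizes), `pairs` (edge index data frame).
#' @export
cohort_effects <- function(counts_list, n_inner = 20, seed = 1) {
  feats <- rownames(counts_list[[1]])
  for (cc in counts_list)
    if (!identical(rownames(cc), feats))
      stop("cohort count tables must share one feature set in one order")
  set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1, length(counts_list))
  pairs <- edge_pairs(feats)
  ut <- upper.tri(diag(length(feats)))
  rho <- vapply(seq_along(counts_list), function(k)
    sparcc(counts_list[[k]], n_inner = n_inner, seed = child[k])[ut],
    numeric(sum(ut)))
  rho <- matrix(rho, ncol = length(counts_list),
                dimnames = list(NULL, names(counts_list)))
  n <- vapply(counts_list, ncol, integer(1))
  z <- atanh(pmin(pmax(rho, -0.999999), 0.999999))
  se <- matrix(rep(1 / sqrt(n - 3), each = nrow(rho)), nrow = nrow(rho),
               dimnames = dimnames(rho))
  list(rho = rho, z = z, se = se, n = n, pairs = pairs)
}

#' Between-cohort edge heterogeneity with cohort-label permutation FDR
#'
#' Observed per-cohort SparCC effects on every feature pair are tested for
#' heterogeneity with Cochran-Q. Each of `n_perm` permutations pools all
#' samples and randomly reassigns them to cohorts (original cohort sizes
#' preserved — the within-sample correlation structure is kept intact, only
#' cohort labels are broken), re-estimates the per-cohort effects and Q
#' p-values, and the plug-in permutation FDR is computed on the Q p-value
#' scale. Classification: heterogeneous iff `q_perm < alpha`; stable iff
#' `p > alpha` (and not heterogeneous); indeterminate otherwise.
#'
#' @inheritParams cohort_effects
#' @param n_perm number of cohort-label permutations (default 100).
#' @param alpha FDR / p threshold for the classification (default 0.05).
#' @param edge_subset optional logical vector over edges restricting the edge
#'   analysis set (e.g. the cross-cohort union of detected co-abundances);
#'   effects are still estimated on all pairs, but FDR and classification are
#'   computed within the subset.
#' @return object of class `heterogeneity_result`: list with `records` (data
#'   frame: feature pair, Q, df, p, q_perm, class), `effects` (observed
#'   [cohort_effects()] output), `perm` (list: `rho` — edges x cohorts x
#'   n_perm array, `p` — n_perm x edges matrix of permuted Q p-values),
#'   `alpha`, `edge_subset`.
#' @export
heterogeneity_fdr <- function(counts_list, n_perm = 100, seed = 1,
                              n_inner = 20, alpha = 0.05,
                              edge_subset = NULL) {
  if (n_perm < 20) warning("fewer than 20 permutations; FDR resolution is coarse")
  set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1, n_perm + 1)
  obs <- cohort_effects(counts_list, n_inner = n_inner, seed = child[1])
  qq <- cochran_q_rows(obs$z, obs$se)
  n_edges <- nrow(obs$pairs)
  if (is.null(edge_subset)) edge_subset <- rep(TRUE, n_edges)
  pooled <- do.call(cbind, counts_list)
  sizes <- vapply(counts_list, ncol, integer(1))
  grp <- rep(seq_along(sizes), sizes)
  rho_perm <- array(NA_real_, c(n_edges, length(sizes), n_perm))
  p_perm <- matrix(NA_real_, n_perm, n_edges)
  for (b in seq_len(n_perm)) {
    set.seed(child[b + 1])
    shuffled <- sample.int(ncol(pooled))
    split_cols <- split(shuffled, grp)
    cl <- lapply(split_cols, function(ix) pooled[, ix, drop = FALSE])
    names(cl) <- names(counts_list)
    eb <- cohort_effects(cl, n_inner = n_inner, seed = child[b + 1])
    rho_perm[, , b] <- eb$rho
    p_perm[b, ] <- cochran_q_rows(eb$z, eb$se)$p
  }
  fdr <- perm_fdr(-qq$p[edge_subset], -p_perm[, edge_subset, drop = FALSE])
  q_perm <- rep(NA_real_, n_edges)
  q_perm[edge_subset] <- fdr$q
  class_ <- rep(NA_character_, n_edges)
  class_[edge_subset] <- ifelse(q_perm[edge_subset] < alpha, "heterogeneous",
                                ifelse(qq$p[edge_subset] > alpha, "stable",
                                       "indeterminate"))
  records <- cbind(obs$pairs[c("feature_i", "feature_j")], qq,
                   q_perm = q_perm, class = class_)
  structure(list(records = records, effects = obs,
                 perm = list(rho = rho_perm, p = p_perm),
                 alpha = alpha, edge_subset = edge_subset,
                 cohorts = names(counts_list), sizes = sizes),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  tab <- table(x$records$class, useNA = "ifany")
  cat(sprintf("<heterogeneity_result> %d edges x %d cohorts; ",
              nrow(x$records), length(x$cohorts)))
  cat(paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

#' IQR outlier rule for cohort specificity of one edge
#'
#' The four cohort effect sizes are ranked b1 <= b2 <= b3 <= b4; quartiles Q1,
#' Q2, Q3 are computed by linear interpolation (type-7 by default); the edge
#' is cohort-specific iff exactly one of `b1 < Q1 - k IQR` and
#' `b4 > Q3 + k IQR` holds (strict inequalities, k = 2), and it is assigned to
#' the cohort carrying the outlying effect. With ties IQR may be 0, in which
#' case the strict test requires b1 < Q1 or b4 > Q3.
#'
#' @param effects exactly 4 finite effect sizes (SparCC rho for co-abundance,
#'   OR for co-occurrence).
#' @param cohorts cohort labels aligned with `effects` (defaults to names or
#'   positions).
#' @param k IQR multiplier (default 2).
#' @param quartile_type quantile algorithm (default 7; 6 also supported).
#' @return one-row data frame: Q1, Q2, Q3, IQR, lower, upper, low_out,
#'   high_out, specific, outlier_cohort.
#' @export
iqr_specificity <- function(effects, cohorts = NULL, k = 2, quartile_type = 7) {
  if (length(effects) != 4 || any(!is.finite(effects)))
    stop("the IQR rule needs exactly 4 finite effects")
  if (is.null(cohorts))
    cohorts <- if (!is.null(names(effects))) names(effects)
               else paste0("cohort", 1:4)
  qs <- stats::quantile(effects, c(0.25, 0.5, 0.75), type = quartile_type,
                        names = FALSE)
  iqr <- qs[3] - qs[1]
  lower <- qs[1] - k * iqr
  upper <- qs[3] + k * iqr
  o <- order(effects)
  # strict inequalities; a guard of ~1e-8 resolves exact boundary ties
  # (which arise on gridded effects) as not outlying despite float noise
  tol <- 1e-8 * max(1, abs(lower), abs(upper))
  low_out <- effects[o[1]] < lower - tol
  high_out <- effects[o[4]] > upper + tol
  specific <- xor(low_out, high_out)
  outlier_cohort <- if (!specific) NA_character_
                    else if (low_out) cohorts[o[1]] else cohorts[o[4]]
  data.frame(Q1 = qs[1], Q2 = qs[2], Q3 = qs[3], IQR = iqr,
             lower = lower, upper = upper, low_out = low_out,
             high_out = high_out, specific = specific,
             outlier_cohort = outlier_cohort, stringsAsFactors = FALSE)
}

apply_iqr_rows <- function(E, cohorts, k = 2, quartile_type = 7) {
  # row-wise IQR rule over an edges x 4 effect matrix
  out <- do.call(rbind, lapply(seq_len(nrow(E)), function(r) {
    e <- E[r, ]
    if (any(!is.finite(e)))
      return(data.frame(Q1 = NA_real_, Q2 = NA_real_, Q3 = NA_real_,
                        IQR = NA_real_, lower = NA_real_, upper = NA_real_,
                        low_out = NA, high_out = NA, specific = FALSE,
                        outlier_cohort = NA_character_))
    iqr_specificity(e, cohorts, k = k, quartile_type = quartile_type)
  }))
  rownames(out) <- NULL
  out
}

#' Cohort-specific edge calls for a heterogeneity result
#'
#' Applies the IQR outlier rule to the per-cohort SparCC correlations of every
#' edge classified heterogeneous.
#'
#' @param het a `heterogeneity_result` from [heterogeneity_fdr()].
#' @inheritParams iqr_specificity
#' @return data frame of heterogeneous edges with the [iqr_specificity()]
#'   columns appended; `specific` rows are the cohort-specific calls.
#' @export
specificity_calls <- function(het, k = 2, quartile_type = 7) {
  idx <- which(het$records$class %in% "heterogeneous")
  if (ncol(het$effects$rho) != 4)
    stop("the IQR specificity rule is defined for exactly 4 cohorts")
  res <- apply_iqr_rows(het$effects$rho[idx, , drop = FALSE], het$cohorts,
                        k = k, quartile_type = quartile_type)
  cbind(het$records[idx, c("feature_i", "feature_j", "Q", "df", "p", "q_perm")],
        rho = het$effects$rho[idx, , drop = FALSE], res)
}

#' Study-level permutation FDR of the cohort-specific edge set
#'
#' Reuses the cohort-label permutations of [heterogeneity_fdr()]: within each
#' permutation, edges are called heterogeneous, the IQR rule is applied to the
#' permuted per-cohort effects, and the number of resulting (false) specific
#' calls is recorded. The study-level FDR estimate is the mean permuted
#' specific count divided by the observed specific count.
#'
#' Two gates for the within-permutation heterogeneity call are offered.
#' `"nominal"` (default) admits permuted edges at Q-test p <= alpha — the
#' same nominal test whose false-discovery behavior the permutation machinery
#' estimates; it keeps the permutation null populated (and the key-node
#' cutoff meaningful) even when the observed signal is strong. `"matched"`
#' admits permuted edges at the p threshold realized by the observed FDR cut
#' (the largest observed Q p among edges with `q_perm < alpha`); it mirrors
#' the observed selection exactly but degenerates to empty permutation sets
#' — and a key-node cutoff of 1 — when observed heterogeneity is
#' overwhelmingly strong.
#'
#' @param het a `heterogeneity_result`.
#' @param calls output of [specificity_calls()] (recomputed if omitted).
#' @param perm_gate `"nominal"` or `"matched"` (see Details).
#' @inheritParams iqr_specificity
#' @return list: `fdr` (study-level fraction, NA if there are no observed
#'   calls), `n_observed`, `perm_counts` (per-permutation false-call counts),
#'   `perm_node_max` (per-permutation maximum per-node false specific edge
#'   count, the input of [key_nodes()]), `p_threshold`.
#' @export
specificity_fdr <- function(het, calls = NULL, k = 2, quartile_type = 7,
                            perm_gate = c("nominal", "matched")) {
  perm_gate <- match.arg(perm_gate)
  if (is.null(calls)) calls <- specificity_calls(het, k, quartile_type)
  n_obs <- sum(calls$specific)
  het_idx <- which(het$records$class %in% "heterogeneous")
  p_thr <- if (perm_gate == "nominal") het$alpha
           else if (length(het_idx)) max(het$records$p[het_idx])
           else NA_real_
  n_perm <- dim(het$perm$rho)[3]
  feats <- unique(c(het$effects$pairs$feature_i, het$effects$pairs$feature_j))
  sub <- het$edge_subset
  perm_counts <- integer(n_perm)
  perm_node_max <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    if (!is.finite(p_thr)) { perm_node_max[b] <- 0L; next }
    hit <- which(sub & het$perm$p[b, ] <= p_thr)
    if (!length(hit)) { perm_node_max[b] <- 0L; next }
    res <- apply_iqr_rows(het$perm$rho[, , b][hit, , drop = FALSE], het$cohorts,
                          k = k, quartile_type = quartile_type)
    sp <- which(res$specific)
    perm_counts[b] <- length(sp)
    if (length(sp)) {
      ends <- c(het$effects$pairs$feature_i[hit[sp]],
                het$effects$pairs$feature_j[hit[sp]])
      perm_node_max[b] <- max(table(factor(ends, levels = feats)))
    }
  }
  fdr <- if (n_obs == 0) NA_real_ else mean(perm_counts) / n_obs
  list(fdr = fdr, n_observed = n_obs, perm_counts = perm_counts,
       perm_node_max = perm_node_max, p_threshold = p_thr)
}

#' Cohort enrichment of the specific edge set (Fisher's exact test)
#'
#' Compares the number of specific edges assigned to one cohort against a
#' uniform expectation (total / number of cohorts) with a two-sided Fisher's
#' exact test on the 2x2 table
#' `[assigned to cohort, assigned elsewhere] x [observed, uniform pseudo]`.
#'
#' @param calls [specificity_calls()] output.
#' @param cohort cohort label to test.
#' @param n_cohorts number of cohorts (default 4).
#' @return list: `odds_ratio`, `p`, `n_cohort`, `n_total`.
#' @export
enrichment_test <- function(calls, cohort, n_cohorts = 4) {
  sp <- calls[calls$specific %in% TRUE, , drop = FALSE]
  total <- nrow(sp)
  if (total == 0) stop("no specific calls to test")
  k <- sum(sp$outlier_cohort == cohort)
  exp_k <- round(total / n_cohorts)
  tab <- matrix(c(k, total - k, exp_k, total - exp_k), nrow = 2)
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value,
       n_cohort = k, n_total = total)
}

#' Key (hub) species / pathway detection
#'
#' A node's observed count of incident cohort-specific edges is compared
#' against a permutation-calibrated cutoff: from each permutation the maximum
#' per-node count of false specific edges is taken, the cutoff is the smallest
#' integer strictly greater than the 97.5th percentile (upper end of the 95%
#' interval, linear interpolation) of these maxima, and a node is key iff its
#' observed count reaches the cutoff.
#'
#' @param calls [specificity_calls()] output.
#' @param perm_node_max per-permutation maxima from [specificity_fdr()].
#' @param features full feature namespace (nodes with zero specific edges are
#'   reported too).
#' @param conf upper percentile (default 0.975).
#' @return list: `nodes` (data frame: feature, n_specific, is_key), `cutoff`,
#'   `perm_quantile`.
#' @export
key_nodes <- function(calls, perm_node_max, features, conf = 0.975) {
  if (length(perm_node_max) < 20)
    warning("fewer than 20 permutations behind the key-node cutoff")
  sp <- calls[calls$specific %in% TRUE, , drop = FALSE]
  counts <- table(factor(c(sp$feature_i, sp$feature_j), levels = features))
  qv <- stats::quantile(perm_node_max, conf, type = 7, names = FALSE)
  cutoff <- max(floor(qv) + 1L, 1L)
  nodes <- data.frame(feature = features, n_specific = as.integer(counts),
                      is_key = as.integer(counts) >= cutoff,
                      stringsAsFactors = FALSE)
  list(nodes = nodes, cutoff = cutoff, perm_quantile = qv)
}

#' Replication of edge estimates between a discovery and a replication cohort
#'
#' Per shared edge, a two-group Cochran-Q test (df = 1) on the Fisher-z
#' effects: `Q = (z1 - z2)^2 / (se1^2 + se2^2)`. An edge is replicable iff the
#' heterogeneity is not significant (p > 0.05). The directional criterion —
#' significant in the replication cohort (p < 0.05) with the same sign — is
#' reported alongside when the replication table carries `p_perm`.
#'
#' @param edges_discovery,edges_replication data frames with columns
#'   `feature_i`, `feature_j`, `rho`, `n` (optionally `p_perm`).
#' @param alpha significance threshold (default 0.05).
#' @return list: `edges` (merged data frame with Q, p, replicable,
#'   directional), `rate_replicable`, `rate_directional`, `n_assessed`,
#'   `n_excluded` (discovery edges not computable in the replication cohort).
#' @export
replication_compare <- function(edges_discovery, edges_replication,
                                alpha = 0.05) {
  m <- merge(edges_discovery, edges_replication,
             by = c("feature_i", "feature_j"), suffixes = c("_disc", "_repl"))
  ok <- is.finite(m$rho_disc) & is.finite(m$rho_repl)
  n_excluded <- nrow(edges_discovery) - sum(ok)
  m <- m[ok, , drop = FALSE]
  f1 <- fisher_z(m$rho_disc, m$n_disc)
  f2 <- fisher_z(m$rho_repl, m$n_repl)
  m$Q <- (f1$z - f2$z)^2 / (f1$se^2 + f2$se^2)
  m$p_het <- stats::pchisq(m$Q, 1, lower.tail = FALSE)
  m$replicable <- m$p_het > alpha
  m$directional <- if ("p_perm_repl" %in% names(m))
    m$p_perm_repl < alpha & sign(m$rho_repl) == sign(m$rho_disc)
  else NA
  list(edges = m,
       rate_replicable = mean(m$replicable),
       rate_directional = if (all(is.na(m$directional))) NA_real_
                          else mean(m$directional),
       n_assessed = nrow(m), n_excluded = n_excluded)
}

#' Differential edges between sub-phenotype strata of one cohort
#'
#' Splits a cohort by a grouping label (disease subtype, medication use, ...),
#' infers SparCC networks per level, tests each edge with a Cochran-Q across
#' the levels, and flags differential edges at Benjamini-Hochberg FDR <
#' `alpha`.
#'
#' @param counts feature x sample count matrix of one cohort.
#' @param groups per-sample grouping labels (>= 2 levels, each with at least
#'   `min_n` samples).
#' @param min_n minimum samples per level (default 30).
#' @inheritParams sparcc
#' @param alpha BH FDR threshold (default 0.05).
#' @return data frame: feature pair, per-level rho, Q, df, p, q_bh,
#'   differential.
#' @export
stratified_compare <- function(counts, groups, min_n = 30, n_inner = 20,
                               seed = 1, alpha = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("grouping label needs at least 2 levels")
  sizes <- table(groups)
  small <- names(sizes)[sizes < min_n]
  if (length(small))
    stop("levels below the minimum sample size: ",
         paste(small, collapse = ", "))
  counts <- unclass(as.matrix(counts))
  cl <- lapply(levels(groups),
               function(l) counts[, groups == l, drop = FALSE])
  names(cl) <- levels(groups)
  eff <- cohort_effects(cl, n_inner = n_inner, seed = seed)
  qq <- cochran_q_rows(eff$z, eff$se)
  out <- cbind(eff$pairs[c("feature_i", "feature_j")], rho = eff$rho, qq)
  out$q_bh <- stats::p.adjust(out$p, method = "BH")
  out$differential <- out$q_bh < alpha
  out
}
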