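#' Partial correlation
#'
#' Single covariate: closed form
#' `r_AB.C = (r_AB - r_AC r_BC) / sqrt((1 - r_AC^2)(1 - r_BC^2))`.
#'
#' @param r_AB,r_AC,r_BC pairwise Pearson correlations.
#' @return partial correlation of A and B given C.
#' @export
partial_correlation <- function(r_AB, r_AC, r_BC) {
  if (any(abs(c(r_AC, r_BC)) >= 1))
    stop("degenerate conditioning: a covariate correlation is +/-1")
  (r_AB - r_AC * r_BC) / sqrt((1 - r_AC^2) * (1 - r_BC^2))
}

#' Partial correlation given several covariates, from a correlation matrix
#'
#' Inverts the full correlation matrix of (A, B, C1, ..., Ck) and normalizes
#' the off-diagonal precision entry: `-P_AB / sqrt(P_AA P_BB)`. For a single
#' covariate this equals the closed form of [partial_correlation()].
#'
#' @param R correlation matrix with A and B in rows/columns `i` and `j`.
#' @param i,j indices of the two variables of interest (default 1 and 2).
#' @return partial correlation of variables i and j given all others.
#' @export
partial_correlation_multi <- function(R, i = 1, j = 2) {
  P <- solve(R)
  -P[i, j] / sqrt(P[i, i] * P[j, j])
}

#' Partial correlation of two data vectors given covariate columns
#'
#' @param x,y numeric vectors.
#' @param Z covariate matrix / data frame (columns = covariates), or NULL for
#'   the marginal correlation.
#' @return scalar partial correlation.
#' @export
partial_cor_data <- function(x, y, Z = NULL) {
  if (is.null(Z) || NCOL(Z) == 0) return(stats::cor(x, y))
  R <- stats::cor(cbind(x, y, as.matrix(Z)))
  partial_correlation_multi(R, 1, 2)
}

#' Re-test cohort-specific calls after covariate adjustment
#'
#' For each cohort-specific edge, the per-cohort effect is recomputed as the
#' partial correlation of the CLR-transformed abundances of the two features
#' given the covariates (age and sex by default), the IQR rule is re-applied
#' to the adjusted effects, and the call survives iff it is still specific to
#' the same cohort. Samples with missing covariate values are dropped (counts
#' reported per cohort in the `n_dropped` attribute).
#'
#' @param calls [specificity_calls()] output.
#' @param counts_list named per-cohort feature x sample count matrices (same
#'   namespace as `calls`).
#' @param metadata_list named per-cohort `sample_metadata` data frames aligned
#'   with the count columns.
#' @param covariates metadata column names to adjust for (default age, sex).
#' @param raw_abundance if TRUE, use relative abundances instead of CLR
#'   coordinates for the partial correlations.
#' @inheritParams iqr_specificity
#' @return `calls` with adjusted per-cohort effects (`adj.<cohort>` columns),
#'   `specific_adjusted`, `outlier_cohort_adjusted` and `survives` columns.
#' @export
adjust_specificity <- function(calls, counts_list, metadata_list,
                               covariates = c("age", "sex"),
                               raw_abundance = FALSE,
                               k = 2, quartile_type = 7) {
  cohorts <- names(counts_list)
  sp_idx <- which(calls$specific %in% TRUE)
  if (!length(sp_idx)) {
    calls$specific_adjusted <- logical(0)[seq_len(nrow(calls))]
    calls$survives <- logical(0)[seq_len(nrow(calls))]
    return(calls)
  }
  n_dropped <- setNames(integer(length(cohorts)), cohorts)
  Xc <- list(); Zc <- list()
  for (ch in cohorts) {
    md <- metadata_list[[ch]]
    Z <- as.matrix(md[, covariates, drop = FALSE])
    keep <- stats::complete.cases(Z)
    n_dropped[ch] <- sum(!keep)
    Xc[[ch]] <- if (raw_abundance) {
      t(sweep(counts_list[[ch]][, keep, drop = FALSE], 2,
              pmax(colSums(counts_list[[ch]][, keep, drop = FALSE]), 1), `/`))
    } else {
      clr_transform(counts_list[[ch]][, keep, drop = FALSE])
    }
    Zc[[ch]] <- Z[keep, , drop = FALSE]
  }
  adj <- matrix(NA_real_, nrow(calls), length(cohorts),
                dimnames = list(NULL, cohorts))
  for (r in sp_idx) {
    fi <- calls$feature_i[r]; fj <- calls$feature_j[r]
    for (ch in cohorts)
      adj[r, ch] <- partial_cor_data(Xc[[ch]][, fi], Xc[[ch]][, fj], Zc[[ch]])
  }
  res <- apply_iqr_rows(adj[sp_idx, , drop = FALSE], cohorts,
                        k = k, quartile_type = quartile_type)
  calls$specific_adjusted <- NA
  calls$outlier_cohort_adjusted <- NA_character_
  calls$specific_adjusted[sp_idx] <- res$specific
  calls$outlier_cohort_adjusted[sp_idx] <- res$outlier_cohort
  calls$survives <- calls$specific %in% TRUE &
    calls$specific_adjusted %in% TRUE &
    !is.na(calls$outlier_cohort_adjusted) &
    calls$outlier_cohort_adjusted == calls$outlier_cohort
  colnames(adj) <- paste0("adj.", cohorts)
  out <- cbind(calls, adj)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Covariate-adjusted Spearman association between species and pathways
#'
#' Both abundance vectors are residualized on the covariates by least squares,
#' Spearman correlation is computed on the residuals, and a permutation FDR is
#' attached by shuffling one residual vector (`n_perm` times, all pairs
#' pooled).
#'
#' @param species feature x sample abundance matrix (or a single vector).
#' @param pathways feature x sample abundance matrix (or a single vector).
#' @param covariates data frame of per-sample covariates (the columns age,
#'   sex, read_depth are taken if a `sample_metadata` is passed); `NULL`
#'   skips residualization and tests the raw Spearman correlation.
#' @param n_perm permutations for the FDR (default 100).
#' @param seed integer seed.
#' @return data frame: species, pathway, rho (Spearman on residuals), p
#'   (asymptotic), p_perm, q, untestable.
#' @export
species_pathway_association <- function(species, pathways, covariates,
                                        n_perm = 100, seed = 1) {
  as_mat <- function(x, what) {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1,
                                     dimnames = list(what, names(x)))
    unclass(as.matrix(x))
  }
  S <- as_mat(species, "species1")
  P <- as_mat(pathways, "pathway1")
  if (inherits(covariates, "sample_metadata"))
    covariates <- covariates[, c("age", "sex", "read_depth")]
  n <- ncol(S)
  if (n < 30) stop("need at least 30 samples")
  stopifnot(ncol(P) == n)
  if (is.null(covariates)) {
    RS <- S
    RP <- P
  } else {
    Z <- as.matrix(covariates)
    stopifnot(nrow(Z) == n)
    D <- cbind(1, Z)
    H <- diag(n) - D %*% solve(crossprod(D), t(D))
    RS <- S %*% t(H)   # residualized rows
    RP <- P %*% t(H)
  }
  const <- function(v) stats::sd(v) < .Machine$double.eps^0.5
  grid <- expand.grid(si = seq_len(nrow(S)), pi_ = seq_len(nrow(P)))
  rho <- p <- numeric(nrow(grid)); untest <- logical(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    xs <- RS[grid$si[g], ]; xp <- RP[grid$pi_[g], ]
    if (const(xs) || const(xp)) { untest[g] <- TRUE; rho[g] <- NA; p[g] <- NA; next }
    ct <- suppressWarnings(stats::cor.test(xs, xp, method = "spearman"))
    rho[g] <- unname(ct$estimate); p[g] <- ct$p.value
  }
  set.seed(seed)
  ok <- !untest
  stat_perm <- matrix(NA_real_, n_perm, sum(ok))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    kk <- 0
    for (g in which(ok)) {
      kk <- kk + 1
      stat_perm[b, kk] <- abs(stats::cor(RS[grid$si[g], perm], RP[grid$pi_[g], ],
                                         method = "spearman"))
    }
  }
  fdr <- perm_fdr(abs(rho[ok]), stat_perm)
  out <- data.frame(species = rownames(S)[grid$si],
                    pathway = rownames(P)[grid$pi_],
                    rho = rho, p = p, p_perm = NA_real_, q = NA_real_,
                    untestable = untest, stringsAsFactors = FALSE)
  out$p_perm[ok] <- fdr$p_perm
  out$q[ok] <- fdr$q
  out
}

#' Species contribution shares to community-level pathway abundance
#'
#' HUMAnN2 reports pathway abundance at the community level and stratified by
#' contributing species. The share of a species is its stratified abundance
#' divided by the community abundance per sample (0 where the community
#' abundance is 0); cohort summaries are mean shares and the top contributor
#' is the species with the largest mean share.
#'
#' @param community pathway x sample matrix of community-level abundances.
#' @param stratified matrix with rownames `"pathway|species"` (e.g. the
#'   `stratified` attribute of [read_abundance_table()]).
#' @param tol tolerated excess of the stratified sum over the community total
#'   (fraction, default 0.01); larger excess is an input-consistency error.
#' @return list: `shares` (data frame pathway, species, mean_share,
#'   top_contributor), `per_sample` (named list of species x sample share
#'   matrices per pathway).
#' @export
species_contribution <- function(community, stratified, tol = 0.01) {
  parts <- strsplit(rownames(stratified), "|", fixed = TRUE)
  pw <- vapply(parts, `[`, character(1), 1)
  sp <- vapply(parts, function(x) paste(x[-1], collapse = "|"), character(1))
  out <- list(); per_sample <- list()
  for (pway in unique(pw)) {
    if (!pway %in% rownames(community))
      stop("stratified rows for '", pway, "' lack a community-level row")
    comm <- community[pway, ]
    strat <- stratified[pw == pway, , drop = FALSE]
    tot <- colSums(strat)
    if (any(tot > comm * (1 + tol) + 1e-12))
      stop("stratified abundances exceed the community total for '", pway, "'")
    shares <- sweep(strat, 2, ifelse(comm > 0, comm, Inf), `/`)
    rownames(shares) <- sp[pw == pway]
    per_sample[[pway]] <- shares
    ms <- rowMeans(shares)
    out[[pway]] <- data.frame(pathway = pway, species = names(ms),
                              mean_share = as.numeric(ms),
                              top_contributor = names(ms) == names(which.max(ms)),
                              stringsAsFactors = FALSE)
  }
  list(shares = do.call(rbind, c(out, list(make.row.names = FALSE))),
       per_sample = per_sample)
}

#' Compare a species' contribution share between two cohorts
#'
#' Wilcoxon rank-sum test on the per-sample shares.
#'
#' @param shares_a,shares_b per-sample share vectors for the same
#'   pathway/species in two cohorts.
#' @return list: `delta` (mean share difference, a - b), `p` (two-sided
#'   Wilcoxon).
#' @export
contribution_compare <- function(shares_a, shares_b) {
  wt <- suppressWarnings(stats::wilcox.test(shares_a, shares_b))
  list(delta = mean(shares_a) - mean(shares_b), p = wt$p.value)
}
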