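#' Canned synthetic validation studies
#'
#' Fixed study designs used throughout the package's validation suite; each
#' returns ground truth alongside the simulated data so recovery can be
#' scored. Sizes follow realistic single-site metagenomic cohorts (hundreds
#' of samples, tens of prevalent species, sequencing depth 50,000 classified
#' reads).
#'
#' * `study_sparcc_recovery(seed)` — one cohort, p = 30 features, 12 basis
#'   edges at rho 0.6, n = 400, depth 50,000; benchmarks SparCC estimation
#'   and permutation-FDR detection.
#' * `study_null(seed)` — identical dimensions with an identity basis
#'   network; benchmarks null calibration of the permutation machinery.
#' * `study_heterogeneity(seed, delta_z, n_shift)` — 4 cohorts (n = 300
#'   each, p = 21) drawn from a shared identity truth, with `n_shift` edges
#'   shifted by `delta_z` on the Fisher-z scale in cohort C4 only; benchmarks
#'   Cochran-Q null uniformity and detection power.
#' * `study_specificity(seed)` — 4 cohorts (n = 300 each, p = 22): one hub
#'   feature with 15 cohort-specific edges (target rho 0.6, spread over the
#'   four cohorts; realized values recorded after the positive-definite
#'   projection) plus 10 ordinary cohort-specific edges at rho 0.6 (one
#'   cohort each, 0 elsewhere) among ~200 null feature pairs; benchmarks the
#'   IQR specificity rule, its study-level FDR and key-node detection.
#'
#' @param seed integer seed; every function is deterministic given it.
#' @param delta_z Fisher-z shift of the planted heterogeneous edges.
#' @param n_shift number of shifted edges.
#' @return a list with `truth` plus either `cohort` (single-cohort designs)
#'   or `counts` (named list of per-cohort count matrices).
#' @name validation_studies
NULL

#' @rdname validation_studies
#' @export
study_sparcc_recovery <- function(seed = 1) {
  truth <- make_basis_network(p = 30, n_edges = 12, rho = 0.6, seed = seed)
  cohort <- simulate_cohort(truth, "A", n = 400, depth = 50000,
                            seed = seed + 1)
  list(truth = truth, cohort = cohort)
}

#' @rdname validation_studies
#' @export
study_null <- function(seed = 1) {
  # moderate zero inflation keeps presence/absence margins non-degenerate so
  # the same study calibrates the co-occurrence null; label permutation makes
  # the co-abundance null calibration insensitive to the marginals
  truth <- make_basis_network(p = 30, n_edges = 0, rho = 0, seed = seed,
                              pi = 0.3)
  cohort <- simulate_cohort(truth, "A", n = 400, depth = 50000,
                            seed = seed + 1)
  list(truth = truth, cohort = cohort)
}

#' @rdname validation_studies
#' @export
study_heterogeneity <- function(seed = 1, delta_z = 0.4, n_shift = 20) {
  truth <- make_basis_network(p = 21, n_edges = 0, rho = 0, seed = seed)
  set.seed(seed + 1)
  pairs <- which(upper.tri(diag(truth$p)), arr.ind = TRUE)
  sel <- sample(nrow(pairs), n_shift)
  for (k in sel)
    truth <- plant_specific_edge(truth, pairs[k, ], "C4", tanh(delta_z))
  counts <- lapply(1:4, function(k)
    simulate_cohort(truth, paste0("C", k), n = 300, depth = 50000,
                    seed = seed + 10 + k)$counts)
  names(counts) <- paste0("C", 1:4)
  list(truth = truth, counts = counts)
}

#' @rdname validation_studies
#' @export
study_specificity <- function(seed = 1) {
  truth <- make_basis_network(p = 22, n_edges = 0, rho = 0, seed = seed)
  cohorts <- paste0("C", 1:4)
  # hub: feature 1 tied to all 15 neighbors, specific edges spread 4/4/4/3
  # over cohorts (a denser star in one cohort could not stay positive
  # definite at rho 0.6; realized values after projection are the truth)
  nb <- 2:16
  for (k in seq_along(nb))
    truth <- plant_specific_edge(truth, c(1, nb[k]),
                                 cohorts[(k - 1) %% 4 + 1], 0.6)
  # 10 ordinary specific edges at rho 0.6, one cohort each, node-disjoint
  # from the hub edges within their cohort
  hub_cohort <- function(v) cohorts[(v - 2) %% 4 + 1]
  pair_nodes <- list(c(2, 3), c(4, 5), c(6, 7), c(8, 9), c(10, 11),
                     c(12, 13), c(14, 15), c(17, 18), c(19, 20), c(21, 22))
  # cohorts chosen to avoid each pair's hub-edge cohorts, balanced overall
  pair_cohort <- c("C3", "C1", "C4", "C2", "C3", "C1", "C4", "C2", "C3", "C4")
  for (k in seq_along(pair_nodes)) {
    stopifnot(all(pair_nodes[[k]] > 16) ||
                !pair_cohort[k] %in% sapply(pair_nodes[[k]], hub_cohort))
    truth <- plant_specific_edge(truth, pair_nodes[[k]], pair_cohort[k], 0.6)
  }
  counts <- lapply(seq_along(cohorts), function(k)
    simulate_cohort(truth, cohorts[k], n = 300, depth = 50000,
                    seed = seed + 10 + k)$counts)
  names(counts) <- cohorts
  list(truth = truth, counts = counts,
       hub = truth$features[1],
       ordinary = data.frame(i = sapply(pair_nodes, `[`, 1),
                             j = sapply(pair_nodes, `[`, 2),
                             cohort = pair_cohort))
}
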