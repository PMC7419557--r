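test_that("partial correlation matches the closed form and the inversion route", {
  expect_equal(partial_correlation(0.6, 0.5, 0.5), 0.35 / 0.75)
  expect_equal(partial_correlation(0.6, 0, 0), 0.6)
  expect_error(partial_correlation(0.5, 1, 0.2), "degenerate")
  # matrix-inversion route equals the closed form for one covariate
  set.seed(71)
  for (r in 1:30) {
    R <- stats::cov2cor(crossprod(matrix(rnorm(12), 4, 3)))
    expect_equal(partial_correlation_multi(R, 1, 2),
                 partial_correlation(R[1, 2], R[1, 3], R[2, 3]),
                 tolerance = 1e-12)
  }
  # exchangeable in the two target variables
  R <- stats::cov2cor(crossprod(matrix(rnorm(20), 5, 4)))
  expect_equal(partial_correlation_multi(R, 1, 2),
               partial_correlation_multi(R, 2, 1))
})

test_that("partialling removes a planted common-cause association", {
  set.seed(72)
  n <- 2000
  C <- rnorm(n)
  A <- 0.6 * C + rnorm(n)
  B <- 0.55 * C + rnorm(n)
  marginal <- stats::cor(A, B)
  expect_gt(marginal, 0.15)
  partial <- partial_cor_data(A, B, C)
  expect_lt(abs(partial), 0.05)
  # conditioning on an irrelevant covariate barely moves the estimate
  Z <- rnorm(n)
  expect_lt(abs(partial_cor_data(A, B, Z) - marginal), 2 / sqrt(n))
})

test_that("adjust_specificity drops a purely age-induced specific call", {
  # features 1 and 2 load on age in cohort C4 only: their correlation there
  # is confounding, not a basis edge
  tr <- make_basis_network(p = 8, n_edges = 0, rho = 0, seed = 73, log_sd = 0.8)
  cohorts <- paste0("C", 1:4)
  sim <- function(ch, seed) {
    ba <- if (ch == "C4") c(0.08, 0.08, rep(0, 6)) else rep(0, 8)
    simulate_cohort(tr, ch, n = 400, depth = 30000, seed = seed, beta_age = ba)
  }
  cos <- lapply(seq_along(cohorts), function(k) sim(cohorts[k], 80 + k))
  names(cos) <- cohorts
  counts <- lapply(cos, `[[`, "counts")
  md <- lapply(cos, `[[`, "metadata")
  het <- heterogeneity_fdr(counts, n_perm = 40, seed = 74, n_inner = 10)
  calls <- specificity_calls(het)
  hit <- calls$feature_i == tr$features[1] & calls$feature_j == tr$features[2]
  expect_true(any(hit))
  expect_equal(calls$outlier_cohort[hit], "C4")
  adj <- adjust_specificity(calls, counts, md)
  expect_false(adj$survives[hit])
  # no specific calls in -> structurally empty out
  none <- calls[calls$specific %in% FALSE, , drop = FALSE]
  adj0 <- adjust_specificity(none, counts, md)
  expect_equal(sum(adj0$survives, na.rm = TRUE), 0)
})

test_that("genuine basis edges survive covariate adjustment", {
  tr <- make_basis_network(p = 8, n_edges = 0, rho = 0, seed = 75)
  tr <- plant_specific_edge(tr, c(3, 7), "C2", 0.7)
  cohorts <- paste0("C", 1:4)
  cos <- lapply(seq_along(cohorts), function(k)
    simulate_cohort(tr, cohorts[k], n = 400, depth = 30000, seed = 90 + k))
  names(cos) <- cohorts
  counts <- lapply(cos, `[[`, "counts")
  md <- lapply(cos, `[[`, "metadata")
  het <- heterogeneity_fdr(counts, n_perm = 40, seed = 76, n_inner = 10)
  calls <- specificity_calls(het)
  hit <- calls$feature_i == tr$features[3] & calls$feature_j == tr$features[7]
  expect_true(any(hit) && calls$specific[hit])
  adj <- adjust_specificity(calls, counts, md)
  expect_true(adj$survives[hit])
})

test_that("species-pathway association is rank-invariant and confounder-aware", {
  set.seed(77)
  n <- 200
  md <- data.frame(age = runif(n, 20, 70), sex = rbinom(n, 1, 0.5),
                   read_depth = round(runif(n, 1e4, 5e4)))
  sp <- rexp(n)
  pw <- sp^2          # monotone transform, no covariate effect
  # rank invariance of the Spearman step: exact without residualization
  out_raw <- species_pathway_association(sp, pw, NULL, n_perm = 50, seed = 78)
  expect_equal(out_raw$rho, 1)
  # residualizing on unrelated covariates perturbs ranks only mildly
  out <- species_pathway_association(sp, pw, md, n_perm = 50, seed = 78)
  expect_gt(out$rho, 0.85)
  expect_lt(out$q, 0.05)
  # independent vectors: small rho
  out0 <- species_pathway_association(rexp(n), rexp(n), md, n_perm = 50,
                                      seed = 79)
  expect_lt(abs(out0$rho), 0.15)
  expect_gt(out0$p_perm, 0.05)
  # association wholly mediated by read depth disappears on residuals
  depth_eff <- md$read_depth / 1e4
  sp2 <- depth_eff + rnorm(n, 0, 0.1)
  pw2 <- depth_eff + rnorm(n, 0, 0.1)
  raw <- stats::cor(sp2, pw2, method = "spearman")
  out2 <- species_pathway_association(sp2, pw2, md, n_perm = 50, seed = 80)
  expect_gt(raw, 0.8)
  expect_lt(abs(out2$rho), 0.2)
})

test_that("contribution shares are ratios with the community total, cohort-comparable", {
  comm <- matrix(c(120, 80, 0, 10), 2, 2, byrow = TRUE,
                 dimnames = list(c("PWY-1", "PWY-2"), c("s1", "s2")))
  strat <- matrix(c(30, 20, 90, 60, 0, 10), 3, 2, byrow = TRUE,
                  dimnames = list(c("PWY-1|g__A.s__a", "PWY-1|g__B.s__b",
                                    "PWY-2|g__A.s__a"), c("s1", "s2")))
  sc <- species_contribution(comm, strat)
  expect_equal(sc$per_sample[["PWY-1"]]["g__A.s__a", "s1"], 0.25)
  expect_equal(sc$per_sample[["PWY-1"]]["g__B.s__b", "s1"], 0.75)
  # zero community abundance gives zero share
  expect_equal(sc$per_sample[["PWY-2"]]["g__A.s__a", "s1"], 0)
  top <- sc$shares[sc$shares$pathway == "PWY-1" & sc$shares$top_contributor, ]
  expect_equal(top$species, "g__B.s__b")
  # single contributor accounting for everything: share 1
  comm1 <- matrix(c(50, 40), 1, 2, dimnames = list("PWY-9", c("s1", "s2")))
  strat1 <- matrix(c(50, 40), 1, 2,
                   dimnames = list("PWY-9|g__C.s__c", c("s1", "s2")))
  expect_equal(unname(species_contribution(comm1, strat1)$per_sample[["PWY-9"]][1, ]),
               c(1, 1))
  # inconsistent input: stratified sum exceeds the community total
  bad <- strat; bad[1, 1] <- 200
  expect_error(species_contribution(comm, bad), "exceed")
  # shares are invariant to global rescaling of a sample's abundances
  sc2 <- species_contribution(comm * 3, strat * 3)
  expect_equal(sc2$per_sample, sc$per_sample)
  # planted two-cohort share difference detected in the right direction
  set.seed(81)
  a <- pmin(pmax(rnorm(50, 0.10, 0.03), 0), 1)
  b <- pmin(pmax(rnorm(50, 0.20, 0.03), 0), 1)
  cmpr <- contribution_compare(a, b)
  expect_lt(cmpr$delta, 0)
  expect_lt(cmpr$p, 0.01)
})
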