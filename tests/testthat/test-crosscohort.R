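test_that("fisher z matches hand values, is odd, and clamps |rho| >= 1", {
  f <- fisher_z(0.5, 103)
  expect_equal(f$z, atanh(0.5))
  expect_equal(f$z, 0.5493, tolerance = 1e-4)
  expect_equal(f$se, 0.1)
  expect_equal(fisher_z(0, 10)$z, 0)
  expect_equal(fisher_z(-0.73, 50)$z, -fisher_z(0.73, 50)$z)
  fc <- fisher_z(1, 30)
  expect_true(fc$clamped)
  expect_equal(fc$z, atanh(0.999999))
})

test_that("cochran Q matches hand values and the textbook oracle", {
  r <- cochran_q(c(0.5, 0.5, 0.5, 0.5), rep(0.1, 4))
  expect_equal(r$Q, 0)
  expect_equal(r$p, 1)
  r2 <- cochran_q(c(0, 0, 0, 1), rep(0.1, 4))
  expect_equal(r2$Q, 75)
  expect_equal(r2$df, 3L)
  # scaling all SEs by k scales Q by 1/k^2
  r3 <- cochran_q(c(0, 0, 0, 1), rep(0.2, 4))
  expect_equal(r3$Q, 75 / 4)
  # random instances against the oracle
  set.seed(12)
  for (i in 1:100) {
    z <- rnorm(4); se <- runif(4, 0.05, 0.3)
    o <- fe_meta_oracle(z, se)
    mine <- cochran_q(z, se)
    expect_equal(mine$Q, o$Q, tolerance = 1e-10)
    expect_equal(mine$p, o$p, tolerance = 1e-10)
  }
  # dropped cohorts reduce df; < 2 usable -> untestable
  r4 <- cochran_q(c(0.2, NA, 0.4), c(0.1, 0.1, 0.1))
  expect_equal(r4$df, 1L)
  expect_true(cochran_q(c(0.2, NA), c(0.1, NA))$untestable)
})

test_that("cochran Q agrees with metafor's fixed-effect QE", {
  skip_if_not_installed("metafor")
  set.seed(13)
  for (i in 1:20) {
    z <- rnorm(4, 0, 0.5); se <- runif(4, 0.05, 0.3)
    fit <- suppressWarnings(metafor::rma(yi = z, sei = se, method = "FE"))
    expect_equal(cochran_q(z, se)$Q, fit$QE, tolerance = 1e-8)
  }
})

test_that("IQR rule reproduces the worked examples and their symmetries", {
  r <- iqr_specificity(c(A = 0.10, B = 0.11, C = 0.12, D = 0.60))
  expect_equal(r$Q1, 0.1075)
  expect_equal(r$Q3, 0.24)
  expect_equal(r$IQR, 0.1325)
  expect_equal(r$upper, 0.505)
  expect_true(r$specific)
  expect_equal(r$outlier_cohort, "D")
  # sign flip assigns the low outlier
  r2 <- iqr_specificity(c(A = -0.10, B = -0.11, C = -0.12, D = -0.60))
  expect_true(r2$specific)
  expect_equal(r2$outlier_cohort, "D")
  # degenerate ties: IQR = 0, strict test fails
  r3 <- iqr_specificity(rep(0.3, 4))
  expect_equal(r3$IQR, 0)
  expect_false(r3$specific)
  expect_error(iqr_specificity(c(0.1, 0.2, 0.3)), "exactly 4")
})

test_that("IQR rule agrees exhaustively with a brute-force oracle on a grid", {
  # all sorted 4-combinations (with repetition) of a coarse grid, covering
  # every tie pattern; both routes are permutation-invariant (the acceptance
  # suite repeats this at the fine 0.05 step)
  grid <- seq(-1, 1, by = 0.1)
  combs <- utils::combn(length(grid) + 3, 4)
  # map combinations-with-repetition onto the grid
  idx <- combs - 0:3
  n_checked <- 0L; n_specific <- 0L
  for (cc in seq_len(ncol(idx))) {
    e <- grid[idx[, cc]]
    mine <- iqr_specificity(e, cohorts = paste0("c", 1:4))
    oracle <- brute_iqr_rule(e)
    if (mine$specific != oracle$specific)
      fail(sprintf("disagreement at (%s)", paste(e, collapse = ", ")))
    n_checked <- n_checked + 1L
    n_specific <- n_specific + mine$specific
  }
  expect_equal(n_checked, ncol(idx))
  expect_gt(n_specific, 0)
  # symmetric double outliers are never specific
  for (s in c(0.3, 0.6, 0.9)) {
    r <- iqr_specificity(c(-s, -0.01, 0.01, s))
    expect_false(r$specific)
  }
})

test_that("Q p-values are uniform under the cross-cohort null", {
  st <- study_heterogeneity(seed = 41, n_shift = 0)
  eff <- cohort_effects(st$counts, n_inner = 10, seed = 42)
  qq <- conetdiff:::cochran_q_rows(eff$z, eff$se)
  expect_gt(stats::ks.test(qq$p, "punif")$p.value, 0.01)
})

test_that("cohort-label permutation FDR detects planted heterogeneity", {
  st <- study_heterogeneity(seed = 43, delta_z = 0.4, n_shift = 20)
  het <- heterogeneity_fdr(st$counts, n_perm = 50, seed = 44, n_inner = 10)
  ps <- st$truth$planted_specific
  planted <- paste(het$records$feature_i, het$records$feature_j) %in%
    paste(st$truth$features[ps$i], st$truth$features[ps$j])
  expect_gte(mean(het$records$q_perm[planted] < 0.05), 0.8)
  expect_lte(mean(het$records$class[!planted] == "heterogeneous"), 0.10)
  # stable edges have nominal p above alpha by definition
  expect_true(all(het$records$p[het$records$class == "stable"] > 0.05))
})

test_that("specificity calls recover planted cohort-specific edges without false calls", {
  st <- study_specificity(seed = 21)
  het <- heterogeneity_fdr(st$counts, n_perm = 50, seed = 33, n_inner = 20)
  calls <- specificity_calls(het)
  sp <- calls[calls$specific %in% TRUE, ]
  ps <- st$truth$planted_specific
  truthkey <- paste(st$truth$features[ps$i], st$truth$features[ps$j], ps$cohort)
  callkey <- paste(sp$feature_i, sp$feature_j, sp$outlier_cohort)
  # every call made is a planted edge with the right cohort
  expect_true(all(callkey %in% truthkey))
  # and a majority of planted edges is recovered (the IQR rule's own power
  # at this sample size caps recovery; see the methods vignette)
  expect_gte(length(callkey), 13)
  # FDR estimate and key-node detection on the same permutations
  sfdr <- specificity_fdr(het, calls)
  expect_lte(sfdr$fdr, 0.3)
  kn <- key_nodes(calls, sfdr$perm_node_max, st$truth$features)
  expect_true(kn$nodes$is_key[kn$nodes$feature == st$hub])
  expect_gt(kn$nodes$n_specific[kn$nodes$feature == st$hub], kn$cutoff)
  expect_gte(kn$cutoff, 2)
})

test_that("key-node cutoff follows the permutation maxima distribution", {
  calls <- data.frame(feature_i = rep("h", 15), feature_j = paste0("x", 1:15),
                      specific = TRUE, outlier_cohort = "A")
  feats <- c("h", paste0("x", 1:15))
  kn <- key_nodes(calls, rep(7, 100), feats)
  expect_equal(kn$cutoff, 8L)
  expect_true(kn$nodes$is_key[1])
  expect_false(any(kn$nodes$is_key[-1]))
  # no node reaches an unattainable cutoff
  kn2 <- key_nodes(calls, rep(40, 100), feats)
  expect_equal(sum(kn2$nodes$is_key), 0)
  # cutoff is monotone in the maxima distribution (stochastic ordering)
  set.seed(5)
  lo <- rpois(100, 2); hi <- lo + rpois(100, 3)
  expect_lte(key_nodes(calls, lo, feats)$cutoff,
             key_nodes(calls, hi, feats)$cutoff)
})

test_that("enrichment test is monotone in concentration and flat when uniform", {
  mk <- function(kA, total) data.frame(
    feature_i = paste0("a", seq_len(total)), feature_j = "z",
    specific = TRUE,
    outlier_cohort = rep(c("A", "B", "C", "D"),
                         c(kA, rep((total - kA) %/% 3, 2),
                           total - kA - 2 * ((total - kA) %/% 3))))
  p_vals <- sapply(c(10, 20, 30), function(k)
    enrichment_test(mk(k, 40), "A")$p)
  expect_true(all(diff(p_vals) < 0))
  unif <- enrichment_test(mk(10, 40), "A")
  expect_equal(unif$p, 1)
  single <- data.frame(feature_i = "a", feature_j = "b", specific = TRUE,
                       outlier_cohort = "A")
  expect_equal(enrichment_test(single, "A")$p, 1)
})

test_that("replication logic: identical replicates, opposite effects do not", {
  ed <- data.frame(feature_i = c("a", "b"), feature_j = c("b", "c"),
                   rho = c(0.4, -0.2), n = 300)
  self <- replication_compare(ed, ed)
  expect_equal(self$edges$Q, c(0, 0))
  expect_equal(self$rate_replicable, 1)
  # opposite strong effects: z = +/-0.6, se = 0.08 on the z scale
  n_eq <- round(1 / 0.08^2 + 3)   # n giving se ~ 0.08
  ed1 <- data.frame(feature_i = "a", feature_j = "b", rho = tanh(0.6), n = n_eq)
  ed2 <- data.frame(feature_i = "a", feature_j = "b", rho = tanh(-0.6), n = n_eq)
  rc <- replication_compare(ed1, ed2)
  expect_equal(rc$edges$Q, (0.6 - -0.6)^2 / (2 * 0.08^2), tolerance = 0.01)
  expect_false(rc$edges$replicable)
  # split-sample self-replication of one synthetic truth
  tr <- make_basis_network(p = 12, n_edges = 6, rho = 0.5, seed = 51)
  c1 <- simulate_cohort(tr, "D1", n = 300, depth = 30000, seed = 52)
  c2 <- simulate_cohort(tr, "D2", n = 300, depth = 30000, seed = 53)
  e1 <- cohort_effects(list(D1 = c1$counts), n_inner = 10, seed = 54)
  e2 <- cohort_effects(list(D2 = c2$counts), n_inner = 10, seed = 55)
  d1 <- cbind(e1$pairs, rho = e1$rho[, 1], n = 300)
  d2 <- cbind(e2$pairs, rho = e2$rho[, 1], n = 300)
  rr <- replication_compare(d1, d2)
  expect_gte(rr$rate_replicable, 0.85)
})

test_that("stratified comparison flags a planted subtype difference only", {
  tr <- make_basis_network(p = 16, n_edges = 0, rho = 0, seed = 61)
  trB <- plant_specific_edge(tr, c(1, 2), "B", 0.6)
  gA <- simulate_cohort(trB, "A", n = 200, depth = 30000, seed = 62)
  gB <- simulate_cohort(trB, "B", n = 200, depth = 30000, seed = 63)
  counts <- cbind(unclass(gA$counts), unclass(gB$counts))
  groups <- rep(c("A", "B"), each = 200)
  out <- stratified_compare(counts, groups, n_inner = 10, seed = 64)
  hit <- out$feature_i == tr$features[1] & out$feature_j == tr$features[2]
  expect_true(out$differential[hit])
  expect_lte(mean(out$differential[!hit]), 0.08)
  # identical groups (same samples both sides, deterministic point
  # estimates): zero differential edges
  out0 <- stratified_compare(cbind(unclass(gA$counts), unclass(gA$counts)),
                             rep(c("x", "y"), each = 200),
                             n_inner = 1, seed = 66)
  expect_equal(sum(out0$differential), 0)
  expect_error(stratified_compare(counts, rep(c("A", "b2"), c(390, 10))),
               "b2")
})
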