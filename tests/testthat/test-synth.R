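test_that("basis network construction records realized edge values", {
  t0 <- make_basis_network(p = 10, n_edges = 0, rho = 0, seed = 1)
  expect_equal(unname(t0$Sigma), diag(10))
  t1 <- make_basis_network(p = 4, n_edges = 1, rho = 0.6, seed = 2)
  # a single off-diagonal 0.6 is already PD: returned unchanged
  expect_equal(t1$edges$rho_realized, 0.6)
  expect_equal(min(eigen(t1$Sigma)$values) > 1e-8, TRUE)
  t2 <- make_basis_network(p = 30, n_edges = 12, rho = 0.6, seed = 3)
  expect_true(all(abs(t2$edges$rho_realized - 0.6) <= 0.05))
  expect_error(make_basis_network(p = 4, n_edges = 7, rho = 0.5), "n_edges")
})

test_that("planting a specific edge modifies only the target cohort", {
  tr <- make_basis_network(p = 6, n_edges = 0, rho = 0, seed = 1)
  tr <- plant_specific_edge(tr, c(2, 5), "D", 0.6)
  expect_equal(tr$cohort_Sigma$D[2, 5], 0.6)
  expect_equal(unname(tr$Sigma), diag(6))   # shared matrix untouched
  # replanting replaces the old value
  tr <- plant_specific_edge(tr, c(2, 5), "D", 0.3)
  expect_equal(tr$cohort_Sigma$D[2, 5], 0.3)
  expect_equal(sum(tr$planted_specific$i == 2 & tr$planted_specific$j == 5), 1)
  # a planting that breaks positive definiteness (0.8-0.8 path through one
  # node) is projected; the realized value is recorded below the target
  tr2 <- make_basis_network(p = 6, n_edges = 0, rho = 0, seed = 1)
  tr2 <- plant_specific_edge(tr2, c(1, 2), "D", 0.8)
  tr2 <- plant_specific_edge(tr2, c(2, 3), "D", 0.8)
  realized <- tr2$planted_specific$rho_realized
  expect_lt(realized[2], 0.8)
  expect_equal(tr2$cohort_Sigma$D[2, 3], realized[2])
  expect_gt(min(eigen(tr2$cohort_Sigma$D)$values), 1e-8)
  # a perturbation that would corrupt earlier planted truth is refused
  tr3 <- plant_specific_edge(make_basis_network(6, 0, 0, seed = 1),
                             c(1, 2), "D", 0.85)
  expect_error(plant_specific_edge(tr3, c(2, 3), "D", 0.85), "> 0.1")
})

test_that("simulated log-basis correlations track the planted truth", {
  tr <- make_basis_network(p = 8, n_edges = 4, rho = 0.6, seed = 5,
                           log_sd = 1)
  co <- simulate_cohort(tr, "A", n = 4000, depth = 30000, seed = 6)
  emp <- stats::cor(t(co$log_basis))
  expect_true(all(abs(emp - tr$Sigma) < 0.05))
  expect_error(simulate_cohort(tr, "A", n = 10, depth = 0), "depth")
})

test_that("covariate loadings of zero leave features uncorrelated with age", {
  tr <- make_basis_network(p = 6, n_edges = 0, rho = 0, seed = 7, log_sd = 1)
  co <- simulate_cohort(tr, "A", n = 2000, depth = 30000, seed = 8)
  lf <- log(fractions_from_counts(co$counts, "mean"))
  r <- apply(lf, 1, function(v) stats::cor(v, co$metadata$age))
  expect_true(all(abs(r) < 0.06))
})

test_that("age loading confounds a feature pair: marginal > partial", {
  # property of the generator itself, checked on the latent log basis (on
  # CLR coordinates at small p the -1/p compositional covariance masks it)
  tr <- make_basis_network(p = 6, n_edges = 0, rho = 0, seed = 9, log_sd = 1,
                           beta_age = c(0.04, 0.04, 0, 0, 0, 0))
  co <- simulate_cohort(tr, "A", n = 2000, depth = 30000, seed = 10)
  A <- co$log_basis[1, ]; B <- co$log_basis[2, ]
  marginal <- stats::cor(A, B)
  partial <- partial_cor_data(A, B, co$metadata$age)
  expect_gt(marginal, 0.15)
  expect_gt(marginal, abs(partial))
  expect_lt(abs(partial), 0.05)
})

test_that("zero inflation produces the requested absence rate, jointly for groups", {
  tr <- make_basis_network(p = 6, n_edges = 0, rho = 0, seed = 11, pi = 0.3,
                           zero_groups = list(c(1, 2)))
  co <- simulate_cohort(tr, "A", n = 800, depth = 10000, seed = 12)
  pres <- presence_matrix(co$abundance)
  expect_true(all(abs(rowMeans(pres) - 0.7) < 0.07))
  # grouped features are absent together far more often than independent ones
  joint12 <- mean(pres[1, ] == 0 & pres[2, ] == 0)
  joint34 <- mean(pres[3, ] == 0 & pres[4, ] == 0)
  expect_gt(joint12, 0.2)   # ~0.3 under shared draws
  expect_lt(joint34, 0.15)  # ~0.09 under independence
})

test_that("make_study is deterministic and validates its config", {
  cfg <- list(p = 8, n_edges = 3, rho = 0.5,
              cohorts = list(A = list(n = 30, depth = 5000),
                             B = list(n = 40, depth = 5000)),
              planted = list(list(edge = c(1, 2), cohort = "B", rho = 0.6)))
  s1 <- make_study(cfg, seed = 42)
  s2 <- make_study(cfg, seed = 42)
  expect_identical(s1$cohorts$A$counts, s2$cohorts$A$counts)
  expect_identical(s1$truth$Sigma, s2$truth$Sigma)
  expect_equal(names(s1$cohorts), c("A", "B"))
  expect_equal(ncol(s1$cohorts$B$counts), 40)
  expect_equal(s1$truth$cohort_Sigma$B[1, 2], 0.6)
  expect_error(make_study(list(p = 8, bogus = 1), seed = 1), "bogus")
  cfg_bad <- cfg
  cfg_bad$cohorts <- list(A = list(n = 30))
  expect_error(make_study(cfg_bad, 1), "depth")
})

test_that("written studies are read back by the table reader", {
  cfg <- list(p = 6, n_edges = 0, cohorts = list(A = list(n = 25, depth = 8000)))
  st <- make_study(cfg, seed = 3)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  md <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  tab <- read_abundance_table(file.path(dir, "A_abundance.tsv"), "species",
                              metadata = md)
  expect_equal(dim(tab), c(6L, 25L))
  expect_equal(unclass(tab), unclass(st$cohorts$A$abundance),
               tolerance = 1e-12, ignore_attr = TRUE)
})
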