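#' Project a symmetric matrix to the nearest positive-definite correlation matrix
#'
#' Eigenvalue clipping at `eig_floor` followed by rescaling to unit diagonal,
#' iterated until the smallest eigenvalue exceeds `tol`.
#'
#' @param S symmetric matrix with unit diagonal.
#' @param eig_floor eigenvalues are clipped at this value before reconstruction.
#' @param tol required smallest eigenvalue of the result.
#' @return positive-definite correlation matrix.
#' @keywords internal
project_correlation <- function(S, eig_floor = 1e-6, tol = 1e-8) {
  for (it in 1:50) {
    e <- eigen(S, symmetric = TRUE)
    if (min(e$values) > tol) return(S)
    v <- pmax(e$values, eig_floor)
    S <- e$vectors %*% (v * t(e$vectors))
    d <- sqrt(diag(S))
    S <- S / tcrossprod(d)
    diag(S) <- 1
    S <- (S + t(S)) / 2
  }
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= tol)
    stop("positive-definite projection failed")
  S
}

#' Build a sparse basis correlation network with known truth
#'
#' Places `n_edges` random off-diagonal correlations of value `rho` in a p x p
#' identity matrix and projects to the nearest positive-definite correlation
#' matrix; the realized (post-projection) edge values are recorded as the
#' ground truth. Feature-level generative parameters (log-scale means and SDs,
#' zero-inflation probabilities, covariate loadings) are drawn here so the
#' whole data-generating process is captured in one `synthetic_truth` object.
#'
#' @param p number of features.
#' @param n_edges number of nonzero basis correlations (<= p(p-1)/2).
#' @param rho target correlation value for planted edges, |rho| < 1.
#' @param seed integer RNG seed.
#' @param mu log-scale mean vector (default: standard normal draws).
#' @param log_sd log-scale SDs (default: uniform(0.5, 1.5) draws, emulating
#'   the heavy-tailed spread of real abundances).
#' @param pi per-feature structural zero probability (scalar recycled).
#' @param beta_age,beta_sex per-feature additive loadings on the log-mean
#'   (per year of age, centered at 45; per unit of sex coded 0/1).
#' @param zero_groups optional list of feature index vectors; the features of
#'   a group share one zero-inflation draw per sample (structural co-absence,
#'   the signal the co-occurrence network detects).
#' @return `synthetic_truth`: list with `features`, `Sigma` (shared basis
#'   correlation matrix), `cohort_Sigma` (named list of per-cohort overrides),
#'   `edges` (data frame i, j, rho_target, rho_realized), `planted_specific`,
#'   `mu`, `log_sd`, `pi`, `beta_age`, `beta_sex`.
#' @export
make_basis_network <- function(p, n_edges, rho = 0.6, seed = 1,
                               mu = NULL, log_sd = NULL, pi = 0,
                               beta_age = 0, beta_sex = 0,
                               zero_groups = NULL) {
  stopifnot(p >= 2, n_edges >= 0, abs(rho) < 1)
  if (n_edges > p * (p - 1) / 2) stop("n_edges exceeds p(p-1)/2")
  set.seed(seed)
  pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
  sel <- if (n_edges > 0) sample(nrow(pairs), n_edges) else integer(0)
  S <- diag(p)
  for (k in sel) {
    S[pairs[k, 1], pairs[k, 2]] <- rho
    S[pairs[k, 2], pairs[k, 1]] <- rho
  }
  S <- project_correlation(S)
  edges <- if (n_edges > 0) {
    data.frame(i = pairs[sel, 1], j = pairs[sel, 2], rho_target = rho,
               rho_realized = S[pairs[sel, , drop = FALSE]])
  } else {
    data.frame(i = integer(0), j = integer(0),
               rho_target = numeric(0), rho_realized = numeric(0))
  }
  features <- sprintf("sp%03d", seq_len(p))
  dimnames(S) <- list(features, features)
  structure(list(
    p = p, features = features, Sigma = S, cohort_Sigma = list(),
    edges = edges,
    planted_specific = data.frame(i = integer(0), j = integer(0),
                                  cohort = character(0),
                                  rho_target = numeric(0),
                                  rho_realized = numeric(0)),
    mu = if (is.null(mu)) stats::rnorm(p) else rep_len(mu, p),
    log_sd = if (is.null(log_sd)) stats::runif(p, 0.5, 1.5) else rep_len(log_sd, p),
    pi = rep_len(pi, p),
    beta_age = rep_len(beta_age, p), beta_sex = rep_len(beta_sex, p),
    zero_groups = zero_groups),
    class = "synthetic_truth")
}

cohort_sigma <- function(truth, cohort) {
  if (!is.null(truth$cohort_Sigma[[cohort]])) truth$cohort_Sigma[[cohort]]
  else truth$Sigma
}

#' Plant a cohort-specific basis correlation
#'
#' Sets the basis correlation of one feature pair to `rho_specific` in one
#' cohort's matrix (creating a per-cohort override of the shared matrix),
#' re-projects to positive definiteness, and records the realized value. If
#' re-projection moves any previously planted edge by more than 0.1 the truth
#' would be corrupted and an error is raised.
#'
#' @param truth a `synthetic_truth`.
#' @param edge integer pair `c(i, j)`.
#' @param cohort cohort label.
#' @param rho_specific the cohort-specific correlation value.
#' @return the updated `synthetic_truth`.
#' @export
plant_specific_edge <- function(truth, edge, cohort, rho_specific) {
  stopifnot(length(edge) == 2, all(edge >= 1), all(edge <= truth$p))
  i <- min(edge); j <- max(edge)
  if (i == j) stop("edge must join two distinct features")
  S <- cohort_sigma(truth, cohort)
  old <- S
  S[i, j] <- S[j, i] <- rho_specific
  S <- project_correlation(S)
  prev <- truth$planted_specific
  prev_here <- prev[prev$cohort == cohort & !(prev$i == i & prev$j == j), , drop = FALSE]
  if (nrow(prev_here)) {
    moved <- abs(S[cbind(prev_here$i, prev_here$j)] -
                   old[cbind(prev_here$i, prev_here$j)])
    if (any(moved > 0.1))
      stop("re-projection perturbed previously planted edges by > 0.1")
  }
  truth$cohort_Sigma[[cohort]] <- S
  keep <- !(prev$i == i & prev$j == j & prev$cohort == cohort)
  truth$planted_specific <- rbind(
    prev[keep, , drop = FALSE],
    data.frame(i = i, j = j, cohort = cohort, rho_target = rho_specific,
               rho_realized = S[i, j]))
  rownames(truth$planted_specific) <- NULL
  truth
}

#' Simulate one cohort from a synthetic truth
#'
#' Logistic-normal-multinomial generator. Per sample: log-basis
#' `y ~ MVN(mu + beta_age (age - 45) + beta_sex sex, D Sigma_c D)` with
#' `D = diag(log_sd)`; basis `w = exp(y)`; structural zeros: feature i is set
#' to 0 with probability `pi_i` before closure; composition `x = w / sum(w)`;
#' counts `~ multinomial(depth, x)`. Age is uniform on [20, 70] years, sex is
#' Bernoulli(0.5). A sample zeroed everywhere is redrawn (at most 100 times).
#'
#' @param truth a `synthetic_truth`.
#' @param cohort cohort label (selects a planted per-cohort matrix if any).
#' @param n number of samples (>= 4).
#' @param depth sequencing depth (total counts per sample), scalar or length n.
#' @param seed integer RNG seed.
#' @param beta_age,beta_sex optional per-cohort overrides of the truth's
#'   covariate loadings (used to emulate cohort-confined confounding).
#' @return `synthetic_cohort`: list with `counts` (a [count_table()]),
#'   `abundance` (an [abundance_table()]), `metadata` ([sample_metadata()]),
#'   `log_basis` (the latent log-scale basis before zero inflation and
#'   closure, kept for truth-recovery diagnostics) and `truth`.
#' @export
simulate_cohort <- function(truth, cohort, n, depth, seed = 1,
                            beta_age = NULL, beta_sex = NULL) {
  stopifnot(n >= 4)
  if (any(depth <= 0)) stop("depth must be positive")
  depth <- rep_len(depth, n)
  set.seed(seed)
  p <- truth$p
  S <- cohort_sigma(truth, cohort)
  L <- chol(S)
  ba <- if (is.null(beta_age)) truth$beta_age else rep_len(beta_age, p)
  bs <- if (is.null(beta_sex)) truth$beta_sex else rep_len(beta_sex, p)
  age <- stats::runif(n, 20, 70)
  sex <- stats::rbinom(n, 1, 0.5)
  X <- matrix(0, nrow = p, ncol = n)
  Y <- matrix(0, nrow = p, ncol = n)   # latent log basis, kept for diagnostics
  for (s in seq_len(n)) {
    for (try in 1:100) {
      z <- stats::rnorm(p)
      y <- truth$mu + ba * (age[s] - 45) + bs * sex[s] +
        truth$log_sd * drop(crossprod(L, z))
      w <- exp(y)
      u <- stats::runif(p)
      for (g in truth$zero_groups) u[g] <- u[g[1]]
      w[u < truth$pi] <- 0
      if (sum(w) > 0) break
      if (try == 100) stop("sample zeroed in all features after 100 retries")
    }
    X[, s] <- w / sum(w)
    Y[, s] <- y
  }
  counts <- vapply(seq_len(n),
                   function(s) stats::rmultinom(1, depth[s], X[, s])[, 1],
                   integer(p))
  ids <- sprintf("%s_s%04d", cohort, seq_len(n))
  dimnames(counts) <- list(truth$features, ids)
  abund <- sweep(counts, 2, pmax(colSums(counts), 1), `/`)
  md <- sample_metadata(data.frame(sample = ids, cohort = cohort, age = age,
                                   sex = sex, read_depth = depth))
  dimnames(Y) <- dimnames(counts)
  structure(list(counts = count_table(counts, depth = depth),
                 abundance = abundance_table(abund, level = "species"),
                 metadata = md, log_basis = Y, truth = truth),
            class = "synthetic_cohort")
}

#' Simulate a multi-cohort study
#'
#' Builds a shared truth, applies per-cohort planted specific edges and
#' covariate-loading overrides, and simulates each cohort, all deterministically
#' from one seed (child seeds are drawn once from the master seed).
#'
#' Config keys: `p`, `n_edges`, `rho` (shared network); optional `mu`,
#' `log_sd`, `pi`, `beta_age`, `beta_sex`; `cohorts` — named list, each with
#' `n`, `depth` and optional `beta_age`/`beta_sex` overrides; optional
#' `planted` — list of `list(edge = c(i, j), cohort =, rho =)`.
#'
#' @param config named list (or path to a YAML file) as described above.
#' @param seed master integer seed.
#' @return `synthetic_study`: list with `truth`, `cohorts` (named list of
#'   `synthetic_cohort`s) and `config`.
#' @export
make_study <- function(config, seed = 1) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("p", "n_edges", "rho", "mu", "log_sd", "pi", "beta_age",
             "beta_sex", "zero_groups", "cohorts", "planted")
  bad <- setdiff(names(config), known)
  need <- setdiff(c("p", "n_edges", "cohorts"), names(config))
  if (length(bad) || length(need))
    stop("config schema violation; unknown keys: [",
         paste(bad, collapse = ", "), "]; missing keys: [",
         paste(need, collapse = ", "), "]")
  nco <- length(config$cohorts)
  if (nco < 1 || is.null(names(config$cohorts)))
    stop("config schema violation; cohorts must be a named list")
  set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1, nco + 1)
  truth <- make_basis_network(
    p = config$p, n_edges = config$n_edges,
    rho = if (is.null(config$rho)) 0.6 else config$rho, seed = child[1],
    mu = config$mu, log_sd = config$log_sd,
    pi = if (is.null(config$pi)) 0 else config$pi,
    beta_age = if (is.null(config$beta_age)) 0 else config$beta_age,
    beta_sex = if (is.null(config$beta_sex)) 0 else config$beta_sex,
    zero_groups = config$zero_groups)
  for (pl in config$planted)
    truth <- plant_specific_edge(truth, pl$edge, pl$cohort, pl$rho)
  cohorts <- list()
  for (k in seq_len(nco)) {
    nm <- names(config$cohorts)[k]
    cc <- config$cohorts[[k]]
    if (is.null(cc$n) || is.null(cc$depth))
      stop("config schema violation; cohort '", nm, "' needs keys n, depth")
    cohorts[[nm]] <- simulate_cohort(truth, nm, n = cc$n, depth = cc$depth,
                                     seed = child[k + 1],
                                     beta_age = cc$beta_age,
                                     beta_sex = cc$beta_sex)
  }
  structure(list(truth = truth, cohorts = cohorts, config = config),
            class = "synthetic_study")
}

#' Write a simulated study in the TSV dialect the readers consume
#'
#' One abundance TSV per cohort plus a single metadata TSV.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  md <- do.call(rbind, lapply(study$cohorts, function(co) as.data.frame(co$metadata)))
  mp <- file.path(dir, "metadata.tsv")
  utils::write.table(md, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- mp
  for (nm in names(study$cohorts)) {
    ab <- study$cohorts[[nm]]$abundance
    fp <- file.path(dir, paste0(nm, "_abundance.tsv"))
    utils::write.table(data.frame(feature = rownames(ab),
                                  unclass(ab), check.names = FALSE),
                       fp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, fp)
  }
  invisible(paths)
}
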