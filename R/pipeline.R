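#' Export an edge table as GraphML
#'
#' @param edges data frame with `feature_i`, `feature_j` and any edge
#'   attribute columns (e.g. `rho`, `q`, `outlier_cohort`).
#' @param path output file.
#' @param nodes optional full node namespace (isolated nodes included).
#' @return invisibly, the igraph object written.
#' @export
export_graphml <- function(edges, path, nodes = NULL) {
  el <- data.frame(from = edges$feature_i, to = edges$feature_j,
                   edges[setdiff(names(edges), c("feature_i", "feature_j"))],
                   check.names = FALSE)
  keep <- vapply(el, function(col) !all(is.na(col)), logical(1))
  g <- igraph::graph_from_data_frame(el[keep], directed = FALSE,
                                     vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(g)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full cross-cohort network pipeline
#'
#' Stages: prevalence filter -> per-cohort SparCC co-abundance with
#' permutation FDR -> StARS-sparsified conditional-independence graph and
#' intersection -> per-cohort co-occurrence network -> Cochran-Q heterogeneity
#' across cohorts with cohort-label permutation FDR -> IQR cohort-specificity
#' with study-level FDR -> key-node detection -> covariate adjustment of
#' specific calls. All outputs are written as TSV (plus GraphML for the
#' cohort-specific subnetwork) under `out_dir` together with a JSON manifest
#' of seeds, parameters and per-stage counts.
#'
#' @param config named list (or YAML path) with entries:
#'   `tables` — named list of per-cohort abundance TSV paths, or a
#'   pre-built named list of `abundance_table`s under `tables_obj`;
#'   `metadata` — metadata TSV path or `sample_metadata` under
#'   `metadata_obj`; `level`; `out_dir`;
#'   optional thresholds `prevalence` (0.20), `fdr` (0.05), `n_perm` (100),
#'   `n_inner` (20), `seed` (1); stage toggles `sparsify`, `cooccur`,
#'   `adjust` (all TRUE by default).
#' @return the manifest (named list), invisibly written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- function(key, default) if (is.null(config[[key]])) default else config[[key]]
  prevalence <- cfg("prevalence", 0.20)
  alpha <- cfg("fdr", 0.05)
  n_perm <- cfg("n_perm", 100)
  n_inner <- cfg("n_inner", 20)
  seed <- cfg("seed", 1)
  level <- cfg("level", "species")
  do_sparsify <- cfg("sparsify", TRUE)
  do_cooccur <- cfg("cooccur", TRUE)
  do_adjust <- cfg("adjust", TRUE)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config needs out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  md <- if (!is.null(config$metadata_obj)) config$metadata_obj
        else read_sample_metadata(config$metadata)
  tables <- if (!is.null(config$tables_obj)) config$tables_obj
            else lapply(config$tables, read_abundance_table, level = level)
  cohorts <- names(tables)
  set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1, 6)
  manifest <- list(package = "conetdiff",
                   version = as.character(utils::packageVersion("conetdiff")),
                   seed = seed, child_seeds = child,
                   parameters = list(prevalence = prevalence, fdr = alpha,
                                     n_perm = n_perm, n_inner = n_inner),
                   cohorts = cohorts, counts = list())
  log_stage <- function(stage, ...) message(sprintf("[%s] %s", stage, sprintf(...)))

  # stage: prevalence filter + counts conversion
  feats <- prevalence_filter(tables, threshold = prevalence)
  counts_list <- lapply(cohorts, function(ch) {
    tb <- tables[[ch]]
    sub <- tb[intersect(feats, rownames(tb)), , drop = FALSE]
    missing <- setdiff(feats, rownames(tb))
    if (length(missing)) {
      pad <- matrix(0, length(missing), ncol(tb),
                    dimnames = list(missing, colnames(tb)))
      sub <- rbind(sub, pad)
    }
    sub <- sub[feats, , drop = FALSE]
    to_counts(abundance_table(sub, level = level),
              md[md$sample %in% colnames(tb), , drop = FALSE])
  })
  names(counts_list) <- cohorts
  manifest$counts$features_filtered <- length(feats)
  log_stage("filter", "%d features retained", length(feats))

  # stage: per-cohort co-abundance
  final_edges <- list(); sparcc_counts <- integer(0)
  for (k in seq_along(cohorts)) {
    ch <- cohorts[k]
    ed <- permutation_edge_test(counts_list[[ch]], n_perm = n_perm,
                                seed = child[1] + k, n_inner = n_inner,
                                cohort = ch)
    write_tsv(ed, file.path(out_dir, paste0("coabundance_", ch, ".tsv")))
    sparcc_counts[ch] <- sum(ed$q < alpha)
    if (do_sparsify) {
      g <- stars_select(clr_transform(counts_list[[ch]]), seed = child[2] + k)
      ed <- intersect_edges(ed, g, alpha = alpha)
    } else {
      ed <- ed[ed$q < alpha, , drop = FALSE]
    }
    final_edges[[ch]] <- ed
    log_stage("coabundance", "%s: %d SparCC edges, %d after intersection",
              ch, sparcc_counts[ch], nrow(ed))
  }
  manifest$counts$sparcc_edges <- as.list(sparcc_counts)
  manifest$counts$final_edges <- lapply(final_edges, nrow)
  all_final <- do.call(rbind, final_edges)
  write_tsv(all_final, file.path(out_dir, "coabundance_final.tsv"))

  # stage: co-occurrence
  if (do_cooccur) {
    cooc <- do.call(rbind, lapply(seq_along(cohorts), function(k) {
      ch <- cohorts[k]
      ab <- sweep(counts_list[[ch]], 2, pmax(colSums(counts_list[[ch]]), 1), `/`)
      cooccurrence_network(presence_matrix(ab), n_perm = n_perm,
                           seed = child[3] + k, cohort = ch)
    }))
    write_tsv(cooc, file.path(out_dir, "cooccurrence.tsv"))
    manifest$counts$cooccurrence_significant <- sum(cooc$q < alpha)
    log_stage("cooccur", "%d significant pairs", sum(cooc$q < alpha))
  }

  # stage: heterogeneity on the cross-cohort union of detected edges
  pairs <- edge_pairs(feats)
  pair_key <- paste(pairs$feature_i, pairs$feature_j)
  union_key <- unique(paste(all_final$feature_i, all_final$feature_j))
  subset <- pair_key %in% union_key
  het <- heterogeneity_fdr(counts_list, n_perm = n_perm, seed = child[4],
                           n_inner = n_inner, alpha = alpha,
                           edge_subset = if (any(subset)) subset else NULL)
  write_tsv(cbind(het$records, rho = het$effects$rho),
            file.path(out_dir, "heterogeneity.tsv"))
  manifest$counts$union_edges <- sum(subset)
  manifest$counts$heterogeneous <-
    sum(het$records$class %in% "heterogeneous")
  log_stage("heterogeneity", "%d heterogeneous of %d tested",
            manifest$counts$heterogeneous, sum(subset))

  # stage: specificity, study FDR, key nodes
  calls <- specificity_calls(het)
  sfdr <- specificity_fdr(het, calls)
  kn <- key_nodes(calls, sfdr$perm_node_max, feats)
  write_tsv(calls, file.path(out_dir, "specificity.tsv"))
  write_tsv(kn$nodes, file.path(out_dir, "key_nodes.tsv"))
  sp <- calls[calls$specific %in% TRUE, , drop = FALSE]
  if (nrow(sp))
    export_graphml(sp[, c("feature_i", "feature_j", "outlier_cohort", "Q", "p")],
                   file.path(out_dir, "specific_network.graphml"), nodes = feats)
  manifest$counts$specific <- nrow(sp)
  manifest$counts$specificity_fdr <- sfdr$fdr
  manifest$counts$key_nodes <- sum(kn$nodes$is_key)
  manifest$counts$key_cutoff <- kn$cutoff
  log_stage("specificity", "%d specific calls (study FDR %.3f), %d key nodes",
            nrow(sp), if (is.na(sfdr$fdr)) NA else sfdr$fdr,
            sum(kn$nodes$is_key))

  # stage: covariate adjustment of the specific calls
  if (do_adjust && nrow(sp)) {
    md_list <- lapply(cohorts, function(ch)
      md[match(colnames(counts_list[[ch]]), md$sample), , drop = FALSE])
    names(md_list) <- cohorts
    adj <- adjust_specificity(calls, counts_list, md_list)
    write_tsv(adj, file.path(out_dir, "specificity_adjusted.tsv"))
    manifest$counts$specific_after_adjustment <- sum(adj$survives)
    log_stage("adjust", "%d of %d specific calls survive adjustment",
              sum(adj$survives), nrow(sp))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Summarize edges by feature groups
#'
#' Counts edges per unordered group pair (genus pairs for species networks,
#' metabolic-category pairs for pathway networks); within-group edges count
#' under the (G, G) pair. Unmapped features fall into `"other"`.
#'
#' @param edges data frame with `feature_i`, `feature_j`.
#' @param mapping named character vector feature -> group.
#' @return data frame: group_a, group_b (group_a <= group_b), n_edges.
#' @export
summarize_by_group <- function(edges, mapping) {
  g1 <- unname(mapping[edges$feature_i]); g1[is.na(g1)] <- "other"
  g2 <- unname(mapping[edges$feature_j]); g2[is.na(g2)] <- "other"
  a <- pmin(g1, g2); b <- pmax(g1, g2)
  agg <- as.data.frame(table(group_a = a, group_b = b),
                       stringsAsFactors = FALSE)
  agg <- agg[agg$Freq > 0, , drop = FALSE]
  names(agg)[3] <- "n_edges"
  rownames(agg) <- NULL
  agg
}
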