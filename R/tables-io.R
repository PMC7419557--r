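#' Abundance tables
#'
#' An `abundance_table` is a feature x sample matrix of relative abundances
#' (fractions) with a `level` attribute (`"species"` or `"pathway"`). It is the
#' universal input of the pipeline: MetaPhlAn species tables and HUMAnN2
#' pathway tables are both read into this container.
#'
#' @param values numeric feature x sample matrix of non-negative fractions.
#' @param level `"species"` or `"pathway"`.
#' @param stratified optional matrix of species-stratified pathway rows
#'   (rownames of the form `"PWY|g__Genus.s__Genus_species"`), kept alongside
#'   the community-level table for contribution analysis.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, level = c("species", "pathway"),
                            stratified = NULL) {
  level <- match.arg(level)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("feature names (rownames) are required")
  if (is.null(colnames(values))) stop("sample names (colnames) are required")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature names: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (any(values < 0)) stop("negative abundance values")
  cs <- colSums(values)
  if (any(cs > 1 + 1e-6))
    stop("column sums exceed 1; normalize to fractions first")
  structure(values, level = level, stratified = stratified,
            class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d %s features x %d samples\n",
              nrow(x), attr(x, "level"), ncol(x)))
  invisible(x)
}

#' Read a MetaPhlAn / HUMAnN2-style abundance TSV
#'
#' Reads a tab-separated table (first column = feature id, header = sample
#' ids). Values on percent scale (column sums > 1.5) are auto-detected and
#' rescaled to fractions. For `level = "species"` only species-level rows are
#' retained: rows whose deepest taxonomic rank prefix is `s__` (higher ranks
#' such as `g__` and strain `t__` rows are dropped; tables without rank
#' prefixes are kept whole). For `level = "pathway"` the unstratified rows form
#' the table and stratified `"pathway|species"` rows are stored in the
#' `stratified` attribute for [species_contribution()].
#'
#' @param path TSV file path.
#' @param level `"species"` or `"pathway"`.
#' @param metadata optional [sample_metadata()] data frame; if given, samples
#'   must match exactly (missing samples are named in the error).
#' @return An `abundance_table`.
#' @export
read_abundance_table <- function(path, level = c("species", "pathway"),
                                 metadata = NULL) {
  level <- match.arg(level)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "", comment.char = "", stringsAsFactors = FALSE)
  feats <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- feats
  if (anyDuplicated(feats))
    stop("duplicate feature names in ", path, ": ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "))
  if (any(m < 0)) stop("negative values in ", path)
  # percent vs fraction dialect, decided on the full table before row filtering
  if (any(colSums(m) > 1.5)) m <- m / 100
  stratified <- NULL
  if (level == "species") {
    last_rank <- vapply(strsplit(rownames(m), "|", fixed = TRUE),
                        function(s) s[[length(s)]], character(1))
    has_ranks <- any(grepl("^[a-z]__", last_rank))
    if (has_ranks) {
      keep <- grepl("^s__", last_rank)
      m <- m[keep, , drop = FALSE]
      rownames(m) <- vapply(strsplit(rownames(m), "|", fixed = TRUE),
                            function(s) s[[length(s)]], character(1))
    }
  } else {
    strat <- grepl("|", rownames(m), fixed = TRUE)
    if (any(strat)) stratified <- m[strat, , drop = FALSE]
    m <- m[!strat, , drop = FALSE]
  }
  if (!is.null(metadata)) {
    missing_meta <- setdiff(colnames(m), metadata$sample)
    missing_tab <- setdiff(metadata$sample, colnames(m))
    if (length(missing_meta) || length(missing_tab))
      stop("sample mismatch with metadata; missing from metadata: [",
           paste(missing_meta, collapse = ", "), "]; missing from table: [",
           paste(missing_tab, collapse = ", "), "]")
  }
  abundance_table(m, level = level, stratified = stratified)
}

#' Read per-sample metadata
#'
#' Required columns: `sample`, `cohort`, `age` (years), `sex` (0/1),
#' `read_depth` (total sequenced reads). Additional columns (sub-phenotype
#' labels, medication use, ...) are carried through.
#'
#' @param path TSV path.
#' @return data frame of class `sample_metadata`.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "", stringsAsFactors = FALSE)
  sample_metadata(md)
}

#' @rdname read_sample_metadata
#' @param df data frame with the required columns.
#' @export
sample_metadata <- function(df) {
  req <- c("sample", "cohort", "age", "sex", "read_depth")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("metadata missing required columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample)) stop("duplicate sample ids in metadata")
  if (any(!is.finite(df$read_depth)) || any(df$read_depth <= 0))
    stop("read_depth must be > 0 for every sample")
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Prevalence filter across cohorts
#'
#' Retains a feature if it is present (abundance strictly > 0) in at least
#' `threshold` of samples in at least one cohort. The feature namespace is the
#' ordered union over cohorts (a feature absent from a cohort's table has
#' prevalence 0 there).
#'
#' @param tables named list of `abundance_table`s, one per cohort.
#' @param threshold prevalence fraction, default 0.20.
#' @param strict if `TRUE` require prevalence strictly greater than
#'   `threshold`; default `FALSE` (`>=`).
#' @return character vector of retained feature ids, union order preserved.
#' @export
prevalence_filter <- function(tables, threshold = 0.20, strict = FALSE) {
  if (!length(tables)) stop("no cohort tables given")
  if (any(vapply(tables, function(t) ncol(t) == 0L || nrow(t) == 0L, logical(1))))
    stop("empty abundance table")
  feats <- Reduce(union, lapply(tables, rownames))
  prev <- vapply(tables, function(t) {
    p <- setNames(numeric(length(feats)), feats)
    p[rownames(t)] <- rowMeans(t > 0)
    p
  }, numeric(length(feats)))
  prev <- matrix(prev, nrow = length(feats),
                 dimnames = list(feats, names(tables)))
  hit <- if (strict) prev > threshold else prev >= threshold
  feats[rowSums(hit) > 0]
}

#' Per-cohort feature prevalence
#'
#' @inheritParams prevalence_filter
#' @return feature x cohort matrix of presence fractions.
#' @export
feature_prevalence <- function(tables) {
  feats <- Reduce(union, lapply(tables, rownames))
  out <- vapply(tables, function(t) {
    p <- setNames(numeric(length(feats)), feats)
    p[rownames(t)] <- rowMeans(t > 0)
    p
  }, numeric(length(feats)))
  matrix(out, nrow = length(feats), dimnames = list(feats, names(tables)))
}

#' Convert relative abundances to predicted read counts
#'
#' Multiplies each sample's relative abundances by its total sequence count
#' and rounds half away from zero (so a rare taxon at exactly half a read is
#' not systematically truncated to zero).
#'
#' @param table an `abundance_table`.
#' @param metadata a `sample_metadata` data frame supplying `read_depth`.
#' @return A `count_table`: integer feature x sample matrix with a `depth`
#'   attribute (per-sample total sequence counts).
#' @export
to_counts <- function(table, metadata) {
  idx <- match(colnames(table), metadata$sample)
  if (anyNA(idx))
    stop("missing read_depth for samples: ",
         paste(colnames(table)[is.na(idx)], collapse = ", "))
  depth <- metadata$read_depth[idx]
  x <- sweep(unclass(table), 2, depth, `*`)
  cnt <- floor(abs(x) + 0.5) * sign(x)  # half away from zero; x >= 0 here
  storage.mode(cnt) <- "integer"
  count_table(cnt, depth = depth)
}

#' @rdname to_counts
#' @param counts integer feature x sample matrix.
#' @param depth per-sample total sequence counts (defaults to column sums).
#' @export
count_table <- function(counts, depth = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  if (any(t(counts) > depth))
    stop("a single count exceeds its sample's read depth")
  structure(counts, depth = depth, class = c("count_table", "matrix", "array"))
}

#' Inverse Simpson index (effective number of features)
#'
#' n_eff = 1 / sum(p_i^2) after renormalizing the composition to sum 1. Equals
#' k for a uniform k-part composition and 1 for a single-feature composition;
#' it is the applicability diagnostic for SparCC (reliable for diverse
#' compositions, roughly n_eff < 13).
#'
#' @param composition non-negative numeric vector.
#' @return scalar n_eff in `[1, length(composition)]`.
#' @export
inverse_simpson <- function(composition) {
  if (any(composition < 0)) stop("negative abundances")
  s <- sum(composition)
  if (s == 0) stop("all-zero composition")
  p <- composition / s
  1 / sum(p^2)
}

#' Cohort composition summary
#'
#' Per cohort: the mean over samples of the per-sample inverse Simpson index
#' (headline n_eff), the inverse Simpson index of the cohort-mean composition,
#' and per-feature prevalence.
#'
#' @inheritParams prevalence_filter
#' @return list with `n_eff` (data frame: cohort, n_eff_mean_of_samples,
#'   n_eff_of_mean) and `prevalence` (feature x cohort matrix).
#' @export
composition_summary <- function(tables) {
  n_eff <- do.call(rbind, lapply(names(tables), function(ch) {
    t <- tables[[ch]]
    per_sample <- apply(unclass(t), 2, inverse_simpson)
    data.frame(cohort = ch,
               n_eff_mean_of_samples = mean(per_sample),
               n_eff_of_mean = inverse_simpson(rowMeans(t)))
  }))
  list(n_eff = n_eff, prevalence = feature_prevalence(tables))
}
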