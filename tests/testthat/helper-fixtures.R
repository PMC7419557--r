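# small programmatic fixtures shared across test files

write_species_tsv <- function(path, percent = TRUE) {
  # MetaPhlAn-style table with a genus row, two species rows and a strain row
  vals <- rbind(
    "k__Bacteria|g__Dorea"                                  = c(30, 40),
    "k__Bacteria|g__Dorea|s__Dorea_longicatena"             = c(20, 25),
    "k__Bacteria|g__Faecalibacterium|s__F_prausnitzii"      = c(80, 75),
    "k__Bacteria|g__Dorea|s__Dorea_longicatena|t__GCF_0001" = c(20, 25))
  if (!percent) {
    # fraction-scale dialect: species-only rows, columns summing to <= 1
    vals <- vals[grepl("s__[^|]+$", rownames(vals)), ] / 100
  }
  df <- data.frame(feature = rownames(vals), vals, check.names = FALSE)
  colnames(df) <- c("#clade", "S1", "S2")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_pathway_tsv <- function(path) {
  vals <- rbind("PWY-5837"                                        = c(120, 90),
                "PWY-5837|g__Escherichia.s__Escherichia_coli"     = c(30, 45),
                "PWY-5837|g__Bacteroides.s__Bacteroides_fragilis" = c(60, 20),
                "PWY-101"                                         = c(10, 5))
  vals <- vals / 400
  df <- data.frame(feature = rownames(vals), vals, check.names = FALSE)
  colnames(df) <- c("#pathway", "S1", "S2")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_metadata <- function(samples, cohort = "A", depth = 10000) {
  sample_metadata(data.frame(
    sample = samples, cohort = cohort,
    age = seq(30, 60, length.out = length(samples)),
    sex = rep_len(c(0, 1), length(samples)),
    read_depth = depth))
}

toy_abundance <- function(p = 4, n = 6, seed = 1, level = "species") {
  set.seed(seed)
  m <- matrix(stats::rexp(p * n), p, n,
              dimnames = list(sprintf("f%02d", 1:p), sprintf("s%02d", 1:n)))
  m <- sweep(m, 2, colSums(m), `/`)
  abundance_table(m, level = level)
}
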