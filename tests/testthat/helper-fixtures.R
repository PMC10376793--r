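# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except through its own tempfile.

write_csv_fixture <- function(df) {
  tf <- tempfile(fileext = ".csv")
  readr::write_csv(df, tf)
  tf
}

# tiny hand-enumerable panel: 3 genes x 4 cell lines
toy_expression_df <- function() {
  data.frame(
    gene_id = c("TRAP1", "HSPD1", "CLPP"),
    C1 = c(5.0, 2.0, 1.0),
    C2 = c(6.0, 2.5, 1.5),
    C3 = c(4.0, 3.0, 2.0),
    C4 = c(7.0, 3.5, 2.5)
  )
}

toy_catalog_df <- function() {
  data.frame(
    drug_id = sprintf("D%02d", 1:12),
    drug_name = sprintf("drug%02d", 1:12),
    targets = rep("T1;T2", 12),
    category = rep(c("Mitosis", "DNA replication"), each = 6)
  )
}

toy_metadata_df <- function() {
  data.frame(
    cell_line_id = c("C1", "C2", "C3", "C4", "C5"),
    tissue = c("ovary", "ovary", "blood", "lung", "lung"),
    subtype = c("ovary", "ovary", "blood", "Lung_Nsclc_SCC", "Lung_Nsclc_SCC")
  )
}

# small but fully-populated synthetic dataset for module tests:
# 2 subtypes x 12 lines, 2 categories x 10 drugs (passes default filters
# only when min thresholds are lowered; used with explicit min_lines)
small_dataset <- function(seed = 42, planted = list(), ...) {
  cfg <- synthetic_config(n_genes = 10, n_drugs = 20, n_categories = 2,
                          n_subtypes = 2, lines_per_subtype = 12,
                          planted = planted, seed = seed, ...)
  suppressWarnings(generate_dataset(cfg))
}

# brute-force oracle: per-pair loop over genes x groups with stats::cor and
# the explicit atanh(r) * sqrt(n - 3) formula, independent of the vectorised
# implementation path
oracle_correlations <- function(cohort, expression, response, genes, z_cutoff = 1.7) {
  out <- list()
  k <- 0
  for (i in seq_len(nrow(cohort$groups))) {
    g <- cohort$groups[i, ]
    lines <- g$cell_lines[[1]]
    auc <- vapply(lines, function(cl) {
      response$auc[response$drug_id == g$drug_id & response$cell_line_id == cl]
    }, numeric(1))
    for (gene in genes) {
      x <- expression[gene, lines]
      r <- if (sd(x) == 0 || sd(auc) == 0) NA_real_ else stats::cor(x, auc)
      z <- if (is.na(r)) NA_real_ else {
        atanh(min(max(r, -1 + 1e-7), 1 - 1e-7)) * sqrt(g$n - 3)
      }
      k <- k + 1
      out[[k]] <- data.frame(gene = gene, drug_id = g$drug_id,
                             subtype = g$subtype, n = g$n, r = r, z = z,
                             sig_pos = !is.na(z) && z >= z_cutoff,
                             sig_neg = !is.na(z) && z <= -z_cutoff)
    }
  }
  do.call(rbind, out)
}
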