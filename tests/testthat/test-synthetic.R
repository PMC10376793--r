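test_that("generation is deterministic in the seed and validates its config", {
  cfg <- synthetic_config(n_genes = 20, n_drugs = 20, n_categories = 2,
                          n_subtypes = 2, lines_per_subtype = 12, seed = 123)
  a <- suppressWarnings(generate_dataset(cfg))
  b <- suppressWarnings(generate_dataset(cfg))
  expect_identical(a$expression, b$expression)
  expect_identical(a$response, b$response)
  expect_identical(a$catalog, b$catalog)
  expect_identical(a$metadata, b$metadata)
  c_ <- suppressWarnings(generate_dataset(synthetic_config(n_genes = 20, n_drugs = 20,
                                          n_categories = 2, n_subtypes = 2,
                                          lines_per_subtype = 12, seed = 124)))
  expect_false(identical(a$response$auc, c_$response$auc))

  # byte-identical files from the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(a, d1); write_dataset(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }

  expect_error(synthetic_config(planted = list(planted_effect(
    "NOT_A_GENE", category_name(1), subtype_name(1), target_r = 0.5))),
    "not a generated gene")
  expect_error(planted_effect("g", "c", "s", target_r = 1.2))
  expect_error(planted_effect("g", "c", "s", drug_fraction = 0, target_r = 0.5))
})

test_that("unplanted pairs are uncorrelated and planted pairs hit their target r", {
  # independence: mean |r| over gene-drug pairs across the full panel
  # (4 x 20 = 80 lines) well below 0.1
  cfg0 <- synthetic_config(n_genes = 200, n_drugs = 8, n_categories = 1,
                           n_subtypes = 4, lines_per_subtype = 20, seed = 55)
  ds0 <- suppressWarnings(generate_dataset(cfg0))
  auc_wide <- tidyr::pivot_wider(ds0$response, names_from = "drug_id",
                                 values_from = "auc")
  auc_mat <- as.matrix(auc_wide[-1])[match(colnames(ds0$expression),
                                           auc_wide$cell_line_id), ]
  r_pool <- stats::cor(t(ds0$expression), auc_mat)
  expect_lt(mean(abs(r_pool)), 0.1)

  # planted r = -0.6 with n = 25: empirical r within +/- 0.25 of target for
  # >= 80% of affected (drug, subtype) pairs, across 10 generation seeds
  hits <- 0; total <- 0
  for (seed in 1:10) {
    cfg <- synthetic_config(
      n_genes = 5, n_drugs = 12, n_categories = 1, n_subtypes = 2,
      lines_per_subtype = 25,
      planted = list(planted_effect(gene_name(1), category_name(1),
                                    subtype_name(1:2), drug_fraction = 1,
                                    target_r = -0.6)),
      seed = seed)
    ds <- suppressWarnings(generate_dataset(cfg))
    cohort <- build_cohort(ds$expression, ds$response, ds$catalog, ds$metadata)
    tab <- correlate_cohort(cohort, ds$expression, ds$response,
                            genes = gene_name(1))
    truth <- planted_truth(cfg)
    planted <- dplyr::semi_join(tab, truth, by = c("gene", "drug_id", "subtype"))
    hits <- hits + sum(abs(planted$r - (-0.6)) <= 0.25)
    total <- total + nrow(planted)
  }
  expect_equal(total, 10 * 12 * 2)
  expect_gte(hits / total, 0.8)
})

test_that("planted truth enumerates exactly the affected combinations", {
  cfg <- synthetic_config(
    n_genes = 30, n_drugs = 20, n_categories = 1, n_subtypes = 3,
    lines_per_subtype = 12,
    planted = list(planted_effect(gene_name(7), category_name(1),
                                  subtype_name(1:2), drug_fraction = 0.5,
                                  target_r = -0.5)),
    seed = 2)
  truth <- planted_truth(cfg)
  expect_identical(nrow(truth), 10L * 2L)   # half of 20 drugs x 2 subtypes
  expect_true(all(truth$sign == -1))
  expect_identical(nrow(planted_truth(synthetic_config(seed = 2))), 0L)

  # truth entries are contained in the generated (drug, subtype) groups
  ds <- suppressWarnings(generate_dataset(cfg))
  cohort <- build_cohort(ds$expression, ds$response, ds$catalog, ds$metadata)
  keys <- paste(cohort$groups$drug_id, cohort$groups$subtype)
  expect_true(all(paste(truth$drug_id, truth$subtype) %in% keys))

  # fractional affected-drug counts round down with a warning
  cfg_frac <- synthetic_config(
    n_genes = 5, n_drugs = 9, n_categories = 1, n_subtypes = 2,
    lines_per_subtype = 12,
    planted = list(planted_effect(gene_name(1), category_name(1),
                                  subtype_name(1), drug_fraction = 0.5,
                                  target_r = 0.5)),
    seed = 3)
  expect_identical(nrow(planted_truth(cfg_frac)), 4L)
  expect_warning(expect_warning(generate_dataset(cfg_frac), "rounded down"),
                 "clipped")
})

test_that("generated files pass every ingest validator and clipping stays modest", {
  ds <- small_dataset(seed = 77)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  expect_no_error({
    read_expression(paths[["expression"]])
    read_drug_response(paths[["response"]])
    read_drug_catalog(paths[["catalog"]])
    read_cell_line_metadata(paths[["metadata"]])
  })
  expect_true(all(ds$response$auc > 0 & ds$response$auc <= 1))
  expect_true(all(ds$expression >= 0))
  # default AUC scales put ~3% of the mass above 1, so the generator warns
  expect_warning(generate_dataset(synthetic_config(n_genes = 5, n_drugs = 10,
                                                   n_categories = 1,
                                                   n_subtypes = 2,
                                                   lines_per_subtype = 15,
                                                   seed = 1)),
                 "clipped")
})
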