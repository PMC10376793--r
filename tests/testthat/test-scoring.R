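# hand-built correlation table covering both directions and an untested
# (drug, subtype) hole; categories catA (2 drugs), catB (1 drug)
toy_cor_table <- function() {
  tidyr::expand_grid(gene = c("TRAP1", "HSPD1"),
                     drug_id = c("D1", "D2", "D3"),
                     subtype = c("S1", "S2")) |>
    dplyr::mutate(
      category = ifelse(.data$drug_id == "D3", "catB", "catA"),
      n = 12,
      z = 0, r = 0, sig_pos = FALSE, sig_neg = FALSE
    ) |>
    dplyr::filter(!(.data$drug_id == "D3" & .data$subtype == "S2"))
}

toy_cat <- tibble::tibble(drug_id = c("D1", "D2", "D3"),
                          drug_name = c("a", "b", "c"),
                          targets = as.list(c("t", "t", "t")),
                          category = c("catA", "catA", "catB"))

test_that("global score implements the exact percentage formula with bounds", {
  tab <- toy_cor_table()
  tab$sig_neg[tab$gene == "TRAP1" & tab$drug_id == "D1"] <- TRUE     # 2 of 2x2 tests
  scores <- score_global(tab, toy_cat, n_subtypes = 2)

  sen <- scores[scores$direction == "sensitivity", ]
  expect_equal(sen$score[sen$gene == "TRAP1" & sen$category == "catA"],
               100 * 2 / (2 * 2))
  # untested (D3, S2) still counts in the denominator
  expect_equal(sen$n_drugs[sen$category == "catB"], c(1L, 1L))
  expect_equal(sen$score[sen$gene == "TRAP1" & sen$category == "catB"], 0)

  # 10 significant of 20 drugs x 5 subtypes -> 10.0
  expect_equal(100 * 10 / (20 * 5), 10.0)
  big <- tidyr::expand_grid(gene = "G", drug_id = sprintf("d%02d", 1:20),
                            subtype = sprintf("s%d", 1:5)) |>
    dplyr::mutate(category = "cat", n = 15, r = -0.5, z = -2,
                  sig_pos = FALSE, sig_neg = FALSE)
  big$sig_neg[seq_len(10)] <- TRUE
  big_cat <- tibble::tibble(drug_id = sprintf("d%02d", 1:20), drug_name = "x",
                            targets = as.list(rep("t", 20)), category = "cat")
  s <- score_global(big, big_cat, n_subtypes = 5)
  expect_equal(s$score[s$direction == "sensitivity"], 10.0)

  # bounds: all significant -> 100, none -> 0
  s_all <- score_global(big |> dplyr::mutate(sig_neg = TRUE), big_cat, 5)
  expect_equal(s_all$score[s_all$direction == "sensitivity"], 100)
  expect_equal(s_all$score[s_all$direction == "resistance"], 0)
  expect_error(score_global(tab, toy_cat, 2, genes = "ABSENT"), "absent")
})

test_that("score significance cutoff is the interpolated tail quantile, strict", {
  expect_equal(score_significance_cutoff(0:99, tail_fraction = 0.05), 94.05)
  expect_equal(score_significance_cutoff(0:99, tail_fraction = 0.5),
               stats::median(0:99))
  expect_warning(score_significance_cutoff(1:5), "unstable")

  # all-equal scores: cutoff equals that value and nothing is significant
  scores <- score_global(toy_cor_table(), toy_cat, 2)
  scores$score <- 7
  flagged <- suppressWarnings(add_score_significance(scores))
  expect_true(all(flagged$score_cutoff == 7))
  expect_false(any(flagged$significant))

  # strict inequality at the threshold itself
  ref <- scores
  ref$score <- rep(c(5, 10), length.out = nrow(ref))
  flagged2 <- suppressWarnings(add_score_significance(ref, tail_fraction = 0.05))
  expect_false(any(flagged2$score == flagged2$score_cutoff & flagged2$significant))
})

test_that("subtype contributions use per-subtype tested denominators and conserve counts", {
  # 16 drugs tested in a subtype, 10 significant -> 62.5%
  tab <- tidyr::expand_grid(gene = "G", drug_id = sprintf("d%02d", 1:16),
                            subtype = "S1") |>
    dplyr::mutate(category = "cat", n = 20, r = -0.4, z = -1,
                  sig_pos = FALSE, sig_neg = FALSE)
  tab$sig_neg[1:10] <- TRUE
  contrib <- subtype_contribution(tab)
  sen <- contrib[contrib$direction == "sensitivity", ]
  expect_equal(sen$percent, 62.5)
  expect_equal(sen$n_drugs_tested, 16L)
  res <- contrib[contrib$direction == "resistance", ]
  expect_equal(res$percent, 0)

  # conservation on a generated instance: sum over subtypes of the
  # per-subtype numerators equals the global numerator, per direction
  ds <- small_dataset(seed = 31, planted = list(planted_effect(
    gene_name(3), category_name(2), subtype_name(1), target_r = 0.65)))
  cohort <- build_cohort(ds$expression, ds$response, ds$catalog, ds$metadata)
  ctab <- correlate_cohort(cohort, ds$expression, ds$response)
  scores <- score_global(ctab, cohort$catalog, cohort$n_subtypes)
  contribs <- subtype_contribution(ctab)
  rollup <- contribs |>
    dplyr::group_by(.data$gene, .data$category, .data$direction) |>
    dplyr::summarise(n_sig = sum(.data$n_sig_subtype), .groups = "drop")
  joined <- dplyr::left_join(scores, rollup,
                             by = c("gene", "category", "direction"),
                             suffix = c("", ".sub"))
  expect_equal(joined$n_sig,
               ifelse(is.na(joined$n_sig.sub), 0L, joined$n_sig.sub))
  # direction exclusivity: one record never feeds both numerators
  expect_false(any(ctab$sig_pos & ctab$sig_neg))
  # the planted resistance effect is visible where it was planted
  planted_pct <- contribs$percent[contribs$gene == gene_name(3) &
                                    contribs$category == category_name(2) &
                                    contribs$direction == "resistance" &
                                    contribs$subtype == subtype_name(1)]
  expect_gt(planted_pct, 50)
})
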