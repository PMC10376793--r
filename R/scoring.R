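#' Global scores per (gene, drug category, direction)
#'
#' Aggregates the correlation table into the global score: for each gene,
#' drug category and direction, the percentage of the category's
#' (drug, subtype) tests whose z-score crossed the cutoff,
#'
#'   score = 100 * n_sig / (n_drugs * n_subtypes),
#'
#' computed separately for sensitivity (negative z, `sig_neg`) and
#' resistance (positive z, `sig_pos`). The denominator is unconditional:
#' every drug of the curated category counts in every subtype, whether or
#' not that (drug, subtype) combination produced a valid correlation, which
#' makes scores conservative for sparsely tested categories.
#'
#' @param cor_table Correlation tibble from [correlate_cohort()].
#' @param catalog Curated drug catalog; supplies each category's drug count.
#' @param n_subtypes Number of cancer subtypes in the cohort
#'   (`cohort$n_subtypes`).
#' @param genes Genes to score; default all genes in `cor_table`.
#'
#' @return A tibble with one row per (gene, category, direction) and columns
#'   `gene`, `category`, `direction` (`"sensitivity"`/`"resistance"`),
#'   `n_sig`, `n_drugs`, `n_subtypes`, `score` (percent in \[0, 100\]).
#' @export
score_global <- function(cor_table, catalog, n_subtypes,
                         genes = unique(cor_table$gene)) {
  stopifnot(n_subtypes >= 1)
  cat_sizes <- catalog |>
    dplyr::count(.data$category, name = "n_drugs")
  missing <- setdiff(genes, unique(cor_table$gene))
  if (length(missing) > 0) {
    stop(sprintf("gene(s) absent from the correlation table: %s",
                 paste(utils::head(missing, 5), collapse = ", ")), call. = FALSE)
  }
  counts <- cor_table |>
    dplyr::filter(.data$gene %in% genes) |>
    dplyr::group_by(.data$gene, .data$category) |>
    dplyr::summarise(sensitivity = sum(.data$sig_neg),
                     resistance = sum(.data$sig_pos), .groups = "drop") |>
    tidyr::pivot_longer(c("sensitivity", "resistance"),
                        names_to = "direction", values_to = "n_sig")

  # full grid: categories with no record for a gene score 0, not NA
  grid <- tidyr::expand_grid(gene = genes,
                             category = cat_sizes$category,
                             direction = c("sensitivity", "resistance"))
  grid |>
    dplyr::left_join(counts, by = c("gene", "category", "direction")) |>
    dplyr::left_join(cat_sizes, by = "category") |>
    dplyr::mutate(n_sig = dplyr::coalesce(.data$n_sig, 0L),
                  n_subtypes = n_subtypes,
                  score = 100 * .data$n_sig / (.data$n_drugs * n_subtypes))
}

#' Score-significance cutoff at a distribution tail
#'
#' The threshold separating remarkable global scores from the bulk: the
#' `(1 - tail_fraction)` quantile (linear-interpolation, type 7) of the
#' score distribution for one direction, normally taken over all genes x
#' categories so that a focused gene panel is judged against the
#' genome-wide background. A score is called significant iff strictly
#' greater than the threshold.
#'
#' @param scores Numeric vector of global scores for one direction.
#' @param tail_fraction Upper-tail fraction (default 0.05).
#'
#' @return A single threshold value. Warns when fewer than 20 scores are
#'   supplied (quantile unstable).
#' @export
score_significance_cutoff <- function(scores, tail_fraction = 0.05) {
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0) stop("no scores supplied", call. = FALSE)
  stopifnot(tail_fraction > 0, tail_fraction < 1)
  if (length(scores) < 20) {
    warning("fewer than 20 scores: tail quantile is unstable", call. = FALSE)
  }
  stats::quantile(scores, probs = 1 - tail_fraction, names = FALSE, type = 7)
}

#' Flag significant global scores
#'
#' Adds per-direction significance calls to a [score_global()] table by
#' computing the tail cutoff within each direction over a reference score
#' distribution (by default the table itself; pass the genome-wide table as
#' `reference` when `scores` is a focused gene panel).
#'
#' @param scores A [score_global()] tibble.
#' @param tail_fraction Upper-tail fraction for the cutoff (default 0.05).
#' @param reference Optional [score_global()] tibble providing the score
#'   distribution the cutoffs are read from.
#'
#' @return `scores` with extra columns `score_cutoff` and `significant`
#'   (`score > score_cutoff`, strict).
#' @export
add_score_significance <- function(scores, tail_fraction = 0.05, reference = scores) {
  cutoffs <- reference |>
    dplyr::group_by(.data$direction) |>
    dplyr::summarise(score_cutoff = score_significance_cutoff(.data$score, tail_fraction),
                     .groups = "drop")
  scores |>
    dplyr::left_join(cutoffs, by = "direction") |>
    dplyr::mutate(significant = .data$score > .data$score_cutoff)
}

#' Per-subtype contribution to global scores
#'
#' Decomposes each (gene, category, direction) global score into the cancer
#' subtypes driving it: for each subtype, the percentage of the category's
#' drugs with a valid correlation in that subtype that carry the matching
#' significance flag. Summing `n_sig_subtype` over subtypes recovers the
#' global score's numerator.
#'
#' @param cor_table Correlation tibble from [correlate_cohort()].
#' @param genes Genes to include; default all genes in the table.
#'
#' @return A tibble with columns `gene`, `category`, `direction`, `subtype`,
#'   `n_sig_subtype`, `n_drugs_tested` (drugs of the category with a valid
#'   correlation for the gene in that subtype), `percent`.
#' @export
subtype_contribution <- function(cor_table, genes = unique(cor_table$gene)) {
  cor_table |>
    dplyr::filter(.data$gene %in% genes) |>
    dplyr::group_by(.data$gene, .data$category, .data$subtype) |>
    dplyr::summarise(n_drugs_tested = sum(!is.na(.data$r)),
                     sensitivity = sum(.data$sig_neg),
                     resistance = sum(.data$sig_pos), .groups = "drop") |>
    tidyr::pivot_longer(c("sensitivity", "resistance"),
                        names_to = "direction", values_to = "n_sig_subtype") |>
    dplyr::mutate(percent = ifelse(.data$n_drugs_tested > 0,
                                   100 * .data$n_sig_subtype / .data$n_drugs_tested,
                                   0)) |>
    dplyr::select("gene", "category", "direction", "subtype",
                  "n_sig_subtype", "n_drugs_tested", "percent") |>
    dplyr::arrange(.data$gene, .data$category, .data$direction, .data$subtype)
}
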