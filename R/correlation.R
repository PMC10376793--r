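#' Sample-size-adjusted Fisher z-transformation
#'
#' Maps a Pearson correlation coefficient to a z-score comparable across
#' groups of different size: `z = atanh(r) * sqrt(n - 3)`. Under the null of
#' no correlation the statistic is approximately standard normal, so a fixed
#' cutoff (here +/-1.7 by default downstream) carries the same tail mass
#' whatever the group size. Perfect correlations are clamped to
#' `1 - 1e-7` in absolute value before `atanh` so tiny groups with exact
#' linear relationships yield a large finite z rather than infinity.
#'
#' @param r Pearson correlation coefficient(s) in `[-1, 1]`; `NA` passes
#'   through.
#' @param n Sample size(s), `>= 4` (the variance-stabilised form needs
#'   `n - 3 > 0`).
#'
#' @return Numeric vector of z-scores; antisymmetric in `r`, strictly
#'   increasing in `|r|` and in `n` for fixed nonzero `r`.
#' @examples
#' fisher_z(0.5, 20)
#' fisher_z(c(-0.3, 0, 0.3), 15)
#' @export
fisher_z <- function(r, n) {
  if (any(n < 4)) stop("fisher_z requires n >= 4", call. = FALSE)
  ok <- !is.na(r)
  if (any(abs(r[ok]) > 1 + 1e-12)) stop("|r| must be <= 1", call. = FALSE)
  eps <- 1e-7
  r_cl <- pmin(pmax(r, -1 + eps), 1 - eps)
  atanh(r_cl) * sqrt(n - 3)
}

#' Per-(gene, drug, subtype) correlation table
#'
#' For every retained (drug, subtype) group in a cohort and every requested
#' gene, computes the Pearson correlation between basal expression and AUC
#' across the group's cell lines, the sqrt(n-3)-scaled Fisher z-score, and
#' two-sided significance flags. A positive z flags a resistance
#' association (higher expression, higher AUC), a negative z a sensitivity
#' association.
#'
#' @param cohort An `analysis_cohort` from [build_cohort()].
#' @param expression Genes x cell lines matrix covering the cohort's lines.
#' @param response Drug-response tibble.
#' @param genes Gene symbols to screen; default all rows of `expression`.
#'   Genes absent from the matrix are reported and skipped.
#' @param z_cutoff Positive significance cutoff on `|z|` (default 1.7).
#'
#' @return A tibble with one row per (gene, drug, subtype) group and columns
#'   `gene`, `drug_id`, `category`, `subtype`, `n`, `r`, `z`, `sig_pos`,
#'   `sig_neg`. Groups where the gene's expression or the AUC has zero
#'   variance keep their row with `r`/`z` set to `NA` and both flags
#'   `FALSE`: the drug was tested, so the record still counts in global
#'   score denominators. The cutoff is stored in attribute `z_cutoff`.
#' @export
correlate_cohort <- function(cohort, expression, response,
                             genes = rownames(expression), z_cutoff = 1.7) {
  stopifnot(inherits(cohort, "analysis_cohort"), z_cutoff > 0)
  missing_genes <- setdiff(genes, rownames(expression))
  if (length(missing_genes) > 0) {
    message(sprintf("correlate_cohort: skipping %d gene(s) absent from the expression matrix: %s",
                    length(missing_genes),
                    paste(utils::head(missing_genes, 5), collapse = ", ")))
    genes <- setdiff(genes, missing_genes)
  }
  if (length(genes) == 0) stop("no requested gene is present in the expression matrix", call. = FALSE)

  auc_lookup <- stats::setNames(response$auc,
                                paste(response$drug_id, response$cell_line_id, sep = "\r"))
  groups <- cohort$groups

  per_group <- purrr::pmap(
    list(groups$drug_id, groups$subtype, groups$category,
         groups$cell_lines, groups$n),
    function(drug, subtype, category, lines, n) {
      auc <- unname(auc_lookup[paste(drug, lines, sep = "\r")])
      em <- expression[genes, lines, drop = FALSE]
      r <- group_pearson(em, auc)
      z <- rep(NA_real_, length(r))
      ok <- !is.na(r)
      if (any(ok)) z[ok] <- fisher_z(r[ok], n)
      tibble::tibble(
        gene = genes, drug_id = drug, category = category, subtype = subtype,
        n = n, r = r, z = z,
        sig_pos = !is.na(z) & z >= z_cutoff,
        sig_neg = !is.na(z) & z <= -z_cutoff
      )
    })
  out <- dplyr::bind_rows(per_group)
  attr(out, "z_cutoff") <- z_cutoff
  out
}

# Pearson r of each row of `em` (genes x lines) against the AUC vector;
# zero-variance rows or a zero-variance AUC yield NA (undefined, not an error).
group_pearson <- function(em, auc) {
  if (stats::sd(auc) == 0) return(rep(NA_real_, nrow(em)))
  r <- suppressWarnings(as.vector(stats::cor(auc, t(em))))
  r[!is.finite(r)] <- NA_real_
  r
}
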