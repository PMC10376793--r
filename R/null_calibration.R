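#' Permutation null distribution of z-scores
#'
#' Builds an empirical null for the z-score by shuffling AUC values across
#' the cell lines of each (drug, subtype) group while leaving expression
#' fixed, then recomputing r and z exactly as [correlate_cohort()] does.
#' This preserves each group's expression structure and AUC marginal while
#' destroying any gene-drug association, so the spread of the resulting
#' z-values is what the significance cutoff should be judged against.
#'
#' @param cohort An `analysis_cohort`.
#' @param expression Genes x cell lines matrix.
#' @param response Drug-response tibble.
#' @param genes Genes to sample; default all rows of `expression`.
#' @param n_perm Permutations per (drug, subtype) group (default 10).
#' @param seed Integer seed; the same seed and inputs reproduce the
#'   distribution exactly.
#'
#' @return An object of class `perm_null`: list with `z` (numeric vector of
#'   null z-scores, one per gene x group x permutation, undefined
#'   correlations dropped), `n_perm`, and `seed`. Warns when fewer than
#'   1000 null values were collected (an empirical cutoff would be
#'   unstable).
#' @export
permutation_null <- function(cohort, expression, response,
                             genes = rownames(expression), n_perm = 10, seed = 1L) {
  stopifnot(inherits(cohort, "analysis_cohort"), n_perm >= 1)
  genes <- intersect(genes, rownames(expression))
  if (length(genes) == 0) stop("no requested gene is present in the expression matrix", call. = FALSE)

  auc_lookup <- stats::setNames(response$auc,
                                paste(response$drug_id, response$cell_line_id, sep = "\r"))
  groups <- cohort$groups
  z_all <- withr::with_seed(seed, {
    purrr::map(seq_len(n_perm), function(p) {
      purrr::pmap(
        list(groups$drug_id, groups$cell_lines, groups$n),
        function(drug, lines, n) {
          auc <- unname(auc_lookup[paste(drug, lines, sep = "\r")])
          em <- expression[genes, lines, drop = FALSE]
          r <- group_pearson(em, sample(auc))
          fisher_z(r[!is.na(r)], n)
        }) |> unlist(use.names = FALSE)
    }) |> unlist(use.names = FALSE)
  })
  if (length(z_all) < 1000) {
    warning(sprintf("only %d null z-values collected; empirical cutoff may be unstable",
                    length(z_all)), call. = FALSE)
  }
  structure(list(z = z_all, n_perm = n_perm, seed = seed), class = "perm_null")
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf("<perm_null> %d null z-values | %d permutation(s) | seed %d\n",
              length(x$z), x$n_perm, x$seed))
  invisible(x)
}

#' Empirical two-sided significance cutoff
#'
#' Reads the cutoff off a null distribution: the `(1 - 2 * tail_mass)`
#' quantile of `|z|`, so that each tail of the null carries `tail_mass`.
#' At the default `tail_mass = 0.0446` a standard-normal null gives a
#' cutoff of about 1.7, the fixed operating cutoff used downstream.
#'
#' @param null A `perm_null` object or a numeric vector of null z-values.
#' @param tail_mass One-sided tail probability, in (0, 0.5); default 0.0446.
#'
#' @return A single positive cutoff value. Warns when the cutoff is 0
#'   (degenerate null).
#' @export
empirical_cutoff <- function(null, tail_mass = 0.0446) {
  z <- if (inherits(null, "perm_null")) null$z else as.numeric(null)
  z <- z[!is.na(z)]
  if (length(z) == 0) stop("empty null distribution", call. = FALSE)
  stopifnot(tail_mass > 0, tail_mass < 0.5)
  cutoff <- stats::quantile(abs(z), probs = 1 - 2 * tail_mass,
                            names = FALSE, type = 7)
  if (cutoff == 0) warning("degenerate null distribution: cutoff is 0", call. = FALSE)
  cutoff
}
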