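#' Configuration for the synthetic CCLE/GDSC-shaped generator
#'
#' Describes a synthetic cell-line panel: a genes x cell lines log2
#' expression matrix, an AUC table for every drug on every line, a drug
#' catalog with categories, and per-subtype metadata, plus a list of
#' planted gene-drug-subtype correlations against which recovery can be
#' judged.
#'
#' Defaults emulate a mid-sized solid-tumour panel: 6 subtypes of 25 lines,
#' 3 drug categories of 20 drugs, AUC resistant-skewed around 0.85 (sd
#' 0.08, GDSC-like), per-gene log2 expression means uniform in \[1, 8\]
#' with sd 1.
#'
#' @param n_genes,n_drugs,n_categories,n_subtypes,lines_per_subtype Panel
#'   dimensions. `n_drugs` is distributed over categories as evenly as
#'   possible; with defaults every category gets at least 10 drugs and every
#'   subtype at least 10 lines, so the cohort filters pass.
#' @param auc_base_mean,auc_base_sd Mean and sd of the unplanted AUC noise.
#' @param expr_mean_range Length-2 range the per-gene expression means are
#'   drawn from (log2 units).
#' @param expr_sd Within-gene expression standard deviation (log2 units).
#' @param planted List of [planted_effect()] objects.
#' @param seed Integer seed making generation fully reproducible.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_genes = 200, n_drugs = 60, n_categories = 3,
                             n_subtypes = 6, lines_per_subtype = 25,
                             auc_base_mean = 0.85, auc_base_sd = 0.08,
                             expr_mean_range = c(1, 8), expr_sd = 1,
                             planted = list(), seed = 1L) {
  stopifnot(n_genes >= 1, n_drugs >= 1, n_categories >= 1,
            n_subtypes >= 1, lines_per_subtype >= 3,
            auc_base_sd > 0, expr_sd > 0,
            length(expr_mean_range) == 2, diff(expr_mean_range) >= 0)
  if (length(planted) > 0 && !all(vapply(planted, inherits, TRUE, "planted_effect"))) {
    stop("planted must be a list of planted_effect() objects", call. = FALSE)
  }
  cfg <- structure(
    list(n_genes = as.integer(n_genes), n_drugs = as.integer(n_drugs),
         n_categories = as.integer(n_categories),
         n_subtypes = as.integer(n_subtypes),
         lines_per_subtype = as.integer(lines_per_subtype),
         auc_base_mean = auc_base_mean, auc_base_sd = auc_base_sd,
         expr_mean_range = expr_mean_range, expr_sd = expr_sd,
         planted = planted, seed = as.integer(seed)),
    class = "synthetic_config")
  lab <- synthetic_labels(cfg)
  for (pe in planted) {
    if (!pe$gene %in% lab$genes) {
      stop(sprintf("planted gene '%s' is not a generated gene name (use gene_name(i))", pe$gene),
           call. = FALSE)
    }
    if (!pe$category %in% lab$categories) {
      stop(sprintf("planted category '%s' is not a generated category", pe$category),
           call. = FALSE)
    }
    if (!all(pe$subtypes %in% lab$subtypes)) {
      stop("planted subtypes must be generated subtype names", call. = FALSE)
    }
  }
  cfg
}

#' A planted gene-drug-subtype association
#'
#' Declares that one gene's expression should correlate (population
#' Pearson coefficient `target_r`) with the AUC of a fraction of one
#' category's drugs, in a chosen set of subtypes. Negative `target_r`
#' plants a sensitivity association (high expression, low AUC), positive a
#' resistance association.
#'
#' @param gene Generated gene name (see [gene_name()]).
#' @param category Generated category name (see [category_name()]).
#' @param subtypes Character vector of generated subtype names.
#' @param drug_fraction Fraction of the category's drugs affected, in
#'   (0, 1]; a fractional drug count is rounded down (with a warning at
#'   generation time).
#' @param target_r Population correlation in (-1, 1), nonzero.
#'
#' @return An object of class `planted_effect`.
#' @export
planted_effect <- function(gene, category, subtypes, drug_fraction = 1, target_r) {
  stopifnot(abs(target_r) < 1, target_r != 0,
            drug_fraction > 0, drug_fraction <= 1, length(subtypes) >= 1)
  structure(list(gene = gene, category = category,
                 subtypes = as.character(subtypes),
                 drug_fraction = drug_fraction, target_r = target_r),
            class = "planted_effect")
}

#' @rdname synthetic_label_helpers
#' @export
gene_name <- function(i) sprintf("GENE%04d", as.integer(i))

#' @rdname synthetic_label_helpers
#' @export
category_name <- function(i) sprintf("category%02d", as.integer(i))

#' Deterministic label helpers for synthetic datasets
#'
#' The generator names genes `GENE0001...`, categories `category01...`,
#' subtypes `subtype01...` (each belonging to tissue `tissue01...`), cell
#' lines `CL00001...`, drugs `D0001...`. These helpers build the names so
#' planted effects can reference them without generating first.
#'
#' @param i Integer index.
#' @return A character label.
#' @name synthetic_label_helpers
#' @export
subtype_name <- function(i) sprintf("subtype%02d", as.integer(i))

# all deterministic labels and the drug -> category assignment
synthetic_labels <- function(config) {
  genes <- gene_name(seq_len(config$n_genes))
  drugs <- sprintf("D%04d", seq_len(config$n_drugs))
  categories <- category_name(seq_len(config$n_categories))
  # block assignment, as even as possible
  drug_category <- categories[ceiling(seq_len(config$n_drugs) /
                                        ceiling(config$n_drugs / config$n_categories))]
  subtypes <- subtype_name(seq_len(config$n_subtypes))
  tissues <- sprintf("tissue%02d", seq_len(config$n_subtypes))
  lines <- sprintf("CL%05d", seq_len(config$n_subtypes * config$lines_per_subtype))
  line_subtype <- rep(subtypes, each = config$lines_per_subtype)
  list(genes = genes, drugs = drugs, categories = categories,
       drug_category = drug_category, subtypes = subtypes, tissues = tissues,
       lines = lines, line_subtype = line_subtype)
}

# drugs affected by a planted effect: the first floor(fraction * size) of the
# category block, deterministic so planted_truth() needs no RNG
affected_drugs <- function(labels, effect, warn = FALSE) {
  in_cat <- labels$drugs[labels$drug_category == effect$category]
  k_exact <- effect$drug_fraction * length(in_cat)
  k <- floor(k_exact + 1e-9)
  if (warn && abs(k_exact - k) > 1e-9) {
    warning(sprintf("drug_fraction %.3f of %d drugs rounded down to %d affected drugs",
                    effect$drug_fraction, length(in_cat), k), call. = FALSE)
  }
  utils::head(in_cat, k)
}

#' Generate a synthetic CCLE/GDSC-shaped dataset
#'
#' Draws log2 expression as Normal(per-gene mean, `expr_sd`) truncated at
#' 0 and AUC as Normal(`auc_base_mean`, `auc_base_sd`) clipped to (0, 1].
#' For each planted effect, the affected drugs' AUC in the affected
#' subtypes is built as a linear blend of the standardised gene signal and
#' independent noise — weight `target_r` on the signal and
#' `sqrt(1 - target_r^2)` on the noise — so the population correlation
#' equals `target_r` before clipping. Clipping that touches 1% or more of
#' the AUC values triggers a warning, since heavy clipping attenuates
#' planted correlations.
#'
#' @param config A [synthetic_config()].
#'
#' @return An object of class `synthetic_dataset`: list with `expression`
#'   (matrix), `response`, `catalog`, `metadata` (tibbles in the ingest
#'   dialect), and the `config`. Byte-identical across calls with the same
#'   config.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  lab <- synthetic_labels(config)
  withr::with_seed(config$seed, {
    gene_means <- stats::runif(config$n_genes,
                               config$expr_mean_range[1], config$expr_mean_range[2])
    n_lines <- length(lab$lines)
    expr <- matrix(stats::rnorm(config$n_genes * n_lines,
                                mean = gene_means, sd = config$expr_sd),
                   nrow = config$n_genes, ncol = n_lines,
                   dimnames = list(lab$genes, lab$lines))
    expr <- pmax(expr, 0)

    # AUC noise field, drugs x lines; planted cells replace the noise by the
    # signal/noise blend on the same standardised scale
    auc <- matrix(stats::rnorm(config$n_drugs * n_lines), nrow = config$n_drugs,
                  dimnames = list(lab$drugs, lab$lines))
    for (pe in config$planted) {
      drugs <- affected_drugs(lab, pe, warn = TRUE)
      cols <- lab$lines[lab$line_subtype %in% pe$subtypes]
      if (length(drugs) == 0 || length(cols) == 0) next
      zg <- (expr[pe$gene, cols] - gene_means[match(pe$gene, lab$genes)]) / config$expr_sd
      for (d in drugs) {
        eps <- stats::rnorm(length(cols))
        auc[d, cols] <- pe$target_r * zg + sqrt(1 - pe$target_r^2) * eps
      }
    }
    auc <- config$auc_base_mean + config$auc_base_sd * auc
    clipped <- mean(auc > 1 | auc <= 0)
    if (clipped >= 0.01) {
      warning(sprintf("%.1f%% of AUC values clipped to (0, 1]; planted correlations may be attenuated",
                      100 * clipped), call. = FALSE)
    }
    auc <- pmin(pmax(auc, 1e-6), 1)

    response <- tibble::tibble(
      drug_id = rep(lab$drugs, times = n_lines),
      cell_line_id = rep(lab$lines, each = config$n_drugs),
      auc = as.vector(auc)
    )
    catalog <- tibble::tibble(
      drug_id = lab$drugs,
      drug_name = paste0("drug_", tolower(lab$drugs)),
      targets = lapply(lab$drug_category, function(ct) paste0("target_", ct)),
      category = lab$drug_category
    )
    metadata <- tibble::tibble(
      cell_line_id = lab$lines,
      tissue = rep(lab$tissues, each = config$lines_per_subtype),
      subtype = lab$line_subtype
    )
    structure(list(expression = expr, response = response,
                   catalog = catalog, metadata = metadata, config = config),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d genes x %d cell lines | %d drugs in %d categories | %d subtypes | %d planted effect(s)\n",
              nrow(x$expression), ncol(x$expression),
              x$config$n_drugs, x$config$n_categories, x$config$n_subtypes,
              length(x$config$planted)))
  invisible(x)
}

#' Ground truth of planted associations
#'
#' Enumerates every (gene, drug, subtype) combination a config's planted
#' effects touch, with the expected correlation sign, for use as recovery
#' ground truth. Purely deterministic in the config (no generation needed).
#'
#' @param config A [synthetic_config()].
#'
#' @return A tibble with columns `gene`, `drug_id`, `subtype`, `sign`
#'   (`-1` sensitivity, `+1` resistance), `target_r`; zero rows when
#'   nothing is planted.
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  lab <- synthetic_labels(config)
  rows <- purrr::map(config$planted, function(pe) {
    drugs <- affected_drugs(lab, pe)
    tidyr::expand_grid(gene = pe$gene, drug_id = drugs, subtype = pe$subtypes) |>
      dplyr::mutate(sign = sign(pe$target_r), target_r = pe$target_r)
  })
  if (length(rows) == 0) {
    return(tibble::tibble(gene = character(), drug_id = character(),
                          subtype = character(), sign = numeric(),
                          target_r = numeric()))
  }
  dplyr::bind_rows(rows)
}

#' Write a synthetic dataset as the four canonical CSV inputs
#'
#' Emits `expression.csv` (genes in rows, `gene_id` first column),
#' `drug_response.csv`, `drug_catalog.csv` (targets `;`-joined) and
#' `cell_line_metadata.csv` in the dialect the `read_*` ingest functions
#' accept, so generated data round-trips through the full pipeline.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#'
#' @return Invisibly, the four file paths (named).
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.csv"),
             response = file.path(dir, "drug_response.csv"),
             catalog = file.path(dir, "drug_catalog.csv"),
             metadata = file.path(dir, "cell_line_metadata.csv"))
  expr_df <- tibble::as_tibble(dataset$expression, rownames = "gene_id")
  readr::write_csv(expr_df, paths["expression"])
  readr::write_csv(dataset$response, paths["response"])
  cat_df <- dataset$catalog
  cat_df$targets <- vapply(cat_df$targets, paste, "", collapse = ";")
  readr::write_csv(cat_df, paths["catalog"])
  readr::write_csv(dataset$metadata, paths["metadata"])
  invisible(paths)
}
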