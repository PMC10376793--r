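#' Default pipeline configuration
#'
#' Every operating constant of the screen in one place: the z-score cutoff
#' (1.7), the minimum drugs per category (10) and cell lines per
#' (drug, subtype) group (10), the excluded tissues (blood, bone, soft
#' tissue), the category merges, the score-distribution tail (0.05), and
#' the optional permutation-calibration settings. Override any entry via
#' `...` or by editing the returned list.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    genes = "all",                     # or a character vector of symbols
    z_cutoff = 1.7,
    min_drugs_per_category = 10,
    min_lines_per_group = 10,
    excluded_tissues = c("blood", "bone", "soft tissue"),
    category_merges = default_category_merges(),
    score_tail_fraction = 0.05,
    calibrate = FALSE,                 # re-derive the z cutoff from permutations
    n_perm = 10,
    tail_mass = 0.0446,
    seed = 1L,
    expression_genes_in = "rows",
    inputs = NULL,                     # named paths: expression, response, catalog, metadata
    out_dir = NULL
  )
  overrides <- list(...)
  if (length(overrides) > 0) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown) > 0) {
      stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
           call. = FALSE)
    }
    cfg[names(overrides)] <- overrides
  }
  cfg
}

#' Run the drug-gene screen on in-memory inputs
#'
#' Executes the full analysis on already-parsed inputs: curates the drug
#' catalog (merges, size filter), excludes tissues, builds the
#' (drug, subtype) cohort, computes the correlation table, aggregates
#' global scores with genome-wide significance cutoffs, and decomposes
#' per-subtype contributions. The genome-wide score distribution (all
#' genes in the expression matrix) always provides the score cutoff, even
#' when `genes` restricts reporting to a panel such as the mitochondrial
#' chaperones.
#'
#' @param expression Genes x cell lines matrix.
#' @param response Drug-response tibble.
#' @param catalog Drug catalog tibble (uncurated).
#' @param metadata Cell-line metadata tibble.
#' @param config A [default_config()] list (or overrides via `...`).
#' @param ... Convenience overrides forwarded to [default_config()] when
#'   `config` is not supplied.
#'
#' @return An object of class `screen_result`: list with `correlations`,
#'   `scores` (significance-flagged, restricted to the requested genes),
#'   `contributions`, `cohort`, `z_cutoff`, `score_cutoffs`, `config`.
#' @export
run_screen <- function(expression, response, catalog, metadata,
                       config = default_config(...), ...) {
  catalog <- catalog |>
    merge_drug_categories(config$category_merges) |>
    filter_drug_categories(min_drugs = config$min_drugs_per_category)
  metadata <- exclude_tissues(metadata, config$excluded_tissues)
  cohort <- build_cohort(expression, response, catalog, metadata,
                         min_lines = config$min_lines_per_group)

  z_cutoff <- config$z_cutoff
  calibration <- NULL
  if (isTRUE(config$calibrate)) {
    calibration <- permutation_null(cohort, expression, response,
                                    n_perm = config$n_perm, seed = config$seed)
    z_cutoff <- empirical_cutoff(calibration, config$tail_mass)
  }

  cor_table <- correlate_cohort(cohort, expression, response,
                                genes = rownames(expression),
                                z_cutoff = z_cutoff)
  all_scores <- score_global(cor_table, cohort$catalog, cohort$n_subtypes) |>
    add_score_significance(config$score_tail_fraction)
  score_cutoffs <- all_scores |>
    dplyr::distinct(.data$direction, .data$score_cutoff)

  genes <- config$genes
  if (identical(genes, "all")) genes <- rownames(expression)
  genes <- intersect(toupper(genes), unique(cor_table$gene))
  if (length(genes) == 0) stop("none of the requested genes survived the screen", call. = FALSE)

  structure(
    list(correlations = cor_table[cor_table$gene %in% genes, ],
         scores = all_scores[all_scores$gene %in% genes, ],
         contributions = subtype_contribution(cor_table, genes = genes),
         cohort = cohort,
         z_cutoff = z_cutoff,
         score_cutoffs = score_cutoffs,
         calibration = calibration,
         config = config),
    class = "screen_result"
  )
}

#' Run the pipeline from a configuration (files in, files out)
#'
#' Reads the four inputs named in `config$inputs`, runs [run_screen()],
#' and, when `config$out_dir` is set, writes the correlation table, the
#' per-direction score tables, the subtype contributions, the report
#' figures with their TSV twins, a copy of the configuration, and a run
#' manifest (row counts and thresholds). Identical config and inputs give
#' identical numeric outputs.
#'
#' @param config A [default_config()] list with `inputs` set, or the path
#'   to a YAML file holding one.
#' @param plots Render report images (default `TRUE`); the TSVs are always
#'   written.
#'
#' @return The `screen_result`, invisibly, with a `manifest` element
#'   attached when outputs were written.
#' @export
run_pipeline <- function(config, plots = TRUE) {
  if (is.character(config) && length(config) == 1) config <- read_config(config)
  base <- default_config()
  missing <- setdiff(names(base), names(config))
  config <- c(config, base[missing])
  inputs <- config$inputs
  if (is.null(inputs) || !all(c("expression", "response", "catalog", "metadata") %in% names(inputs))) {
    stop("config$inputs must name the expression, response, catalog and metadata files",
         call. = FALSE)
  }
  for (p in unlist(inputs)) {
    if (!file.exists(p)) stop(sprintf("input file not found: %s", p), call. = FALSE)
  }
  expression <- read_expression(inputs$expression, genes_in = config$expression_genes_in)
  response <- read_drug_response(inputs$response)
  catalog <- read_drug_catalog(inputs$catalog)
  metadata <- read_cell_line_metadata(inputs$metadata)

  result <- run_screen(expression, response, catalog, metadata, config = config)

  if (!is.null(config$out_dir)) {
    out <- config$out_dir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      correlations = file.path(out, "correlations.tsv"),
      scores_sensitivity = file.path(out, "scores_sensitivity.tsv"),
      scores_resistance = file.path(out, "scores_resistance.tsv"),
      contributions = file.path(out, "subtype_contributions.tsv"),
      config = file.path(out, "config.yaml")
    )
    readr::write_tsv(result$correlations, files["correlations"])
    readr::write_tsv(result$scores[result$scores$direction == "sensitivity", ],
                     files["scores_sensitivity"])
    readr::write_tsv(result$scores[result$scores$direction == "resistance", ],
                     files["scores_resistance"])
    readr::write_tsv(result$contributions, files["contributions"])
    yaml::write_yaml(serialisable_config(config), files["config"])
    report_files <- render_reports(result, out, plots = plots)
    manifest <- list(
      files = as.list(unname(c(files, report_files))),
      n_correlation_records = nrow(result$correlations),
      n_scores = nrow(result$scores),
      n_contributions = nrow(result$contributions),
      n_groups = nrow(result$cohort$groups),
      n_subtypes = result$cohort$n_subtypes,
      z_cutoff = result$z_cutoff,
      score_cutoffs = stats::setNames(as.list(result$score_cutoffs$score_cutoff),
                                      result$score_cutoffs$direction)
    )
    yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
    result$manifest <- manifest
  }
  invisible(result)
}

read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$category_merges)) {
    cfg$category_merges <- tibble::as_tibble(cfg$category_merges)
  }
  cfg
}

serialisable_config <- function(config) {
  config$category_merges <- as.list(config$category_merges)
  config
}

#' @export
print.screen_result <- function(x, ...) {
  nsig <- sum(x$scores$significant)
  cat(sprintf("<screen_result> %d gene(s) x %d categories | %d correlation records | z cutoff %.3g | %d significant score(s)\n",
              dplyr::n_distinct(x$scores$gene),
              dplyr::n_distinct(x$scores$category),
              nrow(x$correlations), x$z_cutoff, nsig))
  invisible(x)
}

#' Tidy a screen result
#'
#' @param x A `screen_result`.
#' @param type Which table to return: `"scores"` (default),
#'   `"correlations"`, or `"contributions"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.screen_result <- function(x, type = c("scores", "correlations", "contributions"), ...) {
  type <- match.arg(type)
  tibble::as_tibble(x[[type]])
}

#' One-row summary of a screen result
#'
#' @param x A `screen_result`.
#' @param ... Unused.
#' @return A one-row tibble with panel dimensions, the cutoffs in force,
#'   and the number of significant scores.
#' @export
glance.screen_result <- function(x, ...) {
  sc <- stats::setNames(x$score_cutoffs$score_cutoff, x$score_cutoffs$direction)
  tibble::tibble(
    n_genes = dplyr::n_distinct(x$scores$gene),
    n_drugs = dplyr::n_distinct(x$cohort$groups$drug_id),
    n_categories = dplyr::n_distinct(x$cohort$catalog$category),
    n_subtypes = x$cohort$n_subtypes,
    n_groups = nrow(x$cohort$groups),
    z_cutoff = x$z_cutoff,
    score_cutoff_sensitivity = unname(sc["sensitivity"]),
    score_cutoff_resistance = unname(sc["resistance"]),
    n_significant_scores = sum(x$scores$significant)
  )
}

#' Autoplot a screen result
#'
#' @param object A `screen_result`.
#' @param gene Gene to plot; defaults to the gene with the largest
#'   significant score.
#' @param type `"bar"` (bi-directional score chart, default) or `"bubble"`.
#' @param direction For `type = "bubble"`, which direction to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screen_result <- function(object, gene = NULL,
                                   type = c("bar", "bubble"),
                                   direction = "sensitivity", ...) {
  type <- match.arg(type)
  if (is.null(gene)) {
    gene <- object$scores$gene[order(-object$scores$score)][1]
  }
  switch(type,
         bar = plot_score_bar(object$scores, gene),
         bubble = plot_contribution_bubble(object$contributions, gene, direction))
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
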