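#' Hierarchical ordering of a labelled score or z-score matrix
#'
#' Clusters the rows and columns of a numeric matrix independently by
#' agglomerative hierarchical clustering (Euclidean distance, unweighted
#' average linkage / UPGMA by default — the common clustermap defaults) and
#' returns the resulting leaf orders and merge trees. Missing cells are
#' replaced by `fill_missing` for the distance computation only: a missing
#' z (drug untested in a subtype) is treated as "no evidence", not dropped,
#' so the full subtype roster stays in the picture. Rows and columns that
#' are entirely missing are dropped first. Labels are sorted before
#' clustering, so the result does not depend on the input row/column order
#' (ties break by label order).
#'
#' @param mat Labelled numeric matrix with at least 2 rows and 2 columns
#'   after dropping all-missing rows/columns.
#' @param fill_missing Value substituted for `NA` in distance computation
#'   (default 0).
#' @param metric Distance metric passed to [stats::dist()] (default
#'   `"euclidean"`).
#' @param linkage Agglomeration method passed to [stats::hclust()] (default
#'   `"average"`).
#'
#' @return An object of class `cluster_result`: list with `row_order` and
#'   `col_order` (label permutations) and `row_linkage`, `col_linkage`
#'   (`hclust` trees).
#' @export
hierarchical_order <- function(mat, fill_missing = 0,
                               metric = "euclidean", linkage = "average") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  mat <- mat[rowSums(!is.na(mat)) > 0, colSums(!is.na(mat)) > 0, drop = FALSE]
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    stop("need at least 2 rows and 2 columns with data to cluster", call. = FALSE)
  }
  mat <- mat[order(rownames(mat)), order(colnames(mat)), drop = FALSE]
  mat[is.na(mat)] <- fill_missing
  hc_row <- stats::hclust(stats::dist(mat, method = metric), method = linkage)
  hc_col <- stats::hclust(stats::dist(t(mat), method = metric), method = linkage)
  structure(
    list(row_order = rownames(mat)[hc_row$order],
         col_order = colnames(mat)[hc_col$order],
         row_linkage = hc_row, col_linkage = hc_col),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d rows x %d cols\n",
              length(x$row_order), length(x$col_order)))
  invisible(x)
}

#' Wide z-score matrix for one (gene, category)
#'
#' Pivots the correlation table into a drugs x subtypes matrix of z-scores
#' for a single gene and drug category, the input to the per-category
#' clustermaps.
#'
#' @param cor_table Correlation tibble from [correlate_cohort()].
#' @param gene,category The (gene, category) slice to extract.
#'
#' @return Numeric matrix, drugs in rows, subtypes in columns; untested
#'   combinations are `NA`.
#' @export
z_matrix <- function(cor_table, gene, category) {
  slice <- cor_table[cor_table$gene == gene & cor_table$category == category, ]
  if (nrow(slice) == 0) {
    stop(sprintf("no records for gene '%s' in category '%s'", gene, category),
         call. = FALSE)
  }
  wide <- slice |>
    dplyr::select("drug_id", "subtype", "z") |>
    tidyr::pivot_wider(names_from = "subtype", values_from = "z")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$drug_id
  m
}

#' Bi-directional global-score bar chart for one gene
#'
#' Sensitivity scores extend left (negative axis, blue), resistance scores
#' right (red), one bar pair per drug category, with dotted lines at the
#' per-direction significance cutoffs when present.
#'
#' @param scores A [score_global()] tibble, ideally after
#'   [add_score_significance()].
#' @param gene Gene to plot.
#'
#' @return A ggplot object.
#' @export
plot_score_bar <- function(scores, gene) {
  df <- scores[scores$gene == gene, ]
  if (nrow(df) == 0) stop(sprintf("gene '%s' not in the score table", gene), call. = FALSE)
  df$signed <- ifelse(df$direction == "sensitivity", -df$score, df$score)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$signed, y = .data$category,
                                        fill = .data$direction)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(sensitivity = "#2166AC", resistance = "#B2182B")) +
    ggplot2::scale_x_continuous(labels = function(x) abs(x)) +
    ggplot2::labs(x = "Score_global (% significant tests)", y = NULL,
                  title = gene,
                  subtitle = "sensitivity (left) / resistance (right)") +
    ggplot2::theme_minimal()
  if ("score_cutoff" %in% names(df)) {
    cuts <- unique(df[c("direction", "score_cutoff")])
    cuts$x <- ifelse(cuts$direction == "sensitivity", -cuts$score_cutoff, cuts$score_cutoff)
    p <- p + ggplot2::geom_vline(data = cuts, ggplot2::aes(xintercept = .data$x),
                                 linetype = "dotted")
  }
  p
}

#' Subtype-contribution bubble plot
#'
#' For one gene and direction, shows which cancer subtypes drive each drug
#' category's global score: bubble area is the percentage of the category's
#' tested drugs significant in that subtype.
#'
#' @param contributions A [subtype_contribution()] tibble.
#' @param gene Gene to plot.
#' @param direction `"sensitivity"` or `"resistance"`.
#'
#' @return A ggplot object.
#' @export
plot_contribution_bubble <- function(contributions, gene,
                                     direction = c("sensitivity", "resistance")) {
  direction <- match.arg(direction)
  df <- contributions[contributions$gene == gene &
                        contributions$direction == direction, ]
  if (nrow(df) == 0) stop(sprintf("no contributions for gene '%s'", gene), call. = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$subtype,
                                   size = .data$percent,
                                   colour = .data$percent)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 10, limits = c(0, 100)) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 100)) +
    ggplot2::labs(title = sprintf("%s - %s", gene, direction),
                  x = NULL, y = NULL, size = "% drugs", colour = "% drugs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Clustered z-score heatmap for one (gene, category)
#'
#' Tile heatmap of the drugs x subtypes z-score matrix with rows and
#' columns ordered by [hierarchical_order()].
#'
#' @param cor_table Correlation tibble.
#' @param gene,category The slice to plot.
#' @param fill_missing Fill for untested combinations during clustering
#'   (default 0); tiles themselves stay blank.
#'
#' @return A ggplot object, or `NULL` (with a message) when the slice is
#'   too small to cluster.
#' @export
plot_z_clustermap <- function(cor_table, gene, category, fill_missing = 0) {
  m <- z_matrix(cor_table, gene, category)
  cl <- tryCatch(hierarchical_order(m, fill_missing = fill_missing),
                 error = function(e) NULL)
  if (is.null(cl)) {
    message(sprintf("z matrix for %s / %s too small to cluster; skipping", gene, category))
    return(invisible(NULL))
  }
  df <- as.data.frame(as.table(m), stringsAsFactors = FALSE)
  names(df) <- c("drug_id", "subtype", "z")
  df$drug_id <- factor(df$drug_id, levels = cl$row_order)
  df$subtype <- factor(df$subtype, levels = cl$col_order)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subtype, y = .data$drug_id,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                                  na.value = "grey90") +
    ggplot2::labs(title = sprintf("%s - %s", gene, category),
                  x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write report figures and their data tables
#'
#' Emits the standard report set for a screen: one bi-directional bar chart
#' per gene, one bubble plot per (gene, direction), and one clustermap per
#' (gene, category) with a significant score, each image accompanied by a
#' TSV holding exactly the plotted numbers.
#'
#' @param result A `screen_result` from [run_screen()] or [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @param genes Genes to report on; default every gene in the result.
#' @param plots If `FALSE`, write only the TSVs.
#' @param width,height,dpi Passed to [ggplot2::ggsave()].
#'
#' @return Invisibly, a character vector of the files written.
#' @export
render_reports <- function(result, out_dir, genes = NULL, plots = TRUE,
                           width = 7, height = 5, dpi = 150) {
  stopifnot(inherits(result, "screen_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(genes)) genes <- unique(result$scores$gene)
  files <- character(0)
  emit <- function(plot, stem, data) {
    tsv <- file.path(out_dir, paste0(stem, ".tsv"))
    readr::write_tsv(data, tsv)
    files <<- c(files, tsv)
    if (plots && !is.null(plot)) {
      png <- file.path(out_dir, paste0(stem, ".png"))
      ggplot2::ggsave(png, plot, width = width, height = height, dpi = dpi)
      files <<- c(files, png)
    }
  }
  for (g in genes) {
    emit(plot_score_bar(result$scores, g), paste0("score_bar_", sanitise(g)),
         result$scores[result$scores$gene == g, ])
    for (dir_ in c("sensitivity", "resistance")) {
      contrib <- result$contributions[result$contributions$gene == g &
                                        result$contributions$direction == dir_, ]
      if (nrow(contrib) == 0) next
      emit(plot_contribution_bubble(result$contributions, g, dir_),
           sprintf("bubble_%s_%s", sanitise(g), dir_), contrib)
    }
    sig <- result$scores[result$scores$gene == g & result$scores$significant, ]
    for (cat_ in unique(sig$category)) {
      slice <- result$correlations[result$correlations$gene == g &
                                     result$correlations$category == cat_, ]
      if (nrow(slice) == 0) next
      emit(plot_z_clustermap(result$correlations, g, cat_),
           sprintf("clustermap_%s_%s", sanitise(g), sanitise(cat_)),
           slice[c("drug_id", "subtype", "n", "r", "z", "sig_pos", "sig_neg")])
    }
  }
  invisible(files)
}

sanitise <- function(x) gsub("[^A-Za-z0-9_.-]+", "_", x)
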