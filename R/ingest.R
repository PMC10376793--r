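#' Read a gene-expression matrix
#'
#' Parses a CSV/TSV of basal log2-scale expression values (CCLE/DepMap-style)
#' into a genes x cell lines numeric matrix. Gene symbols are normalised to
#' upper case and cell-line identifiers stripped of surrounding whitespace;
#' beyond that, identifiers are never renamed or reordered.
#'
#' @param path Path to a delimited file. The first column (or first row when
#'   `genes_in = "cols"`) carries identifiers.
#' @param genes_in Orientation of the file: `"rows"` (default; one row per
#'   gene) or `"cols"` (one column per gene, as in DepMap portal exports).
#' @param delim Field delimiter; `NULL` (default) auto-detects from the file
#'   extension (`.tsv`/`.txt` gives tab, otherwise comma).
#'
#' @return A numeric matrix, genes in rows and cell lines in columns, with
#'   all values finite and non-negative (log2(TPM+1) convention).
#'
#' @details Duplicated gene symbols or cell-line identifiers, non-numeric
#'   cells, and negative or non-finite values are hard errors that name the
#'   offending identifier or cell position; the parser never drops or
#'   deduplicates silently.
#'
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(gene_id = c("TRAP1", "HSPD1"),
#'                      CL1 = c(5.2, 3.1), CL2 = c(4.8, 2.9)),
#'           tf, row.names = FALSE)
#' expr <- read_expression(tf)
#' dim(expr)
#' @export
read_expression <- function(path, genes_in = c("rows", "cols"), delim = NULL) {
  genes_in <- match.arg(genes_in)
  df <- read_delimited(path, delim)
  if (ncol(df) < 2) {
    stop("expression file needs an identifier column plus at least one value column", call. = FALSE)
  }
  ids <- trimws(as.character(df[[1]]))
  other <- trimws(names(df)[-1])

  vals <- df[-1]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad) > 0) {
        stop(sprintf("non-numeric expression value %s at row %d, column '%s'",
                     dQuote(col[bad[1]]), bad[1], names(vals)[j]), call. = FALSE)
      }
      vals[[j]] <- num
    }
  }
  mat <- as.matrix(vals)
  rownames(mat) <- ids
  colnames(mat) <- other
  if (genes_in == "cols") mat <- t(mat)

  rownames(mat) <- toupper(trimws(rownames(mat)))
  colnames(mat) <- trimws(colnames(mat))

  check_unique(rownames(mat), "gene symbol")
  check_unique(colnames(mat), "cell-line identifier")
  if (anyNA(mat) || any(!is.finite(mat))) {
    stop("expression matrix contains missing or non-finite values", call. = FALSE)
  }
  if (any(mat < 0)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative expression value for gene '%s', cell line '%s' (log2(TPM+1) values must be >= 0)",
                 rownames(mat)[bad[1]], colnames(mat)[bad[2]]), call. = FALSE)
  }
  mat
}

#' Read a drug-response table
#'
#' Parses a long-format table of area-under-dose-response-curve (AUC) values,
#' one row per (drug, cell line) pair, GDSC-style. Higher AUC means more
#' resistant. Rows with a missing AUC are dropped with a message reporting
#' the count; out-of-range AUC values and duplicate (drug, cell line) pairs
#' are hard errors.
#'
#' @param path Path to a delimited file.
#' @param drug_col,cell_line_col,auc_col Column names in the file holding the
#'   drug identifier, cell-line identifier and AUC value. Defaults match the
#'   canonical dialect written by [write_dataset()].
#' @param delim Field delimiter; `NULL` auto-detects (see [read_expression()]).
#'
#' @return A tibble with columns `drug_id`, `cell_line_id`, `auc`, where
#'   `auc` is finite and in (0, 1].
#' @export
read_drug_response <- function(path, drug_col = "drug_id",
                               cell_line_col = "cell_line_id",
                               auc_col = "auc", delim = NULL) {
  df <- read_delimited(path, delim)
  require_columns(df, c(drug_col, cell_line_col, auc_col), "drug-response table")
  out <- tibble::tibble(
    drug_id = trimws(as.character(df[[drug_col]])),
    cell_line_id = trimws(as.character(df[[cell_line_col]])),
    auc = as.numeric(df[[auc_col]])
  )
  n_missing <- sum(is.na(out$auc))
  if (n_missing > 0) {
    message(sprintf("read_drug_response: dropped %d row(s) with missing AUC", n_missing))
    out <- out[!is.na(out$auc), ]
  }
  if (any(!is.finite(out$auc) | out$auc <= 0 | out$auc > 1)) {
    bad <- out$auc[!is.finite(out$auc) | out$auc <= 0 | out$auc > 1][1]
    stop(sprintf("AUC value %g outside (0, 1]", bad), call. = FALSE)
  }
  dup <- duplicated(out[c("drug_id", "cell_line_id")])
  if (any(dup)) {
    stop(sprintf("duplicate (drug, cell line) record: ('%s', '%s')",
                 out$drug_id[dup][1], out$cell_line_id[dup][1]), call. = FALSE)
  }
  out
}

#' Read a drug catalog
#'
#' Parses drug annotations: identifier, name, nominal target(s), and the
#' curated target-pathway category used to group drugs for global scoring.
#'
#' @param path Path to a delimited file with columns `drug_id`, `drug_name`,
#'   `targets` (`;`-separated list), `category`. Unknown extra columns are
#'   ignored with a warning.
#' @param delim Field delimiter; `NULL` auto-detects.
#'
#' @return A tibble with columns `drug_id`, `drug_name`, `targets` (list
#'   column of character vectors), `category`. `drug_id` is unique.
#' @export
read_drug_catalog <- function(path, delim = NULL) {
  df <- read_delimited(path, delim)
  wanted <- c("drug_id", "drug_name", "targets", "category")
  require_columns(df, wanted, "drug catalog")
  extra <- setdiff(names(df), wanted)
  if (length(extra) > 0) {
    warning(sprintf("read_drug_catalog: ignoring extra column(s): %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  out <- tibble::tibble(
    drug_id = trimws(as.character(df$drug_id)),
    drug_name = as.character(df$drug_name),
    targets = lapply(strsplit(as.character(df$targets), ";", fixed = TRUE), trimws),
    category = as.character(df$category)
  )
  check_unique(out$drug_id, "drug identifier")
  out
}

#' Read cell-line metadata
#'
#' Parses the cell line -> tissue / tissue-subtype map. Subtype labels are
#' taken verbatim (e.g. `Lung_Nsclc_SCC`); every subtype must map to exactly
#' one tissue.
#'
#' @param path Path to a delimited file with columns `cell_line_id`,
#'   `tissue`, `subtype`. Unknown extra columns are ignored with a warning.
#' @param delim Field delimiter; `NULL` auto-detects.
#'
#' @return A tibble with columns `cell_line_id` (unique), `tissue`,
#'   `subtype`.
#' @export
read_cell_line_metadata <- function(path, delim = NULL) {
  df <- read_delimited(path, delim)
  wanted <- c("cell_line_id", "tissue", "subtype")
  require_columns(df, wanted, "cell-line metadata")
  extra <- setdiff(names(df), wanted)
  if (length(extra) > 0) {
    warning(sprintf("read_cell_line_metadata: ignoring extra column(s): %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  out <- tibble::tibble(
    cell_line_id = trimws(as.character(df$cell_line_id)),
    tissue = as.character(df$tissue),
    subtype = as.character(df$subtype)
  )
  check_unique(out$cell_line_id, "cell-line identifier")
  multi <- dplyr::distinct(out, .data$subtype, .data$tissue) |>
    dplyr::count(.data$subtype) |>
    dplyr::filter(.data$n > 1)
  if (nrow(multi) > 0) {
    stop(sprintf("subtype '%s' maps to more than one tissue", multi$subtype[1]),
         call. = FALSE)
  }
  out
}

# shared delimited-file front end: readr with extension-based delimiter guess
read_delimited <- function(path, delim = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE,
                    name_repair = "minimal")
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing mandatory column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop(sprintf("duplicate %s: %s", what, paste(utils::head(dup, 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(ids)
}
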