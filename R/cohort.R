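#' Default drug-category merges
#'
#' Target-pathway categories that share a pathway are combined before
#' filtering: EGFR signaling into ErbBs signaling, IGF1R signaling into RTK
#' signaling, and "Other, kinases" into Kinases.
#'
#' @return A tibble with columns `from`, `to`.
#' @export
default_category_merges <- function() {
  tibble::tibble(
    from = c("EGFR signaling", "IGF1R signaling", "Other, kinases"),
    to = c("ErbBs signaling", "RTK signaling", "Kinases")
  )
}

#' Merge drug categories
#'
#' Renames target-pathway categories according to a source -> destination
#' mapping. Chained renames (a mapping source that is also another rule's
#' destination) are rejected so the result cannot depend on rule order.
#'
#' @param catalog A drug catalog tibble (see [read_drug_catalog()]).
#' @param merges A tibble with columns `from`, `to`; defaults to
#'   [default_category_merges()].
#'
#' @return The catalog with `category` recoded; all other columns untouched.
#' @export
merge_drug_categories <- function(catalog, merges = default_category_merges()) {
  stopifnot(is.data.frame(merges), all(c("from", "to") %in% names(merges)))
  chained <- intersect(merges$from, merges$to)
  if (length(chained) > 0) {
    stop(sprintf("chained category rename via '%s' is not allowed", chained[1]),
         call. = FALSE)
  }
  if (anyDuplicated(merges$from)) {
    stop("duplicate merge source category", call. = FALSE)
  }
  idx <- match(catalog$category, merges$from)
  catalog$category <- ifelse(is.na(idx), catalog$category, merges$to[idx])
  catalog
}

#' Filter drug categories by size
#'
#' Removes drugs with no usable category (missing, empty, `"Other"` or
#' `"Unclassified"`), then removes whole categories holding fewer than
#' `min_drugs` drugs, so that every retained category supports a stable
#' global score denominator.
#'
#' @param catalog A (merged) drug catalog tibble.
#' @param min_drugs Minimum drugs per retained category (default 10).
#' @param drop_categories Category labels treated as "no assignment";
#'   default `c("Other", "Unclassified")`.
#'
#' @return The filtered catalog; every category has at least `min_drugs`
#'   drugs. Errors if nothing survives.
#' @export
filter_drug_categories <- function(catalog, min_drugs = 10,
                                   drop_categories = c("Other", "Unclassified")) {
  stopifnot(min_drugs >= 1)
  keep <- !is.na(catalog$category) &
    nzchar(trimws(catalog$category)) &
    !(catalog$category %in% drop_categories)
  out <- catalog[keep, ]
  sizes <- table(out$category)
  out <- out[out$category %in% names(sizes)[sizes >= min_drugs], ]
  if (nrow(out) == 0) {
    stop("no drug categories survive filtering; lower min_drugs or check the catalog",
         call. = FALSE)
  }
  out
}

#' Exclude cell lines by tissue
#'
#' Drops cell lines from excluded tissues (case-insensitive comparison).
#' Defaults to blood, bone and soft tissue so the analysis focuses on solid
#' tumours.
#'
#' @param metadata Cell-line metadata tibble (see
#'   [read_cell_line_metadata()]).
#' @param excluded Character vector of tissue names to remove.
#'
#' @return Filtered metadata; warns (not errors) if nothing remains.
#' @export
exclude_tissues <- function(metadata, excluded = c("blood", "bone", "soft tissue")) {
  keep <- !(tolower(trimws(metadata$tissue)) %in% tolower(trimws(excluded)))
  out <- metadata[keep, ]
  if (nrow(out) == 0) {
    warning("all cell lines excluded by tissue filter", call. = FALSE)
  }
  out
}

#' Build the analysis cohort
#'
#' Joins the four validated inputs into per-(drug, subtype) groups of cell
#' lines that have both an AUC for the drug and an expression column. Groups
#' smaller than `min_lines` are dropped: correlations on very small panels
#' are unstable and would dominate the z-score tails.
#'
#' @param expression Genes x cell lines numeric matrix ([read_expression()]).
#' @param response Drug-response tibble ([read_drug_response()]).
#' @param catalog Curated drug catalog (after [merge_drug_categories()] and
#'   [filter_drug_categories()]); drugs outside it are ignored.
#' @param metadata Cell-line metadata (after [exclude_tissues()]).
#' @param min_lines Minimum cell lines per retained (drug, subtype) group
#'   (default 10).
#'
#' @return An object of class `analysis_cohort`: a list with
#'   \describe{
#'     \item{groups}{tibble with columns `drug_id`, `category`, `subtype`,
#'       `cell_lines` (list column), `n`.}
#'     \item{catalog}{the curated catalog actually used.}
#'     \item{n_subtypes}{number of distinct subtypes appearing in at least
#'       one retained group — the `S` in the global score denominator.}
#'   }
#' @export
build_cohort <- function(expression, response, catalog, metadata, min_lines = 10) {
  stopifnot(min_lines >= 1)
  resp <- response |>
    dplyr::filter(.data$drug_id %in% catalog$drug_id,
                  .data$cell_line_id %in% colnames(expression)) |>
    dplyr::inner_join(metadata[c("cell_line_id", "subtype")], by = "cell_line_id")

  groups <- resp |>
    dplyr::group_by(.data$drug_id, .data$subtype) |>
    dplyr::summarise(cell_lines = list(.data$cell_line_id),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n >= min_lines) |>
    dplyr::left_join(catalog[c("drug_id", "category")], by = "drug_id") |>
    dplyr::select("drug_id", "category", "subtype", "cell_lines", "n") |>
    dplyr::arrange(.data$drug_id, .data$subtype)

  if (nrow(groups) == 0) {
    stop("no (drug, subtype) group reaches min_lines cell lines; nothing to analyse",
         call. = FALSE)
  }
  # full curated catalog kept: the global score denominator counts every
  # category drug, including those with no retained group
  structure(
    list(groups = groups,
         catalog = catalog,
         n_subtypes = dplyr::n_distinct(groups$subtype)),
    class = "analysis_cohort"
  )
}

#' @export
print.analysis_cohort <- function(x, ...) {
  cat(sprintf(
    "<analysis_cohort> %d (drug, subtype) groups | %d drugs | %d categories | %d subtypes\n",
    nrow(x$groups), dplyr::n_distinct(x$groups$drug_id),
    dplyr::n_distinct(x$groups$category), x$n_subtypes))
  invisible(x)
}
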