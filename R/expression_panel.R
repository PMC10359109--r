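#' Assemble an annotated single-cell expression panel
#'
#' Bundles a genes x cells count matrix with a per-cell cell-type annotation
#' and panel-level metadata. This is the unit on which cell-type signatures
#' are derived: one panel corresponds to one tissue profiled in one study.
#'
#' Gene symbols are canonicalised with [normalize_symbols()]. When two rows
#' collapse to the same symbol, the row with the larger total count is kept
#' and the collision is reported via a message.
#'
#' @param counts Non-negative integer matrix, genes in rows (rownames are
#'   gene symbols), cells in columns (colnames are cell identifiers).
#' @param cell_types Either a named character vector (names are cell ids,
#'   values are cell-type labels) or a data frame whose first two columns are
#'   cell id and cell-type label.
#' @param panel_id,tissue,organ_system,developmental_stage Panel metadata.
#'   `developmental_stage` must be one of `"fetal"`, `"neonatal"`, `"adult"`,
#'   `"unspecified"`.
#' @param uberon_id Optional Uberon anatomy ontology id for the tissue,
#'   carried as opaque metadata.
#' @param cl_ids Optional named character vector mapping cell-type labels to
#'   Cell Ontology ids, carried as opaque metadata.
#' @return An `expression_panel` object: a list with elements `counts`
#'   (integer matrix), `cell_types` (tibble with columns `cell_id`,
#'   `cell_type`) and `metadata` (list).
#' @examples
#' counts <- matrix(rpois(20, 2), 4, 5,
#'   dimnames = list(paste0("G", 1:4), paste0("c", 1:5)))
#' ann <- setNames(rep(c("T cell", "B cell"), c(2, 3)), colnames(counts))
#' expression_panel(counts, ann, panel_id = "demo", tissue = "blood")
#' @export
expression_panel <- function(counts, cell_types,
                             panel_id = "panel", tissue = "unspecified",
                             organ_system = "unspecified",
                             developmental_stage = c("unspecified", "fetal",
                                                     "neonatal", "adult"),
                             uberon_id = NULL, cl_ids = NULL) {
  developmental_stage <- match.arg(developmental_stage)
  counts <- as.matrix(counts)
  assert_that(!is.null(rownames(counts)), "`counts` must have gene symbols as rownames")
  assert_that(!is.null(colnames(counts)), "`counts` must have cell ids as colnames")
  assert_that(all(is.finite(counts)) && all(counts >= 0) &&
                all(counts == floor(counts)),
              "`counts` must be non-negative integers")
  storage.mode(counts) <- "integer"

  if (is.data.frame(cell_types)) {
    ct <- stats::setNames(as.character(cell_types[[2]]),
                          as.character(cell_types[[1]]))
  } else {
    ct <- cell_types
  }
  assert_that(!is.null(names(ct)), "`cell_types` must map cell ids to labels")
  missing_cells <- setdiff(colnames(counts), names(ct))
  assert_that(length(missing_cells) == 0,
              paste0("cells without a cell-type label: ",
                     paste(utils::head(missing_cells, 5), collapse = ", ")))
  ct <- ct[colnames(counts)]

  rownames(counts) <- normalize_symbols(rownames(counts))
  counts <- collapse_duplicate_symbols(counts)

  structure(
    list(
      counts = counts,
      cell_types = tibble(cell_id = colnames(counts),
                          cell_type = unname(as.character(ct))),
      metadata = list(panel_id = panel_id, tissue = tissue,
                      organ_system = organ_system,
                      developmental_stage = developmental_stage,
                      uberon_id = uberon_id, cl_ids = cl_ids)
    ),
    class = "expression_panel"
  )
}

# keep, per duplicated symbol, the row with the larger total count
collapse_duplicate_symbols <- function(counts) {
  sym <- rownames(counts)
  if (!anyDuplicated(sym)) return(counts)
  totals <- rowSums(counts)
  keep <- lex_order(sym, -totals)          # within symbol, biggest first
  keep <- keep[!duplicated(sym[keep])]
  dropped <- nrow(counts) - length(keep)
  message(dropped, " duplicate gene symbol row(s) collapsed; ",
          "kept the row with the larger total count per symbol")
  counts[sort(keep), , drop = FALSE]
}

#' @export
print.expression_panel <- function(x, ...) {
  tab <- table(x$cell_types$cell_type)
  cat("<expression_panel> ", x$metadata$panel_id,
      " (", x$metadata$tissue, ", ", x$metadata$developmental_stage, ")\n",
      "  ", nrow(x$counts), " genes x ", ncol(x$counts), " cells, ",
      length(tab), " cell types\n", sep = "")
  invisible(x)
}

#' Cell-type composition of a panel
#'
#' @param panel An [expression_panel()].
#' @return A tibble with columns `cell_type` and `n_cells`.
#' @export
cell_type_sizes <- function(panel) {
  stopifnot(inherits(panel, "expression_panel"))
  panel$cell_types |>
    dplyr::count(.data$cell_type, name = "n_cells") |>
    dplyr::arrange(.data$cell_type)
}

#' Log2 counts-per-million normalization
#'
#' Scales every cell (column) to one million total counts and applies
#' `log2(x + 1)`: entry (g, c) becomes
#' `log2(counts[g, c] / colsum(c) * 1e6 + 1)`.
#'
#' @param counts Count matrix (genes x cells), or an [expression_panel()].
#' @return A numeric matrix of the same shape.
#' @examples
#' m <- matrix(c(1L, 3L), 2, 1, dimnames = list(c("A", "B"), "cell1"))
#' normalize_log2_cpm(m)   # log2(250001), log2(750001)
#' @export
normalize_log2_cpm <- function(counts) {
  if (inherits(counts, "expression_panel")) counts <- counts$counts
  counts <- as.matrix(counts)
  libsize <- colSums(counts)
  bad <- which(libsize == 0)
  if (length(bad) > 0) {
    nm <- colnames(counts)[bad] %||% as.character(bad)
    stop("cell(s) with zero total count cannot be CPM-normalized: ",
         paste(utils::head(nm, 5), collapse = ", "), call. = FALSE)
  }
  log2(sweep(counts, 2, libsize, "/") * 1e6 + 1)
}

#' Filter lowly expressed genes
#'
#' Retains genes detected (count > 0) in at least
#' `max(min_cells, ceiling(min_fraction * n_cells))` cells. The defaults
#' (detected in >= 3 cells and >= 0.1% of cells) follow common single-cell
#' practice and keep the downstream t-statistics well-conditioned.
#'
#' @param panel An [expression_panel()].
#' @param min_cells Minimum number of cells a gene must be detected in.
#' @param min_fraction Minimum fraction of cells a gene must be detected in.
#' @return The panel with the gene set reduced; the number of discarded genes
#'   is reported via a message.
#' @export
filter_genes <- function(panel, min_cells = 3, min_fraction = 0.001) {
  stopifnot(inherits(panel, "expression_panel"))
  assert_that(min_cells >= 0, "`min_cells` must be >= 0")
  assert_that(min_fraction >= 0 && min_fraction <= 1,
              "`min_fraction` must be in [0, 1]")
  threshold <- max(min_cells, ceiling(min_fraction * ncol(panel$counts)))
  detected <- rowSums(panel$counts > 0)
  keep <- detected >= threshold
  if (!any(keep)) {
    stop("all ", nrow(panel$counts), " genes removed by the expression filter",
         " (threshold: detected in >= ", threshold, " cells)", call. = FALSE)
  }
  message(sum(!keep), " gene(s) removed by the expression filter (detected in < ",
          threshold, " cells); ", sum(keep), " retained")
  panel$counts <- panel$counts[keep, , drop = FALSE]
  panel
}

#' Drop under-represented cell types
#'
#' Removes every cell whose cell-type label has fewer than `min_cells`
#' members; signature derivation contrasts each focal cell type against all
#' remaining cells, so at least two cell types must survive.
#'
#' @param panel An [expression_panel()].
#' @param min_cells Minimum number of cells per retained cell type
#'   (default 30).
#' @return The panel restricted to cells of the retained cell types.
#' @export
filter_cell_types <- function(panel, min_cells = 30) {
  stopifnot(inherits(panel, "expression_panel"))
  assert_that(min_cells >= 1, "`min_cells` must be >= 1")
  sizes <- table(panel$cell_types$cell_type)
  keep_types <- names(sizes)[sizes >= min_cells]
  if (length(keep_types) < 2) {
    stop("fewer than 2 cell types with >= ", min_cells,
         " cells; the one-vs-rest contrast needs a focal group and a complement",
         call. = FALSE)
  }
  dropped <- setdiff(names(sizes), keep_types)
  if (length(dropped) > 0) {
    message("dropped ", length(dropped), " cell type(s) with < ", min_cells,
            " cells: ", paste(dropped, collapse = ", "))
  }
  keep_cells <- panel$cell_types$cell_type %in% keep_types
  panel$counts <- panel$counts[, keep_cells, drop = FALSE]
  panel$cell_types <- panel$cell_types[keep_cells, , drop = FALSE]
  panel
}
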