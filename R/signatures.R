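#' One-vs-rest t-statistics per gene and cell type
#'
#' For each gene g and cell type j, fits by least squares
#' `expr_g ~ intercept + indicator(cell in j)` over all cells of the panel
#' and records the t-statistic of the indicator coefficient. This equals the
#' pooled-variance two-sample t-statistic contrasting the focal cells with
#' all remaining cells; a large positive value marks a gene specifically
#' elevated in the focal cell type.
#'
#' Genes with zero pooled residual variance (e.g. constant expression) get
#' t = 0, keeping the matrix finite.
#'
#' @param norm Numeric matrix (genes x cells), typically
#'   [normalize_log2_cpm()] output.
#' @param labels Character vector of cell-type labels, one per column of
#'   `norm`.
#' @return Numeric matrix (genes x cell types); column names are the distinct
#'   labels in lexicographic order.
#' @examples
#' norm <- rbind(G1 = c(0, 1, 0, 2, 3), G2 = c(1, 1, 1, 1, 1))
#' colnames(norm) <- paste0("c", 1:5)
#' compute_tc_tstats(norm, c("rest", "rest", "rest", "focal", "focal"))
#' @export
compute_tc_tstats <- function(norm, labels) {
  norm <- as.matrix(norm)
  labels <- as.character(labels)
  assert_that(length(labels) == ncol(norm),
              "`labels` must have one entry per column of `norm`")
  types <- lex_sort(unique(labels))
  assert_that(length(types) >= 2, "need >= 2 distinct cell types")
  sizes <- table(labels)
  if (any(sizes < 2)) {
    stop("cell type(s) with a single cell: ",
         paste(names(sizes)[sizes < 2], collapse = ", "),
         " (filter with filter_cell_types() first)", call. = FALSE)
  }
  n <- ncol(norm)
  out <- matrix(0, nrow(norm), length(types),
                dimnames = list(rownames(norm), types))
  for (j in types) {
    focal <- labels == j
    n1 <- sum(focal); n0 <- n - n1
    x1 <- norm[, focal, drop = FALSE]
    x0 <- norm[, !focal, drop = FALSE]
    m1 <- rowMeans(x1); m0 <- rowMeans(x0)
    ss <- rowSums((x1 - m1)^2) + rowSums((x0 - m0)^2)
    s2 <- ss / (n - 2)
    se <- sqrt(s2 * (1 / n1 + 1 / n0))
    t <- ifelse(se > 0, (m1 - m0) / se, 0)
    out[, j] <- t
  }
  out
}

#' Select top-fraction signature genes per cell type
#'
#' Per cell type, the signature is the `max(1, floor(top_fraction *
#' |universe|))` genes with the largest t-statistic, ordered by descending
#' t-statistic; ties at the cutoff (and within the signature) are broken by
#' lexicographic gene symbol so the selection is deterministic.
#'
#' @param tstats Genes x cell types t-statistic matrix from
#'   [compute_tc_tstats()].
#' @param universe Character vector of gene symbols to select from (default:
#'   all rows of `tstats`). The signature size is a fraction of this set.
#' @param top_fraction Fraction of the universe per signature, in (0, 1].
#'   Default 0.05 (the top 5%).
#' @param panel_id,metadata Panel identity and metadata to carry along.
#' @return A `signature_panel` object: list with elements `panel_id`,
#'   `universe` (sorted), `signatures` (named list, one ordered gene vector
#'   per cell type), `tstats`, `top_fraction`, `metadata`.
#' @export
select_signatures <- function(tstats, universe = rownames(tstats),
                              top_fraction = 0.05,
                              panel_id = "panel", metadata = list()) {
  assert_that(top_fraction > 0 && top_fraction <= 1,
              "`top_fraction` must be in (0, 1]")
  assert_that(length(universe) > 0, "empty gene universe")
  universe <- lex_sort(unique(universe))
  assert_that(all(universe %in% rownames(tstats)),
              "`universe` contains genes absent from `tstats`")
  tstats <- tstats[universe, , drop = FALSE]
  k <- max(1L, floor(top_fraction * length(universe)))
  sigs <- lapply(stats::setNames(colnames(tstats), colnames(tstats)),
                 function(j) {
    ord <- lex_order(-tstats[, j], universe)
    universe[ord[seq_len(k)]]
  })
  structure(
    list(panel_id = panel_id, universe = universe, signatures = sigs,
         tstats = tstats, top_fraction = top_fraction, metadata = metadata),
    class = "signature_panel"
  )
}

#' Derive a signature panel from an annotated expression panel
#'
#' Runs the full derivation: drop under-represented cell types, drop lowly
#' expressed genes, log2-CPM normalize, compute one-vs-rest t-statistics,
#' and select the top-fraction signature per cell type.
#'
#' @param panel An [expression_panel()].
#' @param top_fraction Signature fraction of the retained gene universe
#'   (default 0.05).
#' @param min_cells_per_type Minimum cells per retained cell type
#'   (default 30).
#' @param gene_min_cells,gene_min_fraction Gene expression filter, see
#'   [filter_genes()].
#' @return A `signature_panel` (see [select_signatures()]).
#' @examples
#' sim <- simulate_panel(n_genes = 300,
#'   cell_types = c(A = 40, B = 40), n_markers_per_tc = 10, seed = 1)
#' sp <- build_signature_panel(sim$panel)
#' lengths(sp$signatures)
#' @export
build_signature_panel <- function(panel, top_fraction = 0.05,
                                  min_cells_per_type = 30,
                                  gene_min_cells = 3,
                                  gene_min_fraction = 0.001) {
  stopifnot(inherits(panel, "expression_panel"))
  panel <- filter_cell_types(panel, min_cells = min_cells_per_type)
  panel <- filter_genes(panel, min_cells = gene_min_cells,
                        min_fraction = gene_min_fraction)
  norm <- normalize_log2_cpm(panel$counts)
  tstats <- compute_tc_tstats(norm, panel$cell_types$cell_type)
  select_signatures(tstats, universe = rownames(norm),
                    top_fraction = top_fraction,
                    panel_id = panel$metadata$panel_id,
                    metadata = panel$metadata)
}

#' @export
print.signature_panel <- function(x, ...) {
  cat("<signature_panel> ", x$panel_id, ": ", length(x$signatures),
      " cell types, universe of ", length(x$universe), " genes, ",
      "signature size ", length(x$signatures[[1]]),
      " (top ", format(100 * x$top_fraction), "%)\n", sep = "")
  invisible(x)
}

#' Tissue-cell-type identifiers of signature panels
#'
#' A TC (tissue-cell type) id is `"<panel_id>|<cell_type>"`, unique across a
#' collection of panels as long as panel ids are unique.
#'
#' @param panels A `signature_panel` or list of them.
#' @return Tibble with columns `tc_id`, `panel_id`, `cell_type`, `tissue`,
#'   `organ_system`, `developmental_stage`, `signature_length`.
#' @export
tc_table <- function(panels) {
  panels <- as_panel_list(panels)
  purrr::map_dfr(panels, function(sp) {
    md <- sp$metadata
    tibble(
      tc_id = paste(sp$panel_id, names(sp$signatures), sep = "|"),
      panel_id = sp$panel_id,
      cell_type = names(sp$signatures),
      tissue = md$tissue %||% "unspecified",
      organ_system = md$organ_system %||% "unspecified",
      developmental_stage = md$developmental_stage %||% "unspecified",
      signature_length = lengths(sp$signatures)
    )
  })
}

as_panel_list <- function(panels) {
  if (inherits(panels, "signature_panel")) panels <- list(panels)
  assert_that(length(panels) > 0 &&
                all(vapply(panels, inherits, TRUE, "signature_panel")),
              "`panels` must be a signature_panel or a list of them")
  ids <- vapply(panels, function(p) p$panel_id, "")
  assert_that(!anyDuplicated(ids), "panel ids must be unique")
  panels
}
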