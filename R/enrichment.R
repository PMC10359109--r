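#' Map a query gene list onto a background universe
#'
#' Normalizes symbols, removes duplicates, and records which genes are
#' present in the active background universe; genes outside the universe do
#' not enter the 2x2 table and are reported through `n_input - n_mapped`.
#'
#' @param symbols Character vector of gene symbols.
#' @param universe Character vector, the background gene universe.
#' @return A `query_gene_list`: list with `raw_symbols`, `symbols` (unique,
#'   normalized), `mapped` (subset present in the universe, sorted),
#'   `n_input`, `n_mapped`.
#' @export
query_gene_list <- function(symbols, universe) {
  raw <- as.character(symbols)
  syms <- unique(normalize_symbols(raw))
  syms <- syms[nzchar(syms)]
  mapped <- lex_sort(intersect(syms, universe))
  structure(
    list(raw_symbols = raw, symbols = syms, mapped = mapped,
         n_input = length(syms), n_mapped = length(mapped)),
    class = "query_gene_list"
  )
}

#' @export
print.query_gene_list <- function(x, ...) {
  cat("<query_gene_list> ", x$n_mapped, " of ", x$n_input,
      " genes mapped to the background universe\n", sep = "")
  invisible(x)
}

#' Raw cell-type-specific enrichment test
#'
#' One-sided over-representation test of a query gene list in one cell-type
#' signature: the upper hypergeometric tail `P(X >= a)` where `a` is the
#' observed overlap, the population is the background universe, successes are
#' the signature genes and draws are the mapped query genes. For a 2x2 table
#' this coincides with the one-sided Fisher's exact test for enrichment.
#'
#' @param query A [query_gene_list()] or character vector of gene symbols.
#' @param signature Character vector, the cell type's signature genes
#'   (must lie inside `universe`).
#' @param universe Character vector, the background gene universe.
#' @return List with elements `a`, `b`, `c`, `d` (2x2 counts: overlap,
#'   query-only, signature-only, neither), `p_raw`, `overlap`
#'   (lexicographically sorted), `n_mapped`.
#' @examples
#' uni <- paste0("G", 1:20)
#' csea_raw(c("G1", "G2", "G3", "G15"), paste0("G", 1:5), uni)$p_raw
#' @export
csea_raw <- function(query, signature, universe) {
  if (!inherits(query, "query_gene_list")) {
    query <- query_gene_list(query, universe)
  }
  signature <- unique(signature)
  assert_that(length(signature) >= 1, "empty signature")
  assert_that(all(signature %in% universe), "signature must lie in the universe")
  assert_that(all(query$mapped %in% universe),
              "query was mapped against a different universe")
  N <- length(unique(universe))
  K <- length(signature)
  n <- query$n_mapped
  overlap <- lex_sort(intersect(query$mapped, signature))
  a <- length(overlap)
  if (n == 0) {
    warning("no query genes mapped to the universe; p_raw = 1", call. = FALSE)
    p <- 1
  } else {
    p <- stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
  }
  list(a = a, b = n - a, c = K - a, d = N - K - (n - a),
       p_raw = p, overlap = overlap, n_mapped = n)
}

#' Enrichment of a query across all cell types of a panel
#'
#' Maps the query onto the panel's gene universe once, then runs
#' [csea_raw()] against every cell-type signature.
#'
#' @param query Character vector of gene symbols or a [query_gene_list()]
#'   already mapped against this panel's universe.
#' @param panel A `signature_panel` from [build_signature_panel()].
#' @return A tibble with one row per cell type, in the panel's cell-type
#'   order: `tc_id`, `cell_type`, `a`, `b`, `c`, `d`, `p_raw`, `n_overlap`,
#'   `overlap` (list column of sorted gene vectors). The mapped query size is
#'   attached as attribute `n_mapped`.
#' @export
query_panel <- function(query, panel) {
  stopifnot(inherits(panel, "signature_panel"))
  if (!inherits(query, "query_gene_list")) {
    query <- query_gene_list(query, panel$universe)
  }
  cells <- purrr::map(panel$signatures, function(sig) {
    csea_raw(query, sig, panel$universe)
  })
  out <- tibble(
    tc_id = paste(panel$panel_id, names(cells), sep = "|"),
    cell_type = names(cells),
    a = vapply(cells, `[[`, 0, "a"),
    b = vapply(cells, `[[`, 0, "b"),
    c = vapply(cells, `[[`, 0, "c"),
    d = vapply(cells, `[[`, 0, "d"),
    p_raw = vapply(cells, `[[`, 0, "p_raw"),
    n_overlap = vapply(cells, `[[`, 0, "a"),
    overlap = purrr::map(cells, "overlap")
  )
  attr(out, "n_mapped") <- query$n_mapped
  attr(out, "n_input") <- query$n_input
  out
}
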