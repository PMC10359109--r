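#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then one or more gene symbols, all
#' tab-separated. CRLF and LF line endings are accepted. Gene symbols are
#' normalized with [normalize_symbols()]; duplicates within a line are
#' removed with a warning.
#'
#' @param path Path to a GMT file.
#' @return Named list of gene-set character vectors, with the per-set
#'   descriptions in attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  assert_that(length(lines) > 0, paste0("empty GMT file: ", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    stop("malformed GMT line ", bad[1], " in ", path,
         " (need name, description and >= 1 gene)", call. = FALSE)
  }
  nms <- vapply(fields, `[[`, "", 1)
  desc <- vapply(fields, `[[`, "", 2)
  sets <- lapply(fields, function(f) normalize_symbols(f[-(1:2)]))
  ndup <- sum(vapply(sets, anyDuplicated, 0) > 0)
  if (ndup > 0) {
    warning(ndup, " GMT line(s) contained duplicate genes; deduplicated",
            call. = FALSE)
    sets <- lapply(sets, unique)
  }
  stats::setNames(sets, nms) |>
    structure(descriptions = stats::setNames(desc, nms))
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of gene-set character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to the set names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  assert_that(length(sets) > 0 && !is.null(names(sets)),
              "`sets` must be a non-empty named list")
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "descriptions") %||% names(sets)
  }
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[[i]], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text gene list
#'
#' One gene symbol per line; blank lines ignored, symbols normalized and
#' deduplicated.
#'
#' @param path Path to the file.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- normalize_symbols(sub("\r$", "", readLines(path, warn = FALSE)))
  unique(x[nzchar(x)])
}

#' Read a genes x cells count matrix
#'
#' Either a tab-separated table (first column gene symbols, header row of
#' cell ids) or a matrix-market triplet file accompanied by one-per-line
#' gene and cell id files.
#'
#' @param path Count matrix path (TSV, or MatrixMarket `.mtx`).
#' @param genes_path,cells_path Required for MatrixMarket input: row (gene)
#'   and column (cell) id files, one id per line.
#' @return Integer matrix with gene rownames and cell colnames.
#' @export
read_counts <- function(path, genes_path = NULL, cells_path = NULL) {
  if (grepl("\\.mtx$", path)) {
    assert_that(!is.null(genes_path) && !is.null(cells_path),
                "MatrixMarket input needs `genes_path` and `cells_path`")
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- read_gene_list(genes_path)
    colnames(m) <- sub("\r$", "", readLines(cells_path, warn = FALSE))
    storage.mode(m) <- "integer"
    return(m)
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Read a cell annotation table
#'
#' Tab-separated with at least two columns; the first two are taken as cell
#' id and cell-type label.
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `cell_id` and `cell_type` (extras kept).
#' @export
read_cell_annotations <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  assert_that(ncol(df) >= 2, "annotation table needs >= 2 columns")
  names(df)[1:2] <- c("cell_id", "cell_type")
  as_tibble(df)
}

#' Export a signature panel
#'
#' Writes the per-cell-type signatures as GMT (set name
#' `"<panel_id>|<cell_type>"`), the full t-statistic matrix as TSV, and the
#' panel metadata as a key-value text file, so the panel can be re-read with
#' [read_signature_panel()].
#'
#' @param sp A `signature_panel`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_signature_panel <- function(sp, dir) {
  stopifnot(inherits(sp, "signature_panel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sets <- stats::setNames(sp$signatures,
                          paste(sp$panel_id, names(sp$signatures), sep = "|"))
  write_gmt(sets, file.path(dir, "signatures.gmt"),
            descriptions = paste0("signature of ", names(sp$signatures),
                                  " in panel ", sp$panel_id))
  ts <- data.frame(gene = rownames(sp$tstats), sp$tstats,
                   check.names = FALSE)
  utils::write.table(ts, file.path(dir, "tstats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  md <- sp$metadata
  writeLines(c(
    paste0("panel_id\t", sp$panel_id),
    paste0("top_fraction\t", format(sp$top_fraction, digits = 17)),
    paste0("tissue\t", md$tissue %||% "unspecified"),
    paste0("organ_system\t", md$organ_system %||% "unspecified"),
    paste0("developmental_stage\t", md$developmental_stage %||% "unspecified"),
    paste0("uberon_id\t", md$uberon_id %||% "")
  ), file.path(dir, "panel_info.txt"))
  invisible(dir)
}

#' Re-read an exported signature panel
#'
#' @param dir Directory written by [write_signature_panel()].
#' @return A `signature_panel`.
#' @export
read_signature_panel <- function(dir) {
  info <- utils::read.delim(file.path(dir, "panel_info.txt"), header = FALSE,
                            col.names = c("key", "value"),
                            stringsAsFactors = FALSE)
  kv <- stats::setNames(as.character(info$value), info$key)
  ts <- utils::read.delim(file.path(dir, "tstats.tsv"), check.names = FALSE,
                          stringsAsFactors = FALSE)
  tstats <- as.matrix(ts[, -1, drop = FALSE])
  rownames(tstats) <- ts[[1]]
  select_signatures(tstats, universe = rownames(tstats),
                    top_fraction = as.numeric(kv[["top_fraction"]]),
                    panel_id = kv[["panel_id"]],
                    metadata = list(
                      panel_id = kv[["panel_id"]],
                      tissue = kv[["tissue"]],
                      organ_system = kv[["organ_system"]],
                      developmental_stage = kv[["developmental_stage"]],
                      uberon_id = if (nzchar(kv[["uberon_id"]])) kv[["uberon_id"]]
                    ))
}

#' Export a reference of trait-associated gene sets
#'
#' Writes the TAG sets as GMT, the raw p-value matrix as TSV (first column
#' `tag_id`, one column per `tc_id`), the TC metadata table, and a manifest
#' recording the collection size and a checksum per panel universe.
#'
#' @param ref A `tag_reference`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_reference <- function(ref, dir) {
  stopifnot(inherits(ref, "tag_reference"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gmt(ref$tag_sets, file.path(dir, "tags.gmt"))
  pm <- data.frame(tag_id = rownames(ref$p_matrix), ref$p_matrix,
                   check.names = FALSE)
  utils::write.table(format(pm, digits = 17), file.path(dir, "p_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ref$tc_info, file.path(dir, "tc_info.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(c(paste0("n_tags\t", ref$n_tags),
               paste0("n_tcs\t", length(ref$tc_ids))),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Re-read an exported reference
#'
#' @param dir Directory written by [write_reference()].
#' @return A `tag_reference`.
#' @export
read_reference <- function(dir) {
  tags <- read_gmt(file.path(dir, "tags.gmt"))
  pm <- utils::read.delim(file.path(dir, "p_matrix.tsv"), check.names = FALSE,
                          stringsAsFactors = FALSE)
  p_matrix <- as.matrix(pm[, -1, drop = FALSE])
  rownames(p_matrix) <- pm[[1]]
  tc_info <- as_tibble(utils::read.delim(file.path(dir, "tc_info.tsv"),
                                         check.names = FALSE,
                                         stringsAsFactors = FALSE))
  assert_that(identical(rownames(p_matrix), names(tags)),
              "p-matrix rows do not match the GMT sets")
  structure(
    list(tag_sets = tags[names(tags)], tag_lengths = lengths(tags),
         p_matrix = p_matrix, tc_ids = colnames(p_matrix),
         tc_info = tc_info, n_tags = length(tags)),
    class = "tag_reference"
  )
}

#' Write an enrichment result table
#'
#' Flattens the `overlap` list column to a comma-joined string and writes a
#' TSV with a `#`-prefixed header recording the query-level quantities
#' (mapped genes, cumulative factor, thresholds).
#'
#' @param result A `csea_result` from [run_query()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_query_result <- function(result, path) {
  stopifnot(inherits(result, "csea_result"))
  header <- c(
    paste0("# n_input\t", attr(result, "n_input")),
    paste0("# n_mapped\t", attr(result, "n_mapped")),
    paste0("# cumulative_factor\t",
           format(attr(result, "cumulative_factor"), digits = 17)),
    paste0("# n_tcs\t", attr(result, "n_tcs")),
    paste0("# bonferroni_threshold\t",
           format(attr(result, "bonferroni_threshold"), digits = 17)),
    paste0("# nominal_threshold\t",
           format(attr(result, "nominal_threshold"), digits = 17))
  )
  flat <- tidy(result)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(flat, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
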