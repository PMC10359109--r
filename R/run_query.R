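#' Full cell-type-specific enrichment analysis of a gene list
#'
#' Runs the complete pipeline for one query: raw hypergeometric enrichment
#' against every tissue-cell type (TC) of the supplied signature panels,
#' rank-based permutation adjustment of each raw p-value against the
#' reference p-values of that TC (scaled by the cumulative length factor),
#' a cross-TC rank p-value, and Fisher's-method combination of the two,
#' with Bonferroni and nominal significance flags.
#'
#' The reference columns are matched to the panels' TCs by `tc_id`, never by
#' position, so panel order cannot silently misalign the reference.
#'
#' @param query Character vector of gene symbols (a query gene list).
#' @param panels A `signature_panel` or list of them; their TCs must all be
#'   covered by `reference`.
#' @param reference A `tag_reference` from [build_reference()].
#' @param min_query,max_query Suggested query length bounds (defaults 20 and
#'   2000); violations produce a warning, not an error.
#' @param bonferroni_alpha,nominal_p Significance thresholds, see
#'   [annotate_significance()].
#' @return A `csea_result` tibble, one row per TC sorted by ascending
#'   `p_combined` (ties broken by `tc_id`), with columns `tc_id`,
#'   `panel_id`, `tissue`, `organ_system`, `developmental_stage`,
#'   `cell_type`, `signature_length`, `n_mapped`, `p_raw`, `p_perm`, `p_tc`,
#'   `chi2_stat`, `p_combined`, `n_overlap`, `overlap` (list column),
#'   `bonferroni`, `nominal`. Query-level quantities (`n_input`, `n_mapped`,
#'   `cumulative_factor`, `n_tcs`, thresholds) are attached as attributes
#'   and surfaced by [glance.csea_result()].
#' @examples
#' sim <- simulate_panel(n_genes = 400, cell_types = c(A = 40, B = 40),
#'                       n_markers_per_tc = 10, seed = 7)
#' sp <- build_signature_panel(sim$panel)
#' tags <- simulate_tags(50, sp$universe, log_uniform_lengths(20, 300),
#'                       seed = 8)
#' ref <- build_reference(tags, sp)
#' res <- run_query(sim$truth$marker_of$A, sp, ref)
#' res[1:2, c("tc_id", "p_raw", "p_combined")]
#' @export
run_query <- function(query, panels, reference,
                      min_query = 20, max_query = 2000,
                      bonferroni_alpha = 0.05, nominal_p = 1e-3) {
  stopifnot(inherits(reference, "tag_reference"))
  panels <- as_panel_list(panels)

  syms <- unique(normalize_symbols(as.character(query)))
  syms <- syms[nzchar(syms)]
  n_input <- length(syms)
  assert_that(n_input >= 1, "empty query gene list")
  if (n_input < min_query || n_input > max_query) {
    warning("query has ", n_input, " unique genes; lengths between ",
            min_query, " and ", max_query, " are suggested", call. = FALSE)
  }

  per_panel <- purrr::map(panels, function(sp) query_panel(syms, sp))
  raw <- dplyr::bind_rows(per_panel)
  raw <- dplyr::left_join(tc_table(panels), raw,
                          by = c("tc_id", "cell_type"))
  raw$n_mapped <- raw$a + raw$b

  missing_tc <- setdiff(raw$tc_id, reference$tc_ids)
  assert_that(length(missing_tc) == 0,
              paste0("reference lacks TC(s): ",
                     paste(utils::head(missing_tc, 5), collapse = ", ")))

  cum_factor <- cumulative_factor(n_input, reference$tag_lengths)
  raw$p_perm <- vapply(seq_len(nrow(raw)), function(i) {
    p_perm(raw$p_raw[i], reference$p_matrix[, raw$tc_id[i]], cum_factor)
  }, 0)
  raw$p_tc <- vapply(raw$p_raw, p_tc, 0, all_tc_p = raw$p_raw)
  comb <- combine_pvalues(raw$p_perm, raw$p_tc)
  raw$chi2_stat <- comb$chi2_stat
  raw$p_combined <- comb$p_combined

  n_tcs <- nrow(raw)
  flags <- annotate_significance(raw$p_combined, n_tcs,
                                 bonferroni_alpha = bonferroni_alpha,
                                 nominal_p = nominal_p)
  raw$bonferroni <- flags$bonferroni
  raw$nominal <- flags$nominal

  out <- raw[lex_order(raw$p_combined, raw$tc_id),
             c("tc_id", "panel_id", "tissue", "organ_system",
               "developmental_stage", "cell_type", "signature_length",
               "n_mapped", "p_raw", "p_perm", "p_tc", "chi2_stat",
               "p_combined", "n_overlap", "overlap", "bonferroni", "nominal")]
  universe_union <- unique(unlist(lapply(panels, `[[`, "universe")))
  attr(out, "n_input") <- n_input
  attr(out, "n_mapped") <- length(intersect(syms, universe_union))
  attr(out, "cumulative_factor") <- cum_factor
  attr(out, "n_tcs") <- n_tcs
  attr(out, "bonferroni_threshold") <- attr(flags, "bonferroni_threshold")
  attr(out, "nominal_threshold") <- attr(flags, "nominal_threshold")
  class(out) <- c("csea_result", class(out))
  out
}

#' Group-level Z-score summaries of enrichment results
#'
#' Converts a p-value column to Z scores with [z_from_p()] and averages them
#' per group (organ system, developmental stage, tissue, ...), alongside the
#' mean signature length per group. Comparing these two columns across
#' groups shows how signature length drives apparent specificity: cell types
#' with longer signatures reach smaller raw p-values for unrelated queries.
#'
#' @param results A tibble with the grouping column, a p-value column and a
#'   `signature_length` column (e.g. a `csea_result`, or several stacked).
#' @param group Name of the grouping column (string).
#' @param p_col Name of the p-value column to convert (default `"p_raw"`).
#' @return Tibble with columns `<group>`, `n`, `mean_z`,
#'   `mean_signature_length`.
#' @export
summarize_by_group <- function(results, group, p_col = "p_raw") {
  assert_that(all(c(group, p_col, "signature_length") %in% names(results)),
              "`results` must contain the grouping, p-value and signature_length columns")
  results |>
    dplyr::mutate(.z = z_from_p(.data[[p_col]])) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_z = mean(.data$.z),
                     mean_signature_length = mean(.data$signature_length),
                     .groups = "drop")
}

#' @export
print.csea_result <- function(x, n = 10, ...) {
  cat("<csea_result> ", attr(x, "n_mapped"), "/", attr(x, "n_input"),
      " query genes mapped; ", attr(x, "n_tcs"), " tissue-cell types; ",
      "cumulative factor ", signif(attr(x, "cumulative_factor"), 3), "\n",
      "  Bonferroni threshold ",
      signif(attr(x, "bonferroni_threshold"), 3), ", nominal ",
      signif(attr(x, "nominal_threshold"), 3), "\n", sep = "")
  NextMethod()
}
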