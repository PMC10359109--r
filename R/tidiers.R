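#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an enrichment result
#'
#' Returns the per-TC table as a plain tibble with the `overlap` list column
#' flattened to a comma-joined `overlap_genes` string, suitable for writing
#' or joining.
#'
#' @param x A `csea_result` from [run_query()].
#' @param ... Unused.
#' @return A tibble, one row per tissue-cell type.
#' @method tidy csea_result
#' @export
tidy.csea_result <- function(x, ...) {
  out <- as_tibble(x)
  out$overlap_genes <- vapply(out$overlap, paste, "", collapse = ",")
  out$overlap <- NULL
  out
}

#' Query-level summary of an enrichment result
#'
#' @param x A `csea_result` from [run_query()].
#' @param ... Unused.
#' @return One-row tibble: `n_input`, `n_mapped`, `cumulative_factor`,
#'   `n_tcs`, `bonferroni_threshold`, `nominal_threshold`, `n_bonferroni`,
#'   `n_nominal`, `top_tc`, `top_p_combined`.
#' @method glance csea_result
#' @export
glance.csea_result <- function(x, ...) {
  tibble(
    n_input = attr(x, "n_input"),
    n_mapped = attr(x, "n_mapped"),
    cumulative_factor = attr(x, "cumulative_factor"),
    n_tcs = attr(x, "n_tcs"),
    bonferroni_threshold = attr(x, "bonferroni_threshold"),
    nominal_threshold = attr(x, "nominal_threshold"),
    n_bonferroni = sum(x$bonferroni),
    n_nominal = sum(x$nominal),
    top_tc = x$tc_id[1],
    top_p_combined = x$p_combined[1]
  )
}
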