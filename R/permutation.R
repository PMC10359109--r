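#' Build a reference of trait-associated gene-set enrichment p-values
#'
#' Runs the raw enrichment test for every reference gene set (TAG,
#' trait-associated gene set) against every tissue-cell type of the supplied
#' signature panels. The resulting p-value matrix is the empirical null
#' against which query p-values are ranked: TAGs from genetic studies of many
#' traits have only moderate cell-type specificity, so their enrichment
#' p-values per TC form a biologically meaningful reference distribution.
#'
#' @param tag_sets Named list of character vectors (gene sets), e.g. from
#'   [read_gmt()] or [simulate_tags()].
#' @param panels A `signature_panel` or list of them.
#' @param min_len,max_len Inclusive length bounds applied to the sets before
#'   use (defaults 20 and 2000).
#' @return A `tag_reference`: list with `tag_sets`, `tag_lengths`,
#'   `p_matrix` (TAGs x TCs, entries in (0, 1]), `tc_ids`, `tc_info`
#'   (a [tc_table()]), `n_tags`.
#' @export
build_reference <- function(tag_sets, panels, min_len = 20, max_len = 2000) {
  assert_that(length(tag_sets) > 0, "empty TAG collection")
  panels <- as_panel_list(panels)
  tag_sets <- lapply(tag_sets, function(g) unique(normalize_symbols(g)))
  tag_sets <- filter_tag_length(tag_sets, min_len = min_len, max_len = max_len)
  assert_that(length(tag_sets) > 0, "no TAG passes the length filter")
  lens <- lengths(tag_sets)

  cols <- lapply(panels, function(sp) {
    uni <- sp$universe
    N <- length(uni)
    membership <- vapply(tag_sets, function(g) uni %in% g,
                         logical(N))           # genes x tags
    n_mapped <- colSums(membership)
    sapply(sp$signatures, function(sig) {
      in_sig <- uni %in% sig
      K <- sum(in_sig)
      a <- colSums(membership[in_sig, , drop = FALSE])
      ifelse(n_mapped == 0, 1,
             stats::phyper(a - 1, K, N - K, n_mapped, lower.tail = FALSE))
    })
  })
  p_matrix <- do.call(cbind, cols)
  info <- tc_table(panels)
  colnames(p_matrix) <- info$tc_id
  rownames(p_matrix) <- names(tag_sets)
  structure(
    list(tag_sets = tag_sets, tag_lengths = lens, p_matrix = p_matrix,
         tc_ids = info$tc_id, tc_info = info, n_tags = length(tag_sets)),
    class = "tag_reference"
  )
}

#' @export
print.tag_reference <- function(x, ...) {
  cat("<tag_reference> ", x$n_tags, " reference gene sets x ",
      length(x$tc_ids), " tissue-cell types; set lengths ",
      min(x$tag_lengths), "-", max(x$tag_lengths), "\n", sep = "")
  invisible(x)
}

#' Cumulative length factor
#'
#' The proportion of reference gene sets at least as long as the query list.
#' It multiplies the rank-based permutation p-value to adjust for the length
#' difference between the query and the reference sets. A factor of zero
#' (query longer than every reference set) is floored at `1/n_tags` with a
#' warning so the adjusted p-value stays positive.
#'
#' @param query_len Length of the input gene list (>= 1).
#' @param tag_lengths Integer vector of reference set lengths.
#' @return A number in (0, 1].
#' @examples
#' cumulative_factor(60, c(20, 50, 100, 200))  # 0.5
#' @export
cumulative_factor <- function(query_len, tag_lengths) {
  assert_that(query_len >= 1, "`query_len` must be >= 1")
  assert_that(length(tag_lengths) > 0, "`tag_lengths` must be non-empty")
  f <- sum(tag_lengths >= query_len) / length(tag_lengths)
  if (f == 0) {
    warning("query longer than every reference set; ",
            "cumulative factor floored at 1/n_tags", call. = FALSE)
    f <- 1 / length(tag_lengths)
  }
  f
}

#' Rank-based permutation p-value
#'
#' Ranks a raw enrichment p-value within the reference p-values of one
#' tissue-cell type and scales by the cumulative length factor:
#' `min(1, max(1, #\{ref <= p_raw\}) / n_ref * factor)`. The tie-inclusive
#' count keeps the result a valid empirical p-value bounded below by
#' `1/n_ref`.
#'
#' @param p_raw Raw enrichment p-value(s).
#' @param ref_column Reference p-values for the same tissue-cell type.
#' @param factor Cumulative length factor in (0, 1] from
#'   [cumulative_factor()].
#' @return Numeric vector like `p_raw`, values in (0, 1].
#' @export
p_perm <- function(p_raw, ref_column, factor = 1) {
  assert_that(length(ref_column) > 0, "`ref_column` must be non-empty")
  assert_that(factor > 0 && factor <= 1, "`factor` must be in (0, 1]")
  r <- vapply(p_raw, function(p) max(1L, sum(ref_column <= p)), 0L)
  pmin(1, r / length(ref_column) * factor)
}

#' Cross-cell-type rank p-value
#'
#' Ranks the query's raw p-value in cell type i within the query's own raw
#' p-values across every tested cell type (including i itself):
#' `#\{p <= p_raw_i\} / n_tcs`.
#'
#' @param p_raw_i Raw p-value of the focal cell type.
#' @param all_tc_p The query's raw p-values across all cell types; must
#'   contain `p_raw_i`.
#' @return A number in (0, 1].
#' @export
p_tc <- function(p_raw_i, all_tc_p) {
  assert_that(any(all_tc_p == p_raw_i),
              "`all_tc_p` must contain the focal `p_raw_i`")
  sum(all_tc_p <= p_raw_i) / length(all_tc_p)
}

#' Combine the two rank p-values by Fisher's method
#'
#' `chi2_stat = -2 ln(p_perm * p_tc)` referred to a chi-squared distribution
#' with 4 (= 2 x 2) degrees of freedom; in closed form the combined p-value
#' is `(p_perm * p_tc) * (1 - ln(p_perm * p_tc))`.
#'
#' @param p_perm,p_tc Numeric vectors of p-values in (0, 1].
#' @return List with numeric vectors `chi2_stat` and `p_combined`.
#' @examples
#' combine_pvalues(0.5, 0.5)  # chi2 ~ 2.77, p ~ 0.597
#' @export
combine_pvalues <- function(p_perm, p_tc) {
  assert_that(all(p_perm > 0 & p_perm <= 1) && all(p_tc > 0 & p_tc <= 1),
              "p-values must be in (0, 1]")
  chi2 <- -2 * log(p_perm * p_tc)
  list(chi2_stat = chi2,
       p_combined = stats::pchisq(chi2, df = 4, lower.tail = FALSE))
}

#' Convert p-values to Z scores
#'
#' `z = qnorm(1 - p)`, the standard-normal quantile of the upper cumulative
#' probability: small p-values map to large positive Z. Values at 0 or 1 are
#' clamped into the open unit interval with a warning.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of Z scores.
#' @export
z_from_p <- function(p) {
  assert_that(all(p >= 0 & p <= 1), "p-values must be in [0, 1]")
  eps <- .Machine$double.xmin
  if (any(p <= 0 | p >= 1)) {
    warning("p-values at 0 or 1 clamped into the open unit interval",
            call. = FALSE)
    p <- pmin(1 - .Machine$double.eps / 2, pmax(eps, p))
  }
  stats::qnorm(p, lower.tail = FALSE)
}

#' Flag enrichment significance
#'
#' Two thresholds on the combined p-value, both strict: Bonferroni
#' (`bonferroni_alpha / n_tcs`, e.g. 0.05 / 1355 = 3.69e-5) and nominal
#' (default 1e-3).
#'
#' @param p_combined Numeric vector of combined p-values.
#' @param n_tcs Number of tissue-cell types tested.
#' @param bonferroni_alpha Family-wise alpha before correction (default
#'   0.05).
#' @param nominal_p Nominal threshold (default 1e-3).
#' @return Tibble with logical columns `bonferroni` and `nominal`; the
#'   resolved thresholds are attached as attributes `bonferroni_threshold`
#'   and `nominal_threshold`.
#' @export
annotate_significance <- function(p_combined, n_tcs,
                                  bonferroni_alpha = 0.05, nominal_p = 1e-3) {
  assert_that(n_tcs >= 1, "`n_tcs` must be >= 1")
  assert_that(bonferroni_alpha > 0 && bonferroni_alpha < 1 &&
                nominal_p > 0 && nominal_p < 1,
              "thresholds must be in (0, 1)")
  thr <- bonferroni_alpha / n_tcs
  out <- tibble(bonferroni = p_combined < thr, nominal = p_combined < nominal_p)
  attr(out, "bonferroni_threshold") <- thr
  attr(out, "nominal_threshold") <- nominal_p
  out
}
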