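#' Simulate a single-cell panel with planted cell-type markers
#'
#' Baseline counts are drawn from a negative-binomial model (the usual model
#' for sparse scRNA-seq count marginals); each cell type gets a disjoint
#' block of planted marker genes whose negative-binomial mean is multiplied
#' by `effect_size` in that cell type's cells only. The planted assignments
#' and every generator parameter are returned so fixtures are exactly
#' regenerable from `(parameters, seed)` and recovery can be scored against
#' truth.
#'
#' @param n_genes Total number of genes.
#' @param cell_types Named integer vector: cells per cell type (each >= 2).
#' @param n_markers_per_tc Planted markers per cell type;
#'   `n_markers_per_tc * n_types` must not exceed `n_genes`.
#' @param effect_size Multiplicative effect on the negative-binomial mean of
#'   a marker gene in its own cell type (default 4; 1 plants no signal).
#' @param baseline_mean,dispersion Negative-binomial baseline: mean of a
#'   non-marker gene (default 0.5) and dispersion (default 0.3; the
#'   `size` parameter is `1/dispersion`).
#' @param seed Integer seed; the generator is fully reproducible given it.
#' @param panel_id,tissue,organ_system,developmental_stage Metadata passed
#'   to [expression_panel()].
#' @return List with `panel` (an [expression_panel()]) and `truth` (a
#'   `synthetic_truth`: `marker_of` — named list of planted marker genes per
#'   cell type — plus all generator parameters and the seed).
#' @examples
#' sim <- simulate_panel(200, c(A = 10, B = 10), n_markers_per_tc = 5,
#'                       seed = 1)
#' sim$truth$marker_of$A
#' @export
simulate_panel <- function(n_genes, cell_types, n_markers_per_tc,
                           effect_size = 4, baseline_mean = 0.5,
                           dispersion = 0.3, seed = 1,
                           panel_id = "synthetic_panel",
                           tissue = "synthetic_tissue",
                           organ_system = "synthetic_system",
                           developmental_stage = "unspecified") {
  assert_that(!is.null(names(cell_types)) && all(cell_types >= 2),
              "`cell_types` must be a named vector with >= 2 cells per type")
  n_types <- length(cell_types)
  assert_that(n_markers_per_tc * n_types <= n_genes,
              "marker allocation infeasible: n_markers_per_tc * n_types > n_genes")
  assert_that(effect_size >= 0 && baseline_mean > 0 && dispersion > 0,
              "effect_size must be >= 0; baseline_mean and dispersion > 0")

  genes <- sprintf("SGENE%05d", seq_len(n_genes))
  cells <- sprintf("cell%05d", seq_len(sum(cell_types)))
  labels <- rep(names(cell_types), cell_types)

  marker_of <- split(
    genes[seq_len(n_markers_per_tc * n_types)],
    rep(names(cell_types), each = n_markers_per_tc)
  )[names(cell_types)]

  mu <- matrix(baseline_mean, n_genes, length(cells),
               dimnames = list(genes, cells))
  for (tc in names(cell_types)) {
    mu[marker_of[[tc]], labels == tc] <- baseline_mean * effect_size
  }

  counts <- withr::with_seed(seed, {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
           n_genes, length(cells), dimnames = dimnames(mu))
  })

  panel <- expression_panel(counts,
                            stats::setNames(labels, cells),
                            panel_id = panel_id, tissue = tissue,
                            organ_system = organ_system,
                            developmental_stage = developmental_stage)
  truth <- structure(
    list(marker_of = marker_of, effect_size = effect_size,
         baseline_model = list(mean = baseline_mean, dispersion = dispersion),
         n_genes = n_genes, cell_types = cell_types,
         n_markers_per_tc = n_markers_per_tc, seed = seed),
    class = "synthetic_truth"
  )
  list(panel = panel, truth = truth)
}

#' Log-uniform sampler over an integer range
#'
#' The default length sampler for [simulate_tags()]: uniform on the log
#' scale over `[min_len, max_len]`, covering the 20-2000 range of
#' trait-associated gene sets without concentrating at either end.
#'
#' @param min_len,max_len Inclusive integer bounds.
#' @return A function of `n` returning `n` integer lengths.
#' @export
log_uniform_lengths <- function(min_len = 20, max_len = 2000) {
  assert_that(min_len >= 1 && min_len <= max_len, "bounds must be ordered")
  function(n) {
    as.integer(round(exp(stats::runif(n, log(min_len), log(max_len)))))
  }
}

#' Simulate reference trait-associated gene sets
#'
#' Null sets are uniform draws without replacement from the universe, with
#' lengths from `length_sampler` truncated to the universe size. An optional
#' `enrichment_spec` mixes a stated fraction of one cell type's signature
#' genes into every set, emulating the moderate cell-type specificity of
#' real trait-associated gene sets.
#'
#' @param n_tags Number of sets to generate.
#' @param universe Character vector of gene symbols to draw from.
#' @param length_sampler Function of `n` returning integer lengths (default
#'   [log_uniform_lengths()]).
#' @param enrichment_spec Optional `list(signature = <character>, fraction =
#'   <0..1>)`: each set takes `round(fraction * length)` genes from
#'   `signature` and the rest from the remaining universe.
#' @param seed Integer seed.
#' @return Named list of gene-set character vectors
#'   (`TAG00001`, `TAG00002`, ...).
#' @export
simulate_tags <- function(n_tags, universe,
                          length_sampler = log_uniform_lengths(),
                          enrichment_spec = NULL, seed = 1) {
  assert_that(n_tags >= 0, "`n_tags` must be >= 0")
  universe <- unique(normalize_symbols(universe))
  if (n_tags == 0) return(stats::setNames(list(), character()))
  if (!is.null(enrichment_spec)) {
    assert_that(is.list(enrichment_spec) &&
                  all(c("signature", "fraction") %in% names(enrichment_spec)),
                "`enrichment_spec` needs elements `signature` and `fraction`")
    assert_that(all(enrichment_spec$signature %in% universe),
                "`enrichment_spec$signature` must lie in the universe")
  }
  withr::with_seed(seed, {
    lens <- length_sampler(n_tags)
    assert_that(all(lens >= 1),
                "length_sampler produced non-positive lengths")
    assert_that(all(lens <= length(universe)),
                "requested set length exceeds the universe size")
    sets <- lapply(lens, function(L) {
      if (is.null(enrichment_spec)) {
        sample(universe, L)
      } else {
        sig <- enrichment_spec$signature
        k <- min(round(enrichment_spec$fraction * L), length(sig), L)
        c(sample(sig, k), sample(setdiff(universe, sig), L - k))
      }
    })
    stats::setNames(sets, sprintf("TAG%05d", seq_len(n_tags)))
  })
}

#' Filter gene sets by length
#'
#' Keeps exactly the sets whose size lies in `[min_len, max_len]`
#' (inclusive), the standard 20-2000 bound on trait-associated gene sets,
#' and reports how many were removed on each side.
#'
#' @param tags Named list of gene-set character vectors.
#' @param min_len,max_len Inclusive bounds (defaults 20 and 2000).
#' @return The filtered named list.
#' @examples
#' tags <- lapply(c(19, 20, 2000, 2001), function(n) paste0("G", 1:n))
#' names(tags) <- paste0("S", 1:4)
#' names(filter_tag_length(tags))
#' @export
filter_tag_length <- function(tags, min_len = 20, max_len = 2000) {
  assert_that(min_len <= max_len, "`min_len` must be <= `max_len`")
  lens <- lengths(tags)
  too_short <- sum(lens < min_len)
  too_long <- sum(lens > max_len)
  if (too_short + too_long > 0) {
    message("length filter [", min_len, ", ", max_len, "]: removed ",
            too_short, " too-short and ", too_long, " too-long set(s); ",
            sum(lens >= min_len & lens <= max_len), " retained")
  }
  tags[lens >= min_len & lens <= max_len]
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> ", length(x$marker_of), " cell types x ",
      x$n_markers_per_tc, " planted markers; effect x", x$effect_size,
      "; NB(mean ", x$baseline_model$mean, ", dispersion ",
      x$baseline_model$dispersion, "); seed ", x$seed, "\n", sep = "")
  invisible(x)
}
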