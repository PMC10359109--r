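# deterministic hand-built panel: 6 genes x 9 cells, three cell types
tiny_counts <- function() {
  m <- rbind(
    GA = c(9L, 8L, 7L, 0L, 1L, 0L, 0L, 0L, 1L),  # elevated in type "a"
    GB = c(0L, 1L, 0L, 9L, 7L, 8L, 1L, 0L, 0L),  # elevated in type "b"
    GC = c(0L, 0L, 1L, 0L, 1L, 0L, 8L, 9L, 7L),  # elevated in type "c"
    GD = c(2L, 3L, 2L, 2L, 3L, 2L, 2L, 3L, 2L),  # flat
    GE = c(1L, 0L, 2L, 1L, 0L, 2L, 1L, 0L, 2L),  # flat
    GF = c(5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L)   # constant
  )
  colnames(m) <- paste0("cell", 1:9)
  m
}

tiny_labels <- function() {
  stats::setNames(rep(c("a", "b", "c"), each = 3), paste0("cell", 1:9))
}

tiny_panel <- function() {
  expression_panel(tiny_counts(), tiny_labels(), panel_id = "tiny",
                   tissue = "toy", organ_system = "toy_system")
}

# signature panel on a small simulated dataset, filters relaxed for size
small_signature_panel <- function(seed = 42, n_genes = 400,
                                  cell_types = c(A = 35, B = 35, C = 35),
                                  top_fraction = 0.05) {
  sim <- simulate_panel(n_genes = n_genes, cell_types = cell_types,
                        n_markers_per_tc = 10, effect_size = 4, seed = seed)
  sp <- suppressMessages(
    build_signature_panel(sim$panel, top_fraction = top_fraction,
                          min_cells_per_type = 30, gene_min_cells = 0,
                          gene_min_fraction = 0))
  list(sp = sp, truth = sim$truth)
}

# exhaustive hypergeometric oracle: enumerate every draw of size n from the
# universe and count those overlapping the signature in >= a genes
enum_upper_tail <- function(N, K, n, a) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= a)
}
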