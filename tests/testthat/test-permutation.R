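test_that("reference p-matrix has the right shape and matches per-pair recomputation", {
  fx <- small_signature_panel()
  tags <- simulate_tags(10, fx$sp$universe,
                        log_uniform_lengths(20, 100), seed = 3)
  ref <- build_reference(tags, fx$sp)
  expect_equal(dim(ref$p_matrix), c(10, 3))
  expect_true(all(ref$p_matrix > 0 & ref$p_matrix <= 1))
  expect_identical(colnames(ref$p_matrix), ref$tc_ids)
  for (t in names(tags)) {
    for (i in seq_along(fx$sp$signatures)) {
      expect_equal(ref$p_matrix[t, i],
                   csea_raw(tags[[t]], fx$sp$signatures[[i]],
                            fx$sp$universe)$p_raw,
                   tolerance = 1e-12)
    }
  }
  expect_error(build_reference(list(), fx$sp), "empty TAG collection")
})

test_that("a reference set disjoint from every signature scores 1 everywhere", {
  fx <- small_signature_panel()
  sigs <- unique(unlist(fx$sp$signatures))
  off <- setdiff(fx$sp$universe, sigs)[1:25]
  ref <- build_reference(list(DISJOINT = off, SOME = sigs[1:30]), fx$sp,
                         min_len = 20, max_len = 2000)
  expect_true(all(ref$p_matrix["DISJOINT", ] == 1))
  expect_true(any(ref$p_matrix["SOME", ] < 1))
})

test_that("cumulative factor is the proportion of at-least-as-long reference sets", {
  expect_equal(cumulative_factor(10, c(20, 50, 100, 200)), 1)
  expect_equal(cumulative_factor(60, c(20, 50, 100, 200)), 0.5)
  expect_warning(f <- cumulative_factor(500, c(20, 50, 100, 200)), "floored")
  expect_equal(f, 1 / 4)
})

test_that("permutation p-value is the clamped tie-inclusive rank times the factor", {
  ref <- c(0.01, 0.1, 0.5, 0.9)
  expect_equal(p_perm(0.001, ref, 1), 0.25)  # below all -> rank clamped to 1
  expect_equal(p_perm(0.05, ref, 1), 0.25)   # one reference value <= 0.05
  expect_equal(p_perm(1, ref, 1), 1)         # rank = |ref|
  expect_equal(p_perm(1, ref, 0.3), 0.3)     # p_raw = 1 -> result = factor
  expect_equal(p_perm(c(0.05, 0.6), ref, 0.5), c(0.125, 0.375))
})

test_that("cross-TC rank p-value counts ties inclusively", {
  expect_equal(p_tc(0.001, c(0.001, 0.3, 0.4, 0.5, 0.9)), 1 / 5)
  expect_equal(p_tc(0.2, c(0.2, 0.2, 0.2)), 1)          # full ties
  expect_equal(p_tc(0.2, c(0.001, 0.2, 0.2, 0.9)), 3 / 4)
  expect_error(p_tc(0.15, c(0.001, 0.2)), "must contain")
})

test_that("Fisher combination matches the 4-df closed form", {
  both_half <- combine_pvalues(0.5, 0.5)
  expect_equal(both_half$chi2_stat, -2 * log(0.25))
  expect_equal(both_half$p_combined, 0.25 * (1 + log(4)), tolerance = 1e-12)

  ones <- combine_pvalues(1, 1)
  expect_equal(ones$chi2_stat, 0)
  expect_equal(ones$p_combined, 1)

  grid <- expand.grid(p1 = c(1e-8, 1e-4, 0.01, 0.2, 0.5, 0.99, 1),
                      p2 = c(1e-6, 0.03, 0.5, 1))
  got <- combine_pvalues(grid$p1, grid$p2)
  q <- grid$p1 * grid$p2
  expect_equal(got$p_combined, q * (1 - log(q)), tolerance = 1e-12)
  expect_error(combine_pvalues(0, 0.5), "in \\(0, 1\\]")
})

test_that("the combined p-value decreases when either input decreases", {
  ps <- c(1, 0.5, 0.1, 0.01, 1e-4)
  for (fixed in c(1, 0.3)) {
    expect_true(all(diff(combine_pvalues(ps, fixed)$p_combined) < 0))
    expect_true(all(diff(combine_pvalues(fixed, ps)$p_combined) < 0))
  }
})

test_that("Z conversion is the upper-tail normal quantile", {
  expect_equal(z_from_p(0.5), 0)
  expect_equal(z_from_p(0.025), stats::qnorm(0.975), tolerance = 1e-12)
  expect_warning(z1 <- z_from_p(1), "clamped")
  expect_true(is.finite(z1) && z1 < -8)
})

test_that("significance thresholds are strict and scale with the number of TCs", {
  flags <- annotate_significance(c(3.68e-5, 3.7e-5, 5e-4, 2e-3), n_tcs = 1355)
  expect_identical(flags$bonferroni, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(flags$nominal, c(TRUE, TRUE, TRUE, FALSE))
  thr <- attr(flags, "bonferroni_threshold")
  expect_equal(thr, 0.05 / 1355)
  # p exactly at the threshold is not flagged
  at <- annotate_significance(thr, n_tcs = 1355)
  expect_false(at$bonferroni)
  expect_equal(attr(annotate_significance(0.2, 1), "bonferroni_threshold"),
               0.05)
})

test_that("run_query ranks the planted cell type first and flags consistently", {
  fx <- small_signature_panel()
  tags <- simulate_tags(60, fx$sp$universe,
                        log_uniform_lengths(20, 200), seed = 5)
  ref <- build_reference(tags, fx$sp)
  res <- run_query(fx$sp$signatures$B, fx$sp, ref)
  expect_s3_class(res, "csea_result")
  expect_equal(res$tc_id[1], "synthetic_panel|B")
  expect_true(all(res$p_perm > 0 & res$p_perm <= 1))
  expect_true(all(res$p_tc > 0 & res$p_tc <= 1))
  expect_equal(res$chi2_stat, -2 * log(res$p_perm * res$p_tc))
  expect_true(!is.unsorted(res$p_combined))
  expect_identical(res$bonferroni,
                   res$p_combined < 0.05 / attr(res, "n_tcs"))
})

test_that("a query disjoint from every signature gets no significance flag", {
  fx <- small_signature_panel()
  off <- setdiff(fx$sp$universe, unique(unlist(fx$sp$signatures)))[1:30]
  tags <- simulate_tags(60, fx$sp$universe,
                        log_uniform_lengths(20, 200), seed = 6)
  ref <- build_reference(tags, fx$sp)
  res <- run_query(off, fx$sp, ref)
  expect_true(all(res$p_raw == 1))
  expect_false(any(res$bonferroni) || any(res$nominal))
})

test_that("run_query is invariant to panel order up to row order", {
  fx1 <- small_signature_panel(seed = 21)
  sim2 <- simulate_panel(n_genes = 300, cell_types = c(D = 35, E = 35),
                         n_markers_per_tc = 8, effect_size = 4, seed = 22,
                         panel_id = "second_panel")
  sp2 <- suppressMessages(
    build_signature_panel(sim2$panel, gene_min_cells = 0,
                          gene_min_fraction = 0))
  tags <- simulate_tags(80, union(fx1$sp$universe, sp2$universe),
                        log_uniform_lengths(20, 200), seed = 23)
  ref12 <- build_reference(tags, list(fx1$sp, sp2))
  ref21 <- build_reference(tags, list(sp2, fx1$sp))
  qry <- fx1$sp$signatures$A
  r12 <- run_query(qry, list(fx1$sp, sp2), ref12)
  r21 <- run_query(qry, list(sp2, fx1$sp), ref21)
  expect_equal(nrow(r12), 5)
  r21 <- r21[match(r12$tc_id, r21$tc_id), ]
  expect_equal(as.data.frame(r12), as.data.frame(r21))
})

test_that("reference columns are matched by tc_id, not position", {
  fx <- small_signature_panel()
  tags <- simulate_tags(40, fx$sp$universe,
                        log_uniform_lengths(20, 100), seed = 8)
  ref <- build_reference(tags, fx$sp)
  shuffled <- ref
  perm <- c(3, 1, 2)
  shuffled$p_matrix <- shuffled$p_matrix[, perm]
  shuffled$tc_ids <- shuffled$tc_ids[perm]
  a <- run_query(fx$sp$signatures$C, fx$sp, ref)
  b <- run_query(fx$sp$signatures$C, fx$sp, shuffled)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("factor-free permutation p-values satisfy the empirical validity bound", {
  fx <- small_signature_panel(seed = 31)
  sampler <- log_uniform_lengths(20, 150)
  tags <- simulate_tags(200, fx$sp$universe, sampler, seed = 32)
  ref <- build_reference(tags, fx$sp)
  queries <- simulate_tags(300, fx$sp$universe, sampler, seed = 33)
  praw <- vapply(queries, function(q) query_panel(q, fx$sp)$p_raw,
                 numeric(3))
  for (i in 1:3) {
    pp <- p_perm(praw[i, ], ref$p_matrix[, ref$tc_ids[i]], factor = 1)
    for (alpha in c(0.05, 0.1, 0.25)) {
      expect_lte(mean(pp <= alpha), alpha + 1 / ref$n_tags + 0.06)
    }
  }
})

test_that("group summaries average Z scores and signature lengths", {
  df <- tibble::tibble(
    organ_system = c("s1", "s1", "s2"),
    p_raw = c(0.5, 0.025, 0.5),
    signature_length = c(100, 200, 50)
  )
  out <- summarize_by_group(df, "organ_system")
  expect_equal(out$mean_z[out$organ_system == "s1"],
               mean(c(0, stats::qnorm(0.975))))
  expect_equal(out$mean_signature_length, c(150, 50))
})
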