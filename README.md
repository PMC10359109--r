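# ctsea — cell-type-specific enrichment analysis of gene lists

`ctsea` answers a question that comes up constantly in human genetics and
functional genomics: *given a list of genes — from a GWAS, a rare-variant
screen, a differential-expression study — which tissue-cell types (TCs)
specifically express them?* It is aimed at analysts who have annotated
single-cell RNA-seq panels on one side and gene lists on the other, and who
want a calibrated, length-bias-adjusted enrichment p-value per tissue-cell
type rather than a raw over-representation test.

## The method

**Signatures.** For each tissue panel, counts are log2-CPM normalized
(`log2(counts / libsize * 1e6 + 1)`), cell types with fewer than 30 cells
and lowly expressed genes are dropped, and every gene *g* is scored against
every cell type *j* with the t-statistic of the indicator coefficient in the
per-cell regression

    expr_g ~ intercept + 1{cell ∈ j}

(equivalently a pooled-variance one-vs-rest two-sample t). The top 5% of
genes by t-statistic form cell type *j*'s signature; the retained genes form
the panel's background universe.

**Raw enrichment.** A query list mapped into the universe is tested against
each signature with the one-sided hypergeometric upper tail
P(X ≥ a) — Fisher's exact test for enrichment on the 2×2 table
(overlap *a*; query size *n*; signature size *K*; universe size *N*).

**Permutation adjustment.** Raw p-values are biased by signature and query
length. Both are adjusted by ranking against a reference of trait-associated
gene sets (TAGs; lengths restricted to 20–2000) whose raw enrichment
p-values are precomputed for every TC:

    p_perm(i) = rank(p_raw(i), reference p-values of TC i) / n_tags × cumulative_factor
    p_tc(i)   = rank(p_raw(i), the query's p_raw across all TCs) / n_tcs
    chi2(i)   = −2 ln(p_perm(i) · p_tc(i))  ~  χ²₄

where the cumulative factor is the proportion of reference sets at least as
long as the query. The combined p-value is the χ² upper tail with 4 (= 2·2)
degrees of freedom, in closed form `q(1 − ln q)` with
`q = p_perm · p_tc`. Results are flagged at Bonferroni
(`0.05 / n_tcs`; 3.69 × 10⁻⁵ for the 1,355-TC scale) and nominal
(10⁻³) significance.

## Worked example

Everything below is fully synthetic and reproducible (no downloads): a
liver-like panel with four cell types and 20 planted marker genes each, a
reference of 500 random gene sets, and a query consisting of the 20
hepatocyte markers plus 10 unrelated genes.

```r
library(ctsea)

sim <- simulate_panel(n_genes = 2000,
                      cell_types = c(hepatocyte = 100, kupffer = 100,
                                     stellate = 100, endothelial = 100),
                      n_markers_per_tc = 20, effect_size = 4, seed = 1,
                      panel_id = "liver_demo", tissue = "liver",
                      organ_system = "digestive", developmental_stage = "adult")
sp  <- build_signature_panel(sim$panel)
#> <signature_panel> liver_demo: 4 cell types, universe of 2000 genes,
#>   signature size 100 (top 5%)

tags <- simulate_tags(500, sp$universe, log_uniform_lengths(20, 1500), seed = 2)
ref  <- build_reference(tags, sp)

query <- c(sim$truth$marker_of$hepatocyte, sp$universe[1500:1509])
res   <- run_query(query, sp, ref)
res[, c("tc_id", "p_raw", "p_perm", "p_tc", "p_combined", "n_overlap")]
#>   tc_id                    p_raw  p_perm  p_tc p_combined n_overlap
#> 1 liver_demo|hepatocyte 2.77e-20 0.00179  0.25    0.00389        20
#> 2 liver_demo|kupffer    7.88e- 1 0.633    0.75    0.828           1
#> 3 liver_demo|endothelial 7.88e-1 0.638    0.75    0.831           1
#> 4 liver_demo|stellate   1   e+ 0 0.894    1       0.994           0
```

All 20 planted markers land in the hepatocyte signature (`n_overlap = 20`,
raw p ≈ 3 × 10⁻²⁰). The permutation step is deliberately conservative at
desk scale: the rank p-value cannot go below `1/n_tags × factor`
(here 0.894/500 ≈ 0.0018), and with only 4 TCs the cross-TC rank cannot go
below 0.25 — with the production-scale 19,663 reference sets and 1,355 TCs
the same query would reach far smaller combined p-values. `glance(res)`
returns the query-level summary (30/30 genes mapped, cumulative factor
0.894, Bonferroni threshold 0.05/4 = 0.0125), `tidy(res)` the flat export
table, and `autoplot(res)` the jitter overview with both significance
lines.

A command-line shell over the same functions ships in `inst/cli/`:

```sh
Rscript inst/cli/ctsea.R simulate --out sim --seed 1 --n-tags 200
Rscript inst/cli/ctsea.R build-panel --counts sim/counts.tsv --cells sim/cells.tsv --out panel
Rscript inst/cli/ctsea.R build-reference --tags sim/tags.gmt --panels panel --out ref
Rscript inst/cli/ctsea.R run --genes query.txt --panels panel --reference ref --out out
```

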