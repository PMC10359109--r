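---
title: "Cell-type-specific enrichment: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type-specific enrichment: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctsea)
```

`ctsea` scores a query gene list for specificity to tissue-cell types (TCs)
derived from annotated single-cell RNA-seq panels. This vignette is the
package's account of the statistics it implements: the model at each stage,
the assumptions it rests on, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the places where the design was genuinely open and a choice
had to be made.

## 1. From counts to signatures

A panel is a genes × cells count matrix with one cell-type label per cell.
The derivation pipeline is:

1. **Cell-type filter.** Cell types with fewer than 30 cells are dropped
   (`min_cells_per_type = 30`). The one-vs-rest contrast needs a focal
   group large enough for a stable variance estimate, and at least two
   cell types must survive or there is no contrast at all.
2. **Gene filter.** Genes detected (count > 0) in fewer than
   `max(min_cells, ceiling(min_fraction × n_cells))` cells are removed;
   defaults are 3 cells and 0.1 % of cells. The threshold is deliberately
   mild: its purpose is to keep the t-statistics well-conditioned (a gene
   seen in two cells has essentially no within-group variance
   information), not to shape the universe. The retained genes form the
   panel's **universe**, the population of every downstream 2×2 table.
3. **Normalization.** `log2(CPM + 1)`: each cell is scaled to a library
   size of 10⁶ and log-transformed. Cells with zero total count are
   rejected by name rather than silently dropped — they indicate an
   upstream problem.
4. **t-statistics.** For gene *g* and cell type *j* we fit, by ordinary
   least squares over all cells of the panel,
   `expr_g ~ intercept + 1{cell ∈ j}` and keep the t-statistic of the
   indicator. This is algebraically the pooled-variance two-sample
   t-statistic (focal cells vs all others) with `n − 2` degrees of
   freedom; the test suite verifies the equivalence against independent
   `lm()` fits per gene. Cells are the observations — we regress over the
   single-cell matrix, not over per-cell-type mean profiles, so large cell
   types contribute more information. No further covariates (library
   size, batch) enter the model; the normalization is assumed to have
   absorbed depth differences.
5. **Signature selection.** Per cell type, the signature is the
   `max(1, floor(top_fraction × |universe|))` genes with the largest
   t-statistic; `top_fraction = 0.05` (the top 5 %). The fraction applies
   to the *post-filter* universe, since that is the population the
   enrichment test sees. Selection happens after filtering so that the
   signature and its background are derived from the same gene set.

### Numerical edge rules

* Zero pooled residual variance (e.g. a gene constant in every cell) gives
  t = 0, keeping the matrix finite and the gene neutral.
* Ties at the top-5 % cutoff are broken by lexicographic gene symbol, in
  the C locale (`method = "radix"`), so a signature is a pure function of
  its inputs on every platform.
* `floor` with a clamp to one gene: a 10-gene universe still yields a
  1-gene signature rather than an empty one.
* Gene symbols are upper-cased and whitespace-stripped on ingest; when two
  rows collapse to one symbol, the row with the larger total count wins
  and the collision is reported.

## 2. The raw enrichment test

A query mapped into the universe is tested per signature with the
hypergeometric upper tail P(X ≥ a) (population *N* = universe, successes
*K* = signature, draws *n* = mapped query, observed overlap *a*) — the
one-sided Fisher's exact test of the 2×2 table, computed with
`stats::phyper`. Genes outside the universe are dropped before testing and
reported (`n_input` vs `n_mapped`). An unmappable query is a defined
result (p = 1 with a warning), not an exception, so batch runs degrade
gracefully.

The background universe is **per panel**: signatures are defined relative
to the genes retained in their own panel, so the 2×2 margins use that same
population. The alternative — one global symbol list shared by all panels —
would make margins comparable across panels at the cost of counting genes
a panel never measured; with per-panel universes, a query gene absent from
a small panel simply does not enter that panel's table. The group-level
bias analysis below shows the consequence of this choice deliberately.

## 3. The permutation layer

Raw over-representation p-values are not comparable across TCs or queries:
longer signatures and longer queries reach smaller p-values for purely
combinatorial reasons. The adjustment uses a reference collection of
trait-associated gene sets (TAGs) — in production use, gene sets from
thousands of GWAS and rare-variant association studies, with lengths
restricted to the inclusive range 20–2000 — whose raw enrichment p-values
are precomputed for every TC (`build_reference()`). Because such sets have
only moderate cell-type specificity, their p-value distribution per TC is
a biologically meaningful null: a query is interesting if it outranks most
trait-associated sets *in that TC*, not if it merely beats uniform
sampling.

For TC *i*:

* `p_perm(i) = rank(p_raw(i), reference column i) / n_tags × cumulative_factor`,
  with `rank` the tie-inclusive count `#{p_ref ≤ p_raw}` clamped to ≥ 1.
  The clamp bounds the result in `[1/n_tags, 1]`; ties counted inclusively
  keep it a valid (conservative) empirical p-value.
* The **cumulative factor** is the proportion of reference sets at least
  as long as the query (the query length is taken as the number of unique
  input symbols, before universe mapping, since it adjusts for the length
  of the *input list*). It is computed once per query. A factor of zero —
  a query longer than every reference set — is floored at `1/n_tags` with
  a warning so the product stays positive. As defined, longer queries
  receive a *smaller* factor and hence smaller adjusted p-values; the
  formula is implemented exactly as stated even though this direction is
  debatable (see §5).
* `p_tc(i) = #{p_raw(j) ≤ p_raw(i), all TCs j} / n_tcs`, the query's own
  cross-TC rank, including TC *i* itself — so no clamp is needed and a
  uniquely best TC scores `1/n_tcs`.
* Fisher's method combines the two:
  `chi2 = −2 ln(p_perm · p_tc)` referred to χ² with 2 × 2 = 4 degrees of
  freedom, in closed form `p_combined = q (1 − ln q)`, `q = p_perm · p_tc`.
  The acceptance suite checks the implementation against this closed form
  at 10⁻¹² over a wide grid.

Significance is flagged strictly below two thresholds: Bonferroni
`0.05 / n_tcs` (3.69 × 10⁻⁵ at the production scale of 1,355 TCs) and
nominal 10⁻³. Z-score summaries use `z = Φ⁻¹(1 − p)`; exact 0/1 inputs
are clamped to the machine-representable open interval with a warning.

## 4. What the generator simulates — and what it does not

`simulate_panel()` draws baseline counts from a negative binomial with
mean 0.5 and dispersion 0.3 (`size = 1/dispersion`), typical of the sparse
marginals of droplet scRNA-seq, and multiplies the mean of each planted
marker gene by `effect_size` (default 4) in its own cell type only. Marker
sets are disjoint across cell types, and all parameters plus the seed are
recorded in the returned truth object, so any fixture is exactly
regenerable and recovery is scoreable. `simulate_tags()` draws null
reference sets uniformly without replacement, with lengths log-uniform on
[20, 2000] (intersected with the universe size) — covering the whole
allowed range without piling up at either end; an optional mixing fraction
toward one signature emulates moderately specific trait gene sets.

The generator intentionally omits ambient RNA, doublets, batch effects,
cell-type abundance gradients within a label, and correlated gene modules.
Passing tests therefore demonstrate that the pipeline recovers signal of
the planted form under clean NB noise — they do not certify behaviour
under real-data artifacts, which panel curation is assumed to have handled
upstream.

Default experiment sizes used throughout the tests and the acceptance
script — a 1,200-gene, 4 × 50-cell panel with a 1,000-set reference and
500 null queries for calibration; a 2,000-gene, 4 × 100-cell panel with 20
markers per type and effect 4 for recovery; four panels of 400–3,200 genes
sharing a 4,000-gene global space with 200 null queries for the bias
analysis — were chosen as the smallest designs at which each property is
comfortably identifiable; all of them run in seconds.

## 5. Calibration: what is uniform and what deliberately is not

Under the null (queries drawn by the same generator as the reference
sets), the rank transform `rank/n_tags` is uniform by exchangeability of
the query with the reference draws, up to two discreteness effects, and
the acceptance suite verifies per-TC Kolmogorov–Smirnov uniformity of the
**factor-free** rank p-value at α = 0.01, plus the empirical validity
bound P(p_perm ≤ α) ≤ α + 1/n_tags.

The cumulative factor is excluded from the calibration check on analytic
grounds, not convenience: the factor is a deterministic function of query
length, approximately uniform on (0, 1] when query lengths follow the
reference length law, and independent of the rank under the null — so the
product `rank/n_tags × factor` is a product of two near-uniform variables,
with density ≈ −ln(x), and *cannot* be null-uniform. The factor is a
length re-weighting applied after calibration, shifting significance
toward longer queries; it is implemented exactly as specified, and its
effect on calibration is a documented property of the method, not a bug in
the implementation.

Two discreteness effects bound what uniformity can mean here. First, the
rank lives on a grid of `1/n_tags`. Second, and more visibly, a query with
zero overlap in some TC has p_raw exactly 1, and the tie-inclusive rank
maps the whole atom to p_perm = 1; the mass of that atom is
E[(1 − K/N)^n] over the query-length law — for 5 % signatures and
log-uniform lengths starting at 20, a few percent, independent of the
universe size. A KS statistic at 500 queries sits near its α = 0.01
critical value on this account alone, so the calibration check passes with
modest rather than enormous margin. This conservatism at the
least-significant end of the scale is intrinsic to one-sided discrete
p-values.

Two further choices follow the formulas as printed: rank division by
`n_tags` (not `n_tags + 1`), and Fisher's combination of `p_perm` with
`p_tc` under a 4-df χ² even though the two are computed from the same
`p_raw` and are not independent. The combined p-value is therefore treated
as a ranking score with monotonicity guarantees (the tests check strict
monotonicity in each input), not as a calibrated tail probability.

## 6. Interpreting the bias analysis

`summarize_by_group()` reproduces, on synthetic panels, the reason the
permutation layer exists. When panels of different universe sizes share
one global gene space, a null query maps less completely into a small
panel (small `n_mapped`) and meets shorter signatures; both inflate the
discrete atoms at large p_raw and drag the group's mean
`z = Φ⁻¹(1 − p_raw)` down. Group-mean Z therefore rises with group-mean
signature length — a positive correlation the acceptance suite requires
only qualitatively (r > 0), since its magnitude depends on the panel size
spread. Ranking within each TC's own reference column removes exactly this
cross-TC incomparability.

## 7. Known limitations

* Depletion is not tested; the hypergeometric tail is upper-only.
* `p_combined` is a score, not a calibrated p-value (§5); the Bonferroni
  flag inherits this caveat.
* Per-panel universes make raw p-values incomparable across panels by
  construction; only the permutation-adjusted quantities should be
  compared.
* The t-statistic treats cells as independent observations; panels with
  strong within-type substructure will have optimistic degrees of
  freedom.
* At desk scale (hundreds of reference sets, a handful of TCs) the floors
  `1/n_tags` and `1/n_tcs` dominate small p-values; production-scale
  references are needed for production-scale significance.
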