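---
title: "Methods: directional signature overlap and maturity indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: directional signature overlap and maturity indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maturityscreen)
```

## The problem

Principal neurons of the hippocampal dentate gyrus (DG) mature along a
stereotyped transcriptomic trajectory from infancy to adulthood and drift
further during aging. In several mouse models and in some psychiatric
conditions this trajectory is disturbed in either direction: a
*pseudo-immature* state (adult neurons resembling infant ones) or a
*hyper-mature* state (exaggerated adult-ward change, or change resembling
old age). Both states can be read off bulk differential-expression (DEG)
signatures by asking a single question: **does a model's DEG signature
change in the same direction as a reference developmental (or aging)
signature, and how strongly?**

`maturityscreen` implements that question as an open, fully specified
statistic, plus the downstream analyses that build on it: signed
maturity/aging indices, behavioral anxiety effect sizes and their
correlation with maturity, enrichment meta-analysis of shared feature
genes, PCA grouping of models into enhanced-development versus
accelerated-aging classes, and cell-type contribution scoring of bulk aging
signatures against a single-cell DEG atlas. Commercial platforms offer a
comparable "running Fisher" comparison, but its cutoff schedule,
correction and aggregation are not published; the statistic here is a
transparent analogue whose every choice is stated below and exercised by
tests, not a re-implementation of any proprietary procedure. Published
overlap p-values from such platforms are therefore not bit-reproducible
targets; recovery of *planted* structure in synthetic data is the
package's standard of correctness.

## The directional rank-scan overlap statistic

Each dataset enters as a DEG list: records $(g, \log_2 FC_g, p_g)$,
filtered by the conventional screen $|FC| > 1.2$ and $p < 0.05$ (both
strict; `filter_criteria()`). The filtered list is split into up- and
down-regulated genes, each ranked by decreasing $|\log_2 FC|$ (ties:
ascending p-value, then gene id — a total, reproducible order).

For two ranked lists $A$ and $B$ in a universe of $N$ measured genes
(`harmonize_universe()`: the intersection of the stated universes, or a
configurable default of 20 000, the order of the mouse protein-coding gene
count), the rank-scan statistic evaluates every pair of prefix cutoffs
$(\lceil f_i |A| \rceil, \lceil f_j |B| \rceil)$ over a decile grid
$f = 0.1, \dots, 1.0$ and computes the upper-tail hypergeometric
probability of the prefix overlap:

$$P_{ij} = P\left[X \ge |A_{f_i} \cap B_{f_j}|\right],\qquad
X \sim \mathrm{Hypergeom}(N, \lceil f_i|A|\rceil, \lceil f_j|B|\rceil).$$

The reported p-value is $\min_{ij} P_{ij}$ multiplied by the number of
grid pairs (a Bonferroni correction over the scan, capped at 1). The grid
makes the statistic sensitive to concordance concentrated among
top-ranked, large-effect genes — the documented character of fold-change
ranked overlap testing — while the Bonferroni factor keeps it valid (in
fact conservative, because the grid's tests are nested and highly
correlated; the null calibration test verifies
$P(p < 0.01) \le 0.01$ empirically). Setting
`scan_config(cutoff_fractions = 1, correction = "none")` recovers the
plain one-shot Fisher/hypergeometric test exactly, which is how the
implementation is checked against an exhaustive enumeration oracle for all
universes $N \le 12$.

`compare_datasets()` applies the scan to the four direction pairs
(up/up, down/down, up/down, down/up), aggregates the two concordant and
the two discordant p-values with Fisher's method ($\chi^2$ with 4 df;
both concordant quadrants should contribute, mirroring how shared up- and
down-regulated genes are summed in Venn-diagram breakdowns; `combine =
"min"` is available), and reports

* `overall_p` = min(concordant, discordant) with `sign` $= +1$ when the
  concordant side wins, $-1$ otherwise;
* the four shared-gene sets, always taken at the *full* cutoffs — these
  are Venn-diagram contents, independent of where the scan found its
  minimum.

### Numerical choices

All tail probabilities are computed on the log scale
(`phyper(..., log.p = TRUE)`, $\chi^2$ survival on log scale). Under the
default conditions (800-gene signatures, $N = 20\,000$) true overlap
p-values reach $10^{-1000}$ and would underflow double precision;
log-scale computation keeps the signed indices exact and strictly
monotone in the planted concordance. The public `maturity_index(p, sign)`
entry point floors a bare p-value at $10^{-300}$ only as a finiteness
guard for callers without log information; pipeline code passes the exact
log10 p.

## Signed indices, anxiety effect sizes, and their correlation

The **maturity index** of a model against a reference is
$\mathrm{sign} \times (-\log_{10} p)$. Published descriptions write the
negative-correlation case as $-\log_{10}(-1 \times p)$, which is not
arithmetically usable for a positive probability; the only reading that
yields a bidirectional axis is the signed-p notation adopted here:
the sign records whether concordant or discordant overlap dominates, and
the magnitude is $-\log_{10}|p|$. A model's family-level index (seven
developmental references, three aging references) defaults to the
comparison of largest absolute index — the most significant timepoint,
matching a screening rule of "significant against at least one
developmental reference" — with mean and fixed-timepoint summaries
available (`model_maturity_summary()`); which single timepoint the
published per-model values used is not stated, so the most-significant
rule is the package's choice.

The **anxiety index** is the polarity-adjusted Cohen's d from group
summary statistics, exactly in the unweighted pooled-SD form:
$d = (M_\mathrm{model} - M_\mathrm{control}) / S_\mathrm{pooled}$,
$S_\mathrm{pooled} = \sqrt{(S^2_\mathrm{model} + S^2_\mathrm{control})/2}$.
Polarity ($\pm 1$ per measure) orients every measure so positive means
more anxiety-like behavior (less time in open arms and longer latency to
the light box both count as anxious). SEM-reported tables are converted
as $SD = SEM \sqrt{n}$ on ingestion. A model with several measures gets
the unweighted mean of adjusted effects — no aggregation rule is
published, and the unweighted mean is the minimal assumption.

Maturity and anxiety indices are correlated with Pearson's r and the
exact two-sided t-transform p-value,
$t = r\sqrt{n-2}/\sqrt{1-r^2} \sim t_{n-2}$. For reference, $r = 0.49$
with $n = 19$ gives $p = 0.0332$ by this transformation; a printed pair
(0.49, 0.034) is mutually consistent only if the unrounded correlation
was $\approx 0.487$.

## Enrichment meta-analysis

Feature genes (the concordant shared sets of the screened models) are
tested per gene-set term with the upper-tail hypergeometric probability
and BH q-values within each query set; across query sets, per-term
p-values are combined by Fisher's method ($\chi^2$, $2K$ df) and terms are
ranked by the combined p. This replaces an unpublished platform backend
with a standard, exactly testable statistic; with a single query set the
combination is the identity, so the meta ranking degenerates to the
single-set ranking.

## PCA grouping

The model-by-reference signed index matrix (both families jointly — the
published figure implies but does not state joint columns) is
column-standardized and projected on its first two principal components;
models are split by 2-means seeded deterministically with the two extreme
PC1 models (no random restarts, so the grouping is a pure function of the
matrix). The cluster with the higher mean raw index over the development
columns is labeled `development_like`; labeling therefore cannot be
flipped by re-orienting aging columns. Column standardization is the
package's choice where "PCA on overlap p-values" is scale-ambiguous;
signed $-\log_{10}$ values are the quantity used everywhere else.

## Cell-type contribution

A model's accelerated-aging signature (its concordant shared genes with
an aged reference, directions retained) is compared against each cell
type's filtered old-vs-young DEG list. The score is $-\log_{10} p$ when
the comparison is concordant and 0 when discordant — the plot axis is a
contribution *magnitude*, so discordant cell types are floored rather
than shown negative (stated here to be testable). Bubble size is the
percentage of signature genes shared with the cell type. The universe for
single-cell comparisons is not published; the package defaults to the
shared bulk universe, configurable.

## The synthetic study generator

All statistical guarantees are demonstrated on synthetic data with
planted structure (`sim_config()` defaults are the study conditions):

* 20 000-gene universe; 800-gene signatures (half up, half down);
* seven developmental references (ages 8–29 d vs adult) sharing a core
  signature whose per-gene magnitude decays monotonically toward
  adulthood (scale 1 → 0.45) under a nested activation scheme (100% →
  85% of the core), so adjacent timepoints share ≥ 80% of active genes;
* three aging references (16/24/29 vs 3 mo) on a distinct signature
  sharing 20% of its genes with the developmental one, magnitude growing
  with age;
* 19 models with planted concordance grid $f$: 17 hyper-maturity values
  from 0.9 down to 0.3 plus two immaturity models at −0.4 and −0.7 — a
  fraction $|f|$ of signature genes is differentially expressed in the
  model, concordantly for $f > 0$, discordantly for $f < 0$, topped up
  with background DEGs to a constant 800 true DEGs;
* signature |log2FC| ~ Normal(1, 0.3) truncated at 0.3, null log2FC ~
  Normal(0, 0.1): planted genes clear the |FC| > 1.2 filter realistically
  while weak-timepoint genes sometimes fail it;
* p-values from a one-sample z model (observed effect = true +
  Normal(0, 0.15); $p = 2\Phi(-|obs|/0.15)$) for true DEGs, Uniform(0,1)
  for null genes — the filter stays meaningful without simulating counts;
* behavioral measures (1–3 per model, both polarities) whose true
  polarity-adjusted d is $1 \times f + \mathrm{Normal}(0, 0.2)$, written
  as exact population summaries;
* an 11-cell-type atlas (astrocytes through microglia) in which microglia
  (share 0.55) and astrocytes (0.25) carry planted parts of the aging
  signature, every cell type plus 300 background DEGs;
* a 50-term gene-set collection whose one planted term holds 70% of the
  developmental signature.

Published screening magnitudes per model are not reported, so the effect
magnitudes above are conventions chosen to be realistic, not
calibrations. Everything is deterministic given the seed; ground truth is
recorded in sidecar tables so recovery is assertable.

What the generator deliberately does **not** emulate: read counts,
library size or platform effects, probe-level noise, gene-gene
correlation, homology-mapping error between species, and dataset-specific
universes. Passing tests therefore demonstrate that the statistics
recover the structure they are designed for under a clean noise model —
not that any particular real dataset will show the same effect sizes.

## Problem sizes used by the test suite and acceptance script

The test suite runs the full default conditions where a criterion
specifies them (200 replicate cohorts for rank recovery, 1000 null
replicates for calibration, 100 seeds for classification, cell-type and
enrichment recovery) and a reduced configuration (4 000 genes, 200-gene
signatures, 6 models) for unit-level checks. `scripts/acceptance.R`
reports medians/rates over 25 replicates per quantity and 500 null
replicates, sizes chosen so a complete run stays in the minutes range on
one CPU.

## Known limitations

* The rank-scan schedule (deciles, Bonferroni, Fisher aggregation) is one
  principled instantiation of fold-change ranked overlap testing;
  platform p-values produced by other schedules will differ in magnitude
  (not, in well-powered cases, in sign or ordering).
* Gene identity is by uppercased symbol; cross-species comparison
  inherits symbol-matching errors unless an ortholog map is supplied.
* The Bonferroni scan makes the statistic conservative; near-threshold
  overlaps are under- rather than over-called.
* 2-means on two components is deliberately simple; cohorts with more
  than two phenotype axes would need a richer grouping rule.
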