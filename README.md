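# maturityscreen

Cross-dataset analysis of transcriptomic **maturity** for brain expression
studies. Dentate-gyrus neurons follow a stereotyped expression trajectory
from infancy to adulthood and onward into aging; genetic and environmental
insults can push adult tissue off that trajectory in either direction —
toward a *pseudo-immature* state or toward *hyper-maturity* / accelerated
aging. This package quantifies where a model sits on that axis from
nothing but standard differential-expression (DEG) tables, and carries the
result through the downstream analyses such screens rely on.

For computational neuroscientists and transcriptomics analysts who have
DEG tables (their own or from public repositories) and want an open,
testable alternative to proprietary signature-comparison platforms.

## What it computes

At the core is a **directional rank-scan overlap statistic** between two
signed DEG lists. Lists are filtered (|FC| > 1.2, p < 0.05), split into
up/down genes ranked by |log2FC|, and every pair of top-fraction prefixes
over a decile grid is scored with the upper-tail hypergeometric
probability in a universe of N measured genes:

    P_ij = P[ X >= |A_i ∩ B_j| ],   X ~ Hypergeom(N, |A_i|, |B_j|)

The minimum over the grid is Bonferroni-corrected for the grid size. The
four direction pairs (up/up, down/down, up/down, down/up) are aggregated
with Fisher's method into a concordant and a discordant p-value; the
overall result is the smaller of the two with a sign (+1 concordant, −1
discordant). From there:

* **maturity / aging indices** — sign × (−log10 p) against developmental
  and aged reference panels;
* **anxiety index** — polarity-adjusted Cohen's d from behavioral group
  summaries, d = (M_model − M_control)/S_pooled with
  S_pooled = sqrt((S²_model + S²_control)/2), and its Pearson correlation
  with maturity (two-sided t-transform p);
* **enrichment meta-analysis** — hypergeometric per term, BH within each
  query set, Fisher combination across sets;
* **PCA grouping** — 2-means (deterministic extremal initialization) on
  the first two components of the standardized index matrix, labeling
  clusters development-like vs aging-like;
* **cell-type contribution** — a model's concordant shared genes with an
  aged reference scored against 11 per-cell-type old-vs-young DEG lists;
* a **synthetic study generator** that plants known concordance, effect
  sizes and contributor cell types so every claim above is testable
  without downloads.

## Worked example

Simulate a default cohort (19 models, seven developmental + three aging
references, planted concordance from +0.9 down to −0.7) and run the whole
pipeline:

```r
library(maturityscreen)

report <- run_all(sim_config(seed = 3))
report
#> <maturity_report> 19 models (seed 3)
#>   maturity vs anxiety: r = 0.924, p = 0.0000 (n = 19)
#>   groups: 10 development_like, 9 aging_like
#>   screened in: 17 of 19 models
#>   top enriched term: CORE_MATURATION_PROGRAM (meta p = 0)
#>   top contributing cell type: microglia (-log10 p = 29.7)
```

The correlation line is the headline statistic: across the 19 simulated
models, the maturity index explains most of the variation in anxiety-like
effect sizes (r = 0.92 here, against a planted slope of 1 with noise SD
0.2). Seventeen models pass the screening rule (concordant overlap
p < 1e-10 against at least one developmental reference) — exactly the 17
with planted positive concordance; the two planted-immature models score
negative maturity indices and are screened out. The planted gene-set term
tops the enrichment meta-analysis, and microglia — the designated
contributor in the synthetic atlas — tops the cell-type contribution
ranking.

A single comparison looks like this:

```r
cfg <- sim_config(seed = 3)
panel <- simulate_reference_panel(cfg)
model <- apply_filter(simulate_model_dataset(cfg, 1, panel$truth))
ref <- apply_filter(panel$references$dev_08d)
compare_datasets(model, ref)
#> <signed_overlap> model_01 vs dev_08d (universe 20000)
#>   overall p = 0 (log10 = -1280.92), sign = +1 (concordant)
#>   up_up      397/ 397 shared  349  p = 0
#>   down_down  406/ 400 shared  356  p = 0
#>   up_down    397/ 400 shared    0  p = 1
#>   down_up    406/ 397 shared    0  p = 1
```

Model 1 has planted concordance 0.9: about 720 of the 800 signature genes
are differentially expressed in the same direction as the day-8 reference,
so essentially all shared genes fall in the concordant quadrants and the
overlap is astronomically significant (`overall p` underflows to 0 in
linear scale; the exact value is carried as log10 p = −1280.9).

Real data enter through `read_deg_table()` (TSV with `gene_id`,
`log2fc`/`fold_change`, `pvalue`), `read_behavior_table()` (group
summaries, SEM auto-converted to SD) and `read_gmt()`; the same functions
then apply unchanged.

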