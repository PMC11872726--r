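# immrep

Analysis of B-cell receptor (BCR) heavy-chain repertoires from AIRR
rearrangement tables, together with a cohort simulator with known ground
truth. The package is aimed at immunologists comparing case and control
repertoires — here a four-group design (healthy controls, mild/moderate
and severe ME/CFS, and MS controls) — when the questions are: is the
repertoire more clonal, does germline gene usage differ, is there more
somatic hypermutation or N-glycosylation potential, has the IgM:IgG
balance shifted, and can a handful of gene-usage features classify cases?

## What it computes

- **Quality control.** Productive-record filtering and the per-sample
  depth rule: repertoires with fewer than 1,500 productive UMIs are
  excluded (exactly 1,500 passes). Single-gene-dominated repertoires are
  flagged, not dropped.
- **Clonality and diversity** under fixed-depth rarefaction: each of
  1,000 iterations draws 1,000 UMIs without replacement and computes

  $$G = \frac{\sum_{i=1}^{S}(2i-S-1)\,P_{(i)}}{S\sum_i P_i}, \qquad
    H = -\sum_{i=1}^{S} P_i \ln P_i,$$

  with $P_{(i)}$ the ascending-sorted proportions of the $S$ species
  (unique CDR3 amino-acid sequences, or clonotypes); the across-iteration
  means are reported. Repertoire composition is summarised by the
  proportion held by the top 1 / 2–10 / 11–100 / 101+ clones.
- **Clonotypes.** Records sharing a V gene, J gene and CDR3 length whose
  CDR3s lie within 0.15 substitutions per residue are clustered by
  single linkage — exactly the connected components of the ≤ 0.15
  threshold graph — across all subjects; networks are exported as
  GraphML/edge lists.
- **Repertoire features.** UMI-weighted V/D/J usage matrices, somatic
  mutation counts and frequencies from germline-aligned mismatches,
  N-glycosylation sequons (N-X-S/T, X ≠ P, overlaps counted), and
  IgM/IgG composition.
- **Group statistics.** Mann-Whitney U tests with Bonferroni correction
  for gene usage, Kruskal-Wallis + Dunn's test with Holm-Šidák q-values
  for everything else, Cohen's d, median-usage R², and PCA.
- **Classification.** A logistic model on six gene-usage features
  (IGHV3-30, IGHV3-30-3, IGHV3-49, IGHV1-3, IGHD1-26, IGHJ6) with a
  stratified 60/40 split and rank-based ROC/AUC.
- **Simulation.** `simulate_cohort()` generates AIRR-format cohorts with
  Dirichlet between-subject usage variation, heavy-tailed clone sizes,
  isotype-conditional hypermutation, an optional planted standardized
  shift on one gene's usage (default: Cohen's d = 0.70 on IGHV3-30 in
  the mild/moderate group), and a ledger that reconciles exactly with
  the emitted records.

## Worked example

```r
library(immrep)

cfg <- simulation_config(group_sizes = c(HC = 8L, ME_mm = 8L),
                         umi_range = c(2500L, 3000L), seed = 42L)
res <- run_repertoire_pipeline(out_dir = "cohort_out", config = cfg,
                               seed = 42L)

table(res$qc$qc_status)
#> included
#>       16

head(res$diversity, 3)
#> # A tibble: 3 × 7
#>   subject_id group shannon  gini unit  subsample iterations
#>   <chr>      <chr>   <dbl> <dbl> <chr>     <int>      <int>
#> 1 S001       HC       6.26 0.275 cdr3       1000       1000
#> 2 S002       HC       6.26 0.277 cdr3       1000       1000
#> 3 S003       HC       6.42 0.227 cdr3       1000       1000

res$usage_tests[res$usage_tests$gene == "IGHV3-30", c("comparison",
    "p_raw", "p_adjusted", "effect_size")]
#> # A tibble: 1 × 4
#>   comparison   p_raw p_adjusted effect_size
#>   <chr>        <dbl>      <dbl>       <dbl>
#> 1 ME_mm vs HC 0.0830          1       0.983
```

A Shannon entropy near 6.3 nats at a 1,000-UMI rarefaction depth and a
Gini index around 0.25 describe diverse, mildly skewed repertoires; the
IGHV3-30 row shows the planted usage elevation in the mild/moderate group
(the raw Mann-Whitney p and the within-call Bonferroni adjustment over
all genes and comparisons; the targeted two-comparison design uses
`m_tests = 2`). With only eight subjects per group the effect-size
estimate is noisy — the acceptance script below measures its calibration
properly. (On this small separable cohort the logistic fit logs its
ridge fallback.)

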