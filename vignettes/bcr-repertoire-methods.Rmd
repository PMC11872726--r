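---
title: "Models and methods behind immrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind immrep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`immrep` analyses B-cell receptor (BCR) heavy-chain repertoires from AIRR
rearrangement tables and ships a cohort simulator that emits such tables
with known ground truth. This vignette explains the models, the tunable
parameters and their defaults, the numerical choices, and what the
simulator does and does not emulate. Every quantitative statement here is
one the test suite or `scripts/acceptance.R` computes; nothing is quoted
from elsewhere.

## The analysis model

### Quality filtering

A rearrangement record is one UMI-consensus transcript; `duplicate_count`
is its UMI weight and every abundance in the package is UMI-weighted.
Non-productive records (out-of-frame or stop-containing transcripts) are
removed first. A repertoire is then excluded when its *productive* UMI
total is less than 1,500; a repertoire with exactly 1,500 is kept. The
boundary is deliberate: the rule is "fewer than 1,500 are excluded", so
1,499 fails and 1,500 passes (`apply_depth_threshold()`). Repertoires in
which a single V gene exceeds 90% of UMIs are flagged as aberrant by
`flag_aberrant_repertoires()` but never dropped automatically — that kind
of exclusion is a judgement call that belongs to the analyst.

Multi-call gene assignments (`"IGHV4-34*01,IGHV4-34*02"`) resolve to the
first listed call, and allele suffixes after `*` are stripped while
duplicate-gene suffixes (the `-3` of IGHV3-30-3) are kept
(`strip_allele()`). First-call resolution is the common convention and is
deterministic.

### Clonality and diversity

Diversity is computed on species abundance vectors, where a species is a
unique CDR3 amino-acid sequence (or a clonotype id for clonotype-level
analyses). Two indices are used:

- Gini index, with proportions sorted ascending:
  $G = \sum_{i=1}^{S} (2i - S - 1) P_{(i)} \,/\, (S \sum_i P_i)$.
  The denominator's normalisation is the species count $S$; any other
  reading breaks the $[0, 1)$ range and the "uniform means zero"
  property. $G$ is 0 for an even repertoire and $(S-1)/S$ in the
  single-dominant limit.
- Shannon entropy in nats, $H = -\sum_i P_i \ln P_i$, maximal at
  $\ln S$ for an even repertoire.

Because both indices depend on sequencing depth, repertoires are compared
at a fixed rarefaction depth: each of 1,000 iterations draws 1,000 UMIs
*without replacement* (records expanded by their UMI weight), computes
both indices on the drawn abundances, and the across-iteration means are
reported (`resampled_diversity()`). A repertoire whose depth equals the
subsample size yields the single-pass value for any iteration count — a
useful exactness check. Repertoires below the subsample depth raise an
error rather than being skipped silently: upstream QC guarantees at least
1,500 productive UMIs, so reaching that error indicates a broken
pipeline, not an expected state. Abundance ties in the composition bins
(top 1 / 2–10 / 11–100 / 101+ clones) are broken lexicographically by
CDR3 string so outputs are reproducible.

### Clonotype clustering

Clonotypes group records with the same gene-level V call, J call and CDR3
length whose CDR3s differ by at most 0.15 substitutions per residue.
Within each (V, J, length) cell the package clusters *unique* CDR3s by
single-linkage agglomeration (`stats::hclust`) on the normalized Hamming
distance and cuts the dendrogram at the threshold. Single linkage was
chosen because a single-linkage cut is mathematically identical to the
connected components of the graph joining pairs at distance ≤ 0.15 — the
standard "clonotype" semantics — which also supplies an exact independent
oracle (graph components via igraph) used in the tests. Equal lengths are
a partition key, so insertions and deletions cannot occur and the
substitutions-per-residue distance is exactly the normalized Hamming
distance. Clustering pools all subjects so shared clonotypes across
individuals are found. Clonotype ids are deterministic: cells are
processed in sorted key order and clusters are numbered by their smallest
member `sequence_id`, making outputs invariant to row order.

Networks place one node per record and connect members of a clonotype as
a clique; clonotypes larger than `edge_cap` (default 50) are rendered as
a star centred on the most abundant member to avoid quadratic edge
blow-up, and such clonotypes are flagged in the export. Graphs are
written as GraphML plus a plain edge list for external renderers.

The targeted subset analysis (`subset_network_analysis()`) selects
case-group subjects whose usage of a gene (IGHV3-30 by default) exceeds
the healthy-control mean by more than one control standard deviation
(sample SD, strict inequality), draws the same number of controls at
random, restricts both sides to records using that gene, and
depth-matches the groups by drawing a fixed number of UMIs per group
without replacement before clustering, network construction and the
Shannon / IgM / mutation-frequency comparisons.

### Somatic hypermutation, sequons, isotypes

Mutations are counted as aligned positions where the sequence and its
germline alignment both carry an unambiguous nucleotide and differ; gap
and ambiguity positions are skipped on either strand. Mutation frequency
divides by the number of *compared* positions rather than the raw string
length — identical for clean sequences, but it prevents frequencies
above 1 when ambiguity codes are present. N-glycosylation sequons are
the tripeptides N-X-S/T with X any residue except proline, counted with
overlaps allowed over the full in-frame translation (and, separately,
over the CDR3 junction, since both per-sequence and per-CDR3 readings of
the quantity appear in the literature; the per-sequence count is the
primary output). Translation uses the standard code from position 1 —
the frame the simulator guarantees — dropping a trailing partial codon;
a productive record that nevertheless translates with an internal stop
is flagged and excluded from sequon counting with a warning. Constant
region calls map by prefix to IgM / IgG / other; the assay this analysis
targets sequences IgM and IgG only, so "other" is reported but excluded
from IgM:IgG contrasts.

### Group statistics and the classifier

Per-gene usage differences between two groups use the two-sided
Mann-Whitney U test: the exact null distribution when the combined
sample size is at most 20 with no ties, otherwise the normal
approximation with tie and continuity correction (this is
`stats::wilcox.test`'s behaviour, pinned explicitly). Bonferroni
correction multiplies by the family size, which defaults to the number
of (gene, comparison) tests in the call; the targeted replication design
uses `m_tests = 2` (two case groups against controls per gene).
Multi-group comparisons use the tie-corrected Kruskal-Wallis omnibus
test followed by Dunn's z on pooled ranks, reported with Holm-Šidák
step-down q-values ($q_{(i)} = 1 - (1 - p_{(i)})^{m - i + 1}$ with a
running-maximum repair; no installed R package provides Dunn's test, so
it is implemented directly and checked against the hand formula).
Cohen's d uses the pooled n−1 standard deviation. Median-usage
concordance between groups is the squared Pearson correlation of
per-gene medians.

The six-feature classifier uses IGHV3-30, IGHV3-30-3, IGHV3-49, IGHV1-3,
IGHD1-26 and IGHJ6 usage. Subjects are split 60/40 with stratification
by group: per label, round-half-to-even of count × 0.6, repaired one
subject at a time (largest fractional remainder first) so the total
training size matches the overall 60%, with at least one subject per
label on each side. The logistic model is an unregularized binomial GLM
(`stats::glm.fit`); usage proportions are already commensurate, so
features enter unscaled (whereas PCA standardizes, the usual convention
difference between GLMs and ordination). Perfect separation — a real
possibility in small simulated cohorts — is detected via pinned fitted
probabilities and handled by a small ridge (1e-4) on the slopes through
penalized IRLS, with the fallback flagged in the report. ROC/AUC is the
rank-based U-statistic (ties count one half) with curve points at every
distinct threshold; a brute-force pairwise count and pROC serve as test
oracles, never as the implementation. PCA components have their signs
fixed by making the largest-magnitude loading positive.

## The cohort simulator

`simulate_cohort()` emits fully annotated AIRR records plus a truth
ledger that reconciles exactly with them (record, UMI, isotype and
mutation totals; per-subject usage vectors; clone sizes; the planted
effect). The generative model, per subject:

1. **Gene usage.** A Dirichlet draw centred on population base
   frequencies (IGHV3-23 highest, as in human peripheral blood) with
   concentration 200, giving a between-subject usage SD of
   $\sqrt{p(1-p)/201}$ — for a 5% gene, about 1.5 percentage points,
   a realistic degree of inter-individual variation.
2. **Planted effect.** Mild/moderate-case subjects receive an additive
   shift on IGHV3-30 usage, `delta = d * sd_total`, where `sd_total` is
   the analytic SD of *observed* usage: the Dirichlet component plus the
   clone-sampling component $p(1-p)\,E[\sum_c w_c^2 / (\sum_c w_c)^2]$
   (genes are assigned per clone and weighted by clone size, so the
   sampling noise is governed by clone weights, not raw UMI counts; the
   expectation is estimated once per configuration by a short
   deterministic draw from the clone-size law, thinned by the expected
   productive fraction). An additive shift is an exact location shift,
   so the realized standardized difference equals the configured Cohen's
   d by construction; a logit-scale shift was considered and rejected
   because its curvature and variance inflation bias the realized effect
   by several hundredths in both directions. The default effect is
   d = 0.70 on ME_mm vs the baseline.
3. **Clone sizes.** A truncated discrete power law (exponent 2.5,
   maximum clone size 100 UMIs), drawn until the subject's UMI depth is
   reached and trimmed to hit it exactly. This yields mostly singleton
   clones with occasional expansions of a few percent of the repertoire
   — the regime of healthy peripheral blood. Heavier tails (exponent 2,
   unbounded sizes) were rejected: single clones occupying half a
   repertoire are what the aberrant-repertoire flag exists to catch, and
   they make the observed-usage variance so unstable that no effect-size
   calibration can hold.
4. **CDR3s.** Junctions are `C` + random residues + `W`, lengths 8–24
   with a triangular peak at 15 (the human CDR3 mode). Clone members
   beyond the founder carry one amino-acid substitution with
   probability 0.1, giving clonotype clustering real within-clone
   structure to recover.
5. **Isotype and mutation.** Each record draws IgM vs IgG from a
   per-subject Beta fraction (group means: 0.65 for ME_mm, 0.55
   elsewhere — the mild/moderate IgM elevation is part of the default
   conditions); mutation counts are zero-inflated Poisson for IgM
   (half the transcripts naive) and negative binomial (mean 15,
   size 3) for IgG, i.e. roughly 4% of the 360-nt variable region.
   Substitutions hit distinct positions and always change the base, so
   downstream mismatch counting recovers the planted count exactly. A
   configurable fraction of mutations (5%) is directed to create an
   N-glycosylation sequon by completing an N codon in front of an
   existing X-S/T pair.
6. **Productivity.** Besides a 2% baseline artefact rate, any record
   whose mutations create an internal stop codon is emitted as
   non-productive — a stop-containing transcript cannot encode a
   receptor. A consequence worth knowing: because heavily mutated IgG
   records acquire stops more often, the *productive* IgM fraction runs
   above the planted transcript-level fraction; group contrasts are
   preserved.
7. **Depth.** Per-subject UMI depth is uniform on 2,500–4,000 by
   default, with an option to plant shallow subjects (200–1,400 UMIs)
   that must fail the 1,500 threshold. The real study reports only the
   QC floor and a wide range of input B-cell counts, so depth defaults
   are a package choice; they are set so that after productivity
   filtering every regular subject clears 1,500 with margin. The toy
   germline panel (21 IGHV, 6 IGHD, 6 IGHJ genes, constant per-segment
   lengths, sense codons only) is synthetic: analyses depend only on
   gene names and mismatch counts, never on real IMGT sequence content.

The whole cohort is a deterministic function of the configuration and
seed.

### What the simulator does not emulate

No sequencing reads or UMI consensus building (records are born
annotated); no indels in hypermutation; no light chains; no class-switch
lineages; no hotspot-biased mutation targeting; no shared antigen-driven
convergent clonotypes between subjects beyond what chance produces. Tests
that pass on simulated cohorts therefore validate the statistical
machinery and its calibration, not the upstream bioinformatics of real
AIRR data, and say nothing about biological effects absent from the
generative model.

## Problem sizes and numerical choices

The test suite exercises the study's group sizes (21 healthy controls,
25 mild/moderate, 36 severe, 28 MS) and its analysis parameters (1,500
UMI threshold; 1,000 × 1,000 rarefaction; 0.15 clonotype cut; 60/40
split; Bonferroni m = 2 for the targeted genes). Monte-Carlo recovery of
the planted d = 0.70 runs 500 replicate two-group cohorts at 400–600
UMIs per subject — the two groups that enter the statistic, at a depth
where the calibration above is accurate; the small-sample bias of the d
estimator (about +2% at these group sizes) is visible in the recovered
mean and sits well inside the ±0.05 acceptance band. Type-I error is
checked on 96 null cohorts (about 2,000 gene-tests) against the binomial
99% interval around 5%. The end-to-end pipeline demonstration simulates
the full 110-subject cohort at 2,500–3,000 UMIs per subject. Reported
p-values and indices are double precision throughout; the only tolerance
knobs are the documented clonotype threshold and the 1e-4 ridge
fallback.

## Known limitations

- Usage variance calibration assumes the default Dirichlet/power-law
  machinery; custom clone-size laws are honoured in the calibration only
  through the same Monte-Carlo estimate, which may be coarse for very
  heavy tails.
- At depths below ~300 UMIs the clone-sampling noise becomes so
  outlier-driven that realized standardized effects fall short of the
  configured value; the package does not attempt to correct this regime.
- The Holm-Šidák and Dunn implementations assume two-sided z tests on
  pooled ranks; no exact small-sample Dunn distribution is provided.
- `subsample_matched()` resamples UMI weights, so record-level fields of
  dropped records vanish from the subset; analyses on matched subsets
  are depth-comparable but not record-complete.
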