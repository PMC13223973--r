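---
title: "Methods: single-cell and spatial analysis of the tumor microenvironment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell and spatial analysis of the tumor microenvironment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sctme)
```

`sctme` packages, as seeded and unit-tested functions, the analysis
pattern used to build single-cell + spatial atlases of a tumor and its
matched normal tissue: score cells against gene signatures, classify
malignant cells with a quartile gate cross-checked by expression-derived
copy number, distill signatures by prevalence, gate immune cells down a
marker hierarchy, score ligand–receptor communication, and analyze
spatial neighborhoods. This vignette states the models, the defaults and
their justification, what the synthetic data does and does not emulate,
and the numerical choices made where the procedure was underdetermined.

## Quality control and normalization

Cells are removed when *more than* 20% of raw counts are mitochondrial
(dying cells) or *more than* 5,000 features are detected (doublets).
Both inequalities are strict — "more than" — so boundary cells are
retained; `pct_mito` is computed on raw counts before normalization.

Normalization is fixed as `x = ln(1 + 10^4 · c / total)`. The source
workflow says only "normalized"; this is the de-facto standard transform
of the toolkit it used, and downstream quantities (scores, log2FC) need
one defined transform. Consequently `differential_expression()` reports
`log2FC = log2((mean(expm1(x_A)) + 1) / (mean(expm1(x_B)) + 1))` — the
same toolkit's definition: de-log per cell, average, add pseudocount 1.
A practical corollary worth knowing: a gene whose mean normalized
expression is far below 1 cannot display a large fold change under this
estimator, whatever its true fold.

Clustering is PCA (≤ 50 components) → kNN graph (15 neighbors) → Leiden
at resolution 1, seeded; the underlying algorithm was unnamed in the
source, and this matches its ecosystem while staying deterministic.
"Integration" across samples is plain concatenation of normalized
matrices — a recorded limitation; no anchor-based correction is applied.
The immune/epithelial split is cluster-level: clusters are split into
two k-means groups by mean PTPRC (CD45) expression, the higher group
being immune. Cluster-level voting absorbs per-cell dropout of PTPRC.

## Signature scoring

Two scorers are provided because the source workflow used two tools and
does not say which produced the malignancy score:

* **sum-ratio**: `100 · Σ_{g∈S} x_gc / Σ_g x_gc` on normalized values;
  bounded by 100, invariant to rescaling a cell's vector, zero for cells
  with no signature expression.
* **rank-AUC**: genes ranked per cell by decreasing expression (average
  ranks on ties), ranks beyond `rank_max` (default 1500) truncated to
  `rank_max + 1`; with `U' = Σ ranks(S) − n(n+1)/2` the score is
  `1 − U'/(n · rank_max)`, floored at 0. One numerical convention is
  ours: when *every* signature gene ranks beyond `rank_max` the score is
  defined as exactly 0 — the truncated formula alone would leave a
  residue of `(n−1)/(2 rank_max)` (≈ 3·10⁻⁴ at the defaults), and the
  operation's stated extremes require 0.

The pipeline default is sum-ratio (listed first at the source);
`pipeline_config(scoring_method=)` switches. The reporting convention
for multigene-score comparisons is adjusted p < 5.46·10⁻⁶.

## Malignancy gate and CNV cross-validation

The gate threshold is Q3 of the control-condition score distribution,
computed with type-7 (linear interpolation) quantiles — the default of
the source's analysis environment; the quantile rule is configurable so
alternatives can be compared against a published threshold. Wording
("exceeded", "above", "below") implies strict inequalities: a
tumor-condition cell at exactly the threshold is excluded, a control
cell at it is retained. The gate therefore *partitions* cells into
malignant / non-malignant / excluded; by construction about 25% of
control cells sit above their own Q3 and are excluded rather than
misclassified.

CNV inference is a deliberately simplified, oracle-checkable stand-in
for clonal-CNV callers: genes ordered by (chromosome, position),
expression centered on the reference-cell mean, clipped to ±3, smoothed
with a centered 101-gene moving average within each chromosome (only
full windows; chromosomes shorter than the window are skipped with a
warning). The per-cell burden is the mean squared window score, and
`cnv_concordance()` calls CNV-positive above the 95th percentile of
reference burdens — so ≈ 5% of copy-number-normal cells are expected
positive, and the report says so. Segmentation/clonal analysis of the
original tool is out of scope.

## Prevalence distillation

`distill_signature()` intersects a published reference gene list with
the up-regulated DEGs (log2FC > 1; adjusted-p filtering available but
off by default, matching the printed DEG definition) and keeps genes
detected (raw count > 0) in at least 40% of malignant cells — an
inclusive bound. "Present" = raw count > 0 is the simplest reading and
is configurable.

## Progressive immune gating

Annotation walks a tree (default: T/B/NK/ILC/myeloid, then T → CD8/CD4/γδ,
CD4 → Th1/Th2/Th17/Treg/Tfh/Tn, B → plasma/memory/naive/Breg, myeloid →
monocyte-like/Mac_Angio/Mac_Prolif/mast, ILC → ILC1/2/3). At each node a
cell takes the child with the maximal score *among children scoring
strictly above zero*; if none does, it is "unclassified" at that level
and stops descending — the rule that reproduces the published zero-score
behavior for unclassifiable ILCs. Exact thresholds of the prior strategy
are not public, so argmax-over-positive is the minimal consistent rule;
per-node thresholds are configurable. Ties are broken by tree
declaration order, deterministically, with a reported tie count.
Pseudotime-based differentiation labels (Tcm/Tem/Temra) are not
implemented (they require an external reference atlas) and may be
supplied as input columns. Activation is `max(score1, score2) > 0` on
two activation signatures. Proportion shifts between conditions use
Pearson chi-squared without continuity correction.

## Cell–cell communication

For each ordered group pair and ligand–receptor pair:
L = geometric mean over ligand subunits of the per-group Tukey trimean
(Q1 + 2·median + Q3)/4 of normalized expression; R likewise in the
target group; P = LR / (Kh + LR). Kh = 0.5 and 100 permutations are the
published defaults of the tool the source parameterized (it states only
the tool, the trimean, and min cells = 10); both are configurable.
Groups under 10 cells are excluded entirely. Significance permutes group
labels (sizes preserved) with the add-one estimator
`p = (1 + #{P_perm ≥ P_obs})/(1 + B)`; an observed P of 0 gives p = 1.
Pathway summaries are sums of member-pair probabilities. Normalized log
values feed the scorer (the source does not say which slot its tool
saw).

## Spatial analysis

Marker gating thresholds default to per-marker Otsu on log intensities —
a reproducible stand-in for the interactive manual gating actually used;
thresholds are overridable. The boolean rules (tumor = EPCAM⁺PanCK⁺,
CD8/CD4 T = CD3e⁺CD8⁺ / CD3e⁺CD4⁺, B = CD20⁺, monocyte = CD14⁺CD68⁺,
macrophage = CD14⁻CD68⁺) are evaluated in that priority order so
multi-positive cells resolve deterministically (counts reported).

The proximity graph joins cells within 100 (µm assumed; the unit was
unstated). Niches are k-means (k = 6 by default) on row-normalized
neighborhood composition vectors that include the cell itself (so no
neighborhood is empty). The original used *minibatch* k-means; no
minibatch implementation exists in this package's dependency set, so
full-batch `stats::kmeans` stands behind the same surface — same
objective, deterministic under seed, if anything more exact. Rows are
canonically sorted before clustering so labels are equivariant under
input permutation. Enrichment uses a k = 8 nearest-neighbor graph
("eight neighborhoods" read as kNN = 8; the alternative reading was a
different neighborhood rule), ordered-pair edge counts, and
`z = (obs − mean_perm)/sd_perm` over 1,000 label permutations, with
z = 0 where the permutation sd is 0. The epithelial/stromal compartment
rule — epithelial iff ≥ 3 tumor cells within 50 µm — is invented
plumbing standing in for an unstated manual delineation; both parameters
are exposed.

A scale note from the synthetic experiments: composition neighborhoods
should match the structure scale. For 50 µm aggregates, a 50 µm
proximity graph separates aggregate from background niches cleanly,
while the 100 µm default smears their boundaries; the package keeps 100
as the pipeline default (the source's value) and leaves the radius free
where niche recovery is the goal.

## What the synthetic data emulates — and what it does not

`simulate_counts()` draws UMI counts from a negative binomial with mean
`lib_c · base_g · 2^Δ` (gene-level size parameter, default 2; log-normal
library sizes, median 5,000) over a 2,000-gene panel on 4
pseudo-chromosomes with 13 mitochondria-flagged genes. Planted, with
truth tables returned:

* a tumor DEG program (50 genes, |log2FC| = 2, half up/half down) in
  malignant cells;
* three CNV blocks of 150 contiguous genes (1.5× gains, 0.5× loss);
* hierarchical marker programs: 8 genes per gating-tree node, *off→on*
  — near-zero baseline (0.01 expected counts) switched up 2⁷. Real
  marker genes are off→on (CD8A is silent outside T cells), and the
  zero-score gating rules are meaningless in a matrix where every gene
  is detected everywhere;
* broad 40-gene epithelial and immune compartment programs
  (condition-symmetric, so they cancel in AC-vs-AV contrasts but give
  clustering the global structure real compartments have);
* a ligand–receptor pair 8-fold enriched between malignant cells and
  angiogenic macrophages, among 20 decoy pairs;
* an activated CD8 sub-population at exactly 70%, marked by two 6-gene
  signatures;
* 5% QC violators (half 30%-mitochondrial, half doublet-like with
  inflated libraries);
* 10% normal-cell contamination inside the tumor-condition epithelium —
  the cells a quartile gate exists to exclude.

DEG, ligand–receptor and compartment-program genes are drawn from the
above-median-abundance stratum: under the pseudocount-1 fold estimator a
planted fold on a barely-expressed gene is unrecoverable by *any*
method, so planting there would test the generator, not the pipeline.
With a 2,000-gene panel the 5,000-feature doublet cap can never fire;
synthetic runs use a proportionally scaled cap (1,600) while the
package default stays 5,000.

`simulate_spatial()` scatters background cells as a homogeneous Poisson
process, adds TLS-like Gaussian aggregates (σ = radius/3, 50% B / 35%
CD4 T) and optional tumor nests, and draws log-normal marker intensities
(high/low mean 50/5, sdlog 0.4). The planted niche truth is the
*footprint* — any cell within the stated radius of an aggregate center
belongs to that niche, whichever process generated it.

Not emulated: ambient RNA, batch effects, spliced/unspliced counts,
realistic gene–gene correlation beyond the planted programs, cell
segmentation errors, or fluorophore spillover. A green recovery test
therefore establishes that the procedures identify the structure they
target at realistic effect sizes and sparsity — not that they are robust
to every artifact of real data.

## Numerical choices and degenerate inputs

* Quantiles everywhere are type 7; Tukey's trimean uses the same rule.
* Wilcoxon tests use the normal approximation (`exact = FALSE`);
  all-constant genes get p = 1 and log2FC 0.
* All-zero cells normalize to all-zero vectors and score 0.
* `niche_clusters` reduces k to the number of distinct composition rows;
  all-identical compositions give a single niche.
* Permutation p-values use the add-one estimator, so they are never 0.
* Gene matching is by symbol, case-sensitive, after whitespace
  stripping; unmatched signature genes are dropped with a reported
  count.
* Every stochastic step takes an explicit seed, and the pipeline derives
  all stage seeds from one master seed; same inputs + config ⇒
  byte-identical stage tables.

## Known limitations

No anchor-based integration or batch correction; no doublet detection
beyond the feature cap; CNV has no segmentation or clonal analysis; the
CLI surface is the R API (`run_pipeline()` / `run_spatial_pipeline()`
plus the stage functions) rather than a shell executable; chi-squared
proportion tests treat cells as the unit, which overstates significance
when cells within a sample are correlated.
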