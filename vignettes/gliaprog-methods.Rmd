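---
title: "Models and methods behind gliaprog"
author: "gliaprog authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gliaprog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

gliaprog implements the computational core of a single-cell dissection of
pilocytic astrocytoma (PA): quality control and normalization, covariate
regression, PCA plus shared-nearest-neighbor (SNN) clustering with Wilcoxon
marker detection, fold-enrichment signature scoring, principal-component
gene-programme derivation, compartment-signature deconvolution of bulk
expression, and windowed copy-number inference — together with a
synthetic-data generator that plants the population structure these
analyses assume. This vignette records the models, the parameter choices
and their rationale, the numerical decisions, and the known limitations.
It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

# Preprocessing model

**Quality control.** "Expressed" means count > 0. Cells are kept when they
express at least 1000 genes (human; 3000 for mouse) and their mitochondrial
count fraction — raw mitochondrial counts over raw total counts, genes
identified by the `MT-`/`mt-` prefix or an explicit list — is at most 4%
(human; 3% mouse). Genes expressed in fewer than 10 retained cells are then
dropped; cells are filtered before genes, so gene prevalence is computed on
the retained cells. Thresholds quoted with "<" or ">" are strict
throughout; interval bounds are closed. `qcFilter()` is idempotent and
stores a per-step attrition report.

**Normalization.** Counts are divided by the cell total, multiplied by a
scale factor of 10,000, and transformed with the natural log and a
pseudocount of one: `ln(1 + 10^4 * count/total)`. The natural log with
pseudocount is the convention of the standard single-cell toolkits; a
consequence used as a test invariant is that `sum(expm1(values))` equals
the scale factor in every cell. Either raw counts or TPM-like matrices can
be supplied; the normalization treats them identically and only the
relative within-cell structure matters downstream.

**Covariate regression and scaling.** For each gene, ordinary least squares
residuals are taken against an intercept, the number of detected genes, and
tumor-of-origin indicator variables (any subset selectable), then
standardized to mean 0 / SD 1. Genes whose residual SD falls below 1e-10
are treated as zero-variance and mapped to all-zero rows rather than having
numerical noise amplified by the standardization. A rank-deficient design
is an error suggesting a covariate drop, not a silent pseudo-inverse.

**Variable genes.** Genes with mean log-normalized expression in the closed
interval [0.25, 5] and log-normalized SD strictly above 1. Both statistics
are computed on the log-normalized layer (not the scaled residuals),
because the interval is only meaningful on that scale. For cancer-subset
analyses the selection is re-run on the cancer cells, where
programme-driven variance is not diluted by the immune compartments.

**Immune purge.** Candidate cancer cells expressing the cytotoxic granzyme
GZMB above 1.5 log-normalized units (strict) are removed from cancer-cell
analyses; such cells carry a sorting marker but transcriptionally behave as
lymphocytes.

# Population structure

PCA runs on the scaled matrix restricted to the variable genes; 7
components are the default for the full dataset, 5 for the cancer subset.
Every component is oriented so that its largest-magnitude loading is
positive, which makes the top/bottom poles — and therefore the derived
programmes — deterministic across runs and BLAS implementations.

`snnCluster()` builds the k-nearest-neighbor graph under Euclidean distance
in PC space, weights edges between neighbors by the Jaccard overlap of
their neighbor sets, and maximizes modularity (Louvain) at a configurable
resolution (default 0.8), with an explicit seed. The classical parameter
k = 150 in the configuration defaults targets datasets of roughly a
thousand cells with clusters of hundreds; for the synthetic datasets, whose
smallest planted compartment has 100 cells, analyses use k = 30 (k below
the smallest expected population, around the square root of n). Modularity
optimization on a k-NN graph of a single homogeneous blob can split it —
with no true substructure the split is resolution noise — so coarse
recoveries (e.g. two well-separated blobs) are run at low resolution, and
compartment identity is established not by the raw partition but by
`annotateCompartments()`, which assigns each cluster the compartment with
the maximal mean fold-enrichment score (ties broken lexicographically, with
a warning). In the synthetic data the raw cancer partition genuinely splits
into MAPK-high and AC-high subclusters — the same substructure the tumors
show — so cluster-to-truth agreement is evaluated after compartment
annotation.

Markers come from a two-sided Wilcoxon rank-sum test on log-normalized
expression. Both groups at most 8 cells: the p-value is exact, by
enumeration of all group assignments over the pooled average ranks, defined
symmetrically as P(|U − E[U]| ≥ |u − E[U]|). Larger groups: a tie-corrected
normal approximation without continuity correction (the same symmetric
definition). Exact enumeration is also the fallback whenever a group has
fewer than 3 cells. The log fold change is the difference of group means on
the log-normalized (natural-log) scale. Both Bonferroni-adjusted p-values
and Benjamini–Hochberg q-values are reported; callers choose.

# Signature scoring

The fold-enrichment score of signature S in cell c is

    score(c, S) = mean_{g in S} expr(g, c) / mean_{all g} expr(g, c)

computed on the log-normalized layer. The scaled (z-scored) layer cannot
serve here: its per-cell mean is ~0 and the ratio would be undefined, so
"mean expression of all expressed genes" forces the non-negative layer.
The denominator runs over the entire post-QC gene universe, and signature
genes missing from the universe are dropped (not imputed as zero), with a
message. Scores are scale-free per cell, and for any partition of the
universe the sizes-weighted score average reconstructs 1 exactly — both are
test invariants. Cluster- and tumor-level scores apply the same ratio to
the per-group mean expression vector. Subpopulations are cells whose score
strictly exceeds 2.5. Immune-atlas subtype signatures are the genes with
fold change strictly above 1.5 and Bonferroni-adjusted q below 0.05 in the
subtype's reference DE table; subtypes with no usable gene after ortholog
mapping are skipped with a message rather than failing the run. Because
atlas signatures have incomparable raw scales, their scores are divided by
the mean score over the tumor-cluster cells. Cross-tumor-type comparisons
draw a seeded sample of up to 500 cells per type so large types do not
dominate.

One caveat the tests make explicit: all signatures share the per-cell
denominator, so compartments whose overall expression differs shift even a
random gene set's scores (compositional coupling). The calibrated null for
compartment-enrichment testing is therefore label permutation, not random
gene sets.

# Gene programmes and their statistics

Programmes are the 50 genes with the largest and the 50 with the smallest
signed loadings of a component (ties broken by gene id). Signed loadings —
not magnitudes — matter because the two poles are biologically distinct
programmes. Programme relationships use Spearman correlation with average
ranks for ties, two-sided p from the t approximation, and Bonferroni
q-values with the multiplier equal to the number of pairs actually tested
in the call. Gene-list overlaps use the one-sided (enrichment)
hypergeometric upper tail P(X ≥ k) in a genome of 18,000 genes; depletion
is not of interest.

# Bulk deconvolution

Compartment signatures are the genes upregulated (positive log fold
change, Bonferroni-adjusted p < 0.05) in one-vs-rest Wilcoxon tests per
compartment. For a bulk matrix: signature genes absent from the platform
are discarded and counted; each gene is z-scored across samples (samples
are the only population available to standardize over); the raw score of
compartment c in sample s is the mean z over c's signature genes; negative
scores are clipped at zero; fractions are the clipped scores normalized to
sum to 1 (an all-zero sample gets uniform fractions with a warning).

The description this implements contained one unusable step: dividing the
average z-scored expression by "the average expression of all genes" is
degenerate on z-scored data (the per-sample all-gene average is ~0). The
package treats that denominator as a sample-level constant — equivalently,
drops it, since any positive per-sample constant cancels in the final
normalization. This is the pipeline's single largest interpretive decision.

Clipping has a structural consequence worth knowing: samples whose true
compartment weight is below the cross-sample average get a negative raw
score and an estimated fraction of exactly 0, so roughly half the samples
tie at zero for each compartment. Rank recovery of true mixing weights is
therefore ceiling-limited (applying the same arithmetic to the true weights
with no noise at all already leaves substantial ties), and the estimated
fraction is monotone but not strictly monotone in the planted weight. The
raw scores — exposed via `compartmentScores()` — are strictly monotone, and
a shift policy (`negative = "shift"`, subtracting the per-sample minimum
instead of clipping) avoids the zero ties; clipping remains the default
because "percent contribution" presupposes non-negative scores. Whether
bulk data are log-transformed before z-scoring is a flag
(`log_transform`), off by default.

# CNV inference

Genes are ordered by (chromosome, start); per cell, expression is averaged
over sliding windows of 100 consecutive genes within each chromosome (step
1 — "contiguous stretches" with maximal positional resolution); each window
is centered by its mean over the reference set, canonically all cancer
cells (the cell itself included; the leave-one-out difference is O(1/n)).
Log-normalized expression is the input layer. Chromosomes shorter than the
window yield one truncated, flagged window (or an error when truncation is
disabled and no chromosome reaches the window size). No expression clamping
or per-cell median re-centering is applied by default; these are
refinements of other tools, not part of this model. Windows never span
chromosomes, and the per-window reference mean is zero by construction — a
validity condition of the `CnvMatrix` class. Arm-level calls average
windows per arm (default: one arm per chromosome) and flag |mean| above a
configurable cutoff.

# The synthetic-data generator

`simulateCells()` draws per-gene, per-cell negative-binomial counts with
mean `baseline_g × exp(Σ module effects) × library factor` and size 2,
log-normal library sizes (median 1e5, sdlog 0.3), lognormal(0, 2.2)
baselines (a skewed, few-genes-dominate profile typical of expression
data), and 10% uniform dropout — full-length plate-based data are deep, so
dropout is modest. Defaults: 2000 genes × 1000 cells (500 cancer, 300
microglia, 100 macrophage, 100 T cells, matching the roughly 30% microglia
and smaller macrophage/T populations seen in these tumors).

Eight 50-gene modules (MAPK, AC-like, OC-like, cycling, senescence, and
three immune marker sets) sit on a fixed moderate baseline and activate at
4.5 natural-log units (~90-fold — the scale of on/off cell-type markers
and strongly induced immediate-early genes). The effect size is chosen so
that module genes clear the variable-gene SD > 1 gate on the cancer
subset, MAPK-high cells reach fold-enrichment scores above 3, and low-MAPK
cells stay below the 2.5 subpopulation threshold. A quarter of cancer
cells are MAPK-high (activity uniform on [0.85, 1]); the rest draw
activity on [0, 0.3]; AC-like activity is 1 − MAPK activity plus small
jitter, making the two programmes anti-correlated by construction. A small
OC-like branch (5%) is planted independently. Within the MAPK-high cells,
30% are flagged cycling and 30% senescent, mutually exclusively; both
modules also carry a weak graded component (0.045 × MAPK activity) in all
cancer cells, reflecting scores that rise with MAPK signaling but peak in
disjoint cells — with purely binary flags the cycling and senescence
scores would be *negatively* correlated through their disjointness, which
is not the structure these analyses assume. The grade is the one generator
constant calibrated against the reported correlation pattern.

Planted QC failures are extra cells with a 1500-count library (far below
the expressed-gene floor) or an 8× mitochondrial rate (~11% fraction);
planted immune contaminants are T cells labeled marker-positive whose GZMB
count is guaranteed against dropout (the contaminant is *defined* by
expressing the purge gene). The CNV segment spans 150 contiguous genes on
one chromosome in 40% of cancer cells; its `cnv_shift` of +0.4 is the
planted shift in mean log-normalized expression, realized by per-gene rate
multipliers — a flat count multiplier of e^0.4 would attenuate to much
less than 0.4 log-units for low-expressed genes and under-deliver the
planted signal. Bulk samples are Dirichlet-weighted convex mixtures of
compartment mean log-normalized profiles with 10% multiplicative
log-normal noise; the concentration (5.7, 3.0, 0.7, 0.6) centers the
weights on the compartment proportions reported for bulk low-grade glioma
cohorts (cancer ~57%, microglia ~30%). `simulateMouseNSC()` plants three
construct groups (vector, fusion-like, V600E-like; 170/154/163 cells,
5000 genes so mouse QC thresholds are meaningful) with group-specific
modules and an AC-like module reduced to 0.2 activity in the oncogene
groups — oncogenic BRAF opposing glial maturation.

What the generator does *not* emulate: batch and plate effects, ambient
RNA, doublets, gene-length and GC biases, realistic gene-gene correlation
beyond the planted modules, tumor-of-origin expression differences
(tumors are assigned round-robin with no effect, so the tumor covariate in
the regression is exercised but carries no signal), or read-level
artifacts. Passing tests on synthetic data therefore demonstrate
correctness of the computations and recoverability of planted structure at
realistic noise levels — not robustness to every artifact of real tissue.

# Problem sizes and determinism

Tests and the acceptance script run the full pipeline on the default
2000 × 1000 datasets (a five-seed panel for programme recovery and
correlation structure), 50-sample bulk mixtures, and brute-force oracle
checks up to 500 genes × 50 cells; everything completes in a few minutes
on one CPU. All stochastic steps take explicit seeds; `simulateCells()` is
bitwise-reproducible from its seed, and `scripts/acceptance.R` derives
every seed it uses from its `--seed` argument.

# Known limitations

* Louvain partitions are seed- and order-dependent in the absence of clear
  structure; only component-separated or annotation-merged results are
  stable guarantees.
* The deconvolution estimator is relative by construction (z-scores across
  the supplied cohort): fractions are comparable within a cohort, not
  calibrated absolute proportions, and clipping ties below-average samples
  at zero (see above).
* The Wilcoxon normal approximation is used for groups above 8 cells;
  p-values for heavily tied small-expression genes are approximate there.
* CNV inference reports reference-relative expression shifts; without an
  external diploid reference it cannot distinguish a gain in carriers from
  a loss in non-carriers, and inherits all expression-CNV confounders
  (e.g. a coordinated transcriptional programme along a chromosome).
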