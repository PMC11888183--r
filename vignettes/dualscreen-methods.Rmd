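---
title: "Methods: dual-readout CRISPR screen analysis for epidermal differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-readout CRISPR screen analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

`dualscreen` analyses pooled CRISPR knockout screens of keratinocyte
differentiation read out two complementary ways:

* **Sorted-bin (flow) arm.** Cells carrying a guide library are sorted by a
  differentiation reporter (KRT10 protein level) into low / medium / high
  bins plus an unsorted reference, and guide abundance per bin is measured
  by UMI-deduplicated amplicon sequencing. Genes whose knockout blocks
  reporter induction are depleted from the high bin and enriched in the low
  bin; genes whose knockout forces differentiation show the mirror image.
* **Perturb-seq arm.** The same library is read out by single-cell RNA-seq
  with per-cell guide capture. Cells are placed on a differentiation
  pseudotime axis, and each target is tested for shifting its cells along
  that axis.

Because screen-scale inputs are wet-lab data, the package ships a
first-class synthetic generator that plants known knockout effects, so every
stage of the analysis has a ground-truth acceptance surface.

## Sorted-bin arm

**Counting.** Guide abundance is the number of *distinct* 9-nt UMIs observed
per guide (exact-match deduplication; no mismatch collapsing, since the UMI
is simply a random tag and collapse rules are a sequencing-error model we
deliberately avoid). Malformed UMIs and unknown guide ids are logged rather
than fatal, because real screens contain recombined reads. Library
representation QC reports coverage (fraction of designed guides observed),
the Gini coefficient of counts, and the 90th/10th percentile ratio (with an
infinite sentinel when the 10th percentile is zero).

**Normalization and fold changes.** Size factors use the median-of-ratios
estimator over guides with nonzero counts in every sample; with fewer than
`min_ratio_guides` (default 100) such guides the table falls back to
total-count scaling. Guide effects are `log2((t + 1) / (r + 1))` on
normalized counts, comparing each replicate's high bin against the pooled
rest (unsorted + low + medium), and the low bin against its rest.

**alpha-RRA.** Within-replicate guide ranks are averaged across replicate
pairs and re-ranked to a permutation of $i/N$. For a gene with sorted
normalized ranks $r_1 \le \dots \le r_m$, only ranks at or below `alpha`
(default 0.25, configurable; the cutoff is not externally specified)
qualify, and

$$\rho = \min_{k:\, r_k \le \alpha} F_{\mathrm{Beta}(k,\, m-k+1)}(r_k),$$

the smallest order-statistic probability. Significance is a permutation
p-value, $(1 + \#\{\rho^* \le \rho\})/(n_{perm}+1)$, drawing gene-sized rank
sets without replacement from the ranks of the safe-targeting control
guides (guides that cut phenotypically neutral loci). Null draws depend only
on the gene size, so one null distribution per size is shared across genes.
Note that a permutation p of this kind has a structural atom at 1 — genes
with no guide inside the alpha quantile — so its null distribution is
uniform only in the tail; the package's calibration checks are therefore
stated as tail type-I error rather than global uniformity.

**psi-P and direction.** Each gene is evaluated under two directional
hypotheses: enrichment-in-high plus depletion-in-low (knockout raises the
reporter; the gene maintains the progenitor state) and the mirror
combination (knockout blocks reporter induction; the gene drives
differentiation). Each pair is combined by Fisher's method,
$\psi P = S_{\chi^2_4}(-2(\ln p_a + \ln p_b))$. The two comparisons share
background samples — each sorting bin sits in the other comparison's
reference pool — so the combination is reported as a *pseudo* p-value and
never treated as calibrated; the direction call at `psi_alpha` is
correspondingly qualitative. The gene-level effect size (`beta_score`) is
the median guide log2 fold change of the high-vs-rest comparison averaged
over replicates; this is a documented proxy for the ambiguous "beta score"
axis label in the upstream tooling, which mixes rank-aggregation and
maximum-likelihood vocabularies.

## Perturb-seq arm

**Preprocessing.** A guide is detected in a cell at `min_umis >= 3` capture
UMIs (no external threshold exists; 3 separates real integrations from
stray molecules at typical capture depths). Cells are kept when they have
exactly one detected guide, strictly less than 5% mitochondrial reads, and
at least 200 total UMIs — the boundary semantics (strict `<` for
mitochondria, `>=` for RNAs) follow the stated filters, and "200 RNAs" is
read as total UMIs rather than detected genes (ambiguity noted).
Normalization is `log1p` of counts scaled per cell to the median total
count. A Pearson-residual normalization would also be defensible; the
downstream trajectory uses correlation distances, which are insensitive to
the monotone choice at this fidelity, and the normalization sits behind a
single function boundary so it can be swapped. Variable features are the
top 2000 genes by standardized dispersion (variance/mean z-scored within
mean-expression bins, deterministic tie-break by gene id).

**Trajectory.** Cell-cell distances are $1 - $ Pearson correlation over the
selected features. Classical multidimensional scaling (double-centered
squared distances, eigen-decomposition, 10 dimensions) gives coordinates;
signs are fixed deterministically (largest-magnitude loading positive).
Above `n_landmarks = 500` cells, a seeded landmark subset is embedded
exactly and the remaining cells are projected onto the same axes from
their squared distances to the landmarks (Nystrom projection), so the full
$n \times n$ matrix is never formed; on overlapping problem sizes the
landmark embedding reproduces the exact pairwise geometry to high
correlation (tested). A principal curve is fitted by iterating: order cells
by current curve position (initialized from the first embedding axis),
smooth each coordinate against that order with a centered rolling mean
spanning 10% of cells, downsample the smoothed path to 100 nodes, and
project every cell onto the piecewise-linear curve. Convergence is declared
when the mean absolute change in normalized arc-length position falls below
`tol = 1e-4`; otherwise the best iterate is returned flagged. Pseudotime is
arc length min-max rescaled to $[0, 1]$ (ties at the endpoints are
possible where cells project onto the curve's ends). The axis is oriented
by markers: if mean progenitor-marker expression (ITGB1/KRT14/ITGA6-like)
correlates positively with pseudotime, the axis is flipped, guaranteeing
progenitors at $t \approx 0$ and differentiation-marker-high cells
(KRTDAP/SBSN/KRT10-like) at $t \approx 1$.

**Phenotyping.** For each target gene, a one-sided Mann-Whitney test
compares the pseudotimes of its single-guide cells against all other
single-guide cells; the p-value is exact for small tie-free pooled samples
and otherwise uses the tie- and continuity-corrected normal approximation.
The signed standardized U is the shift Z (negative = target cells sit lower
on the trajectory). Density structure is summarized by a Gaussian KDE of
each gene's cell pseudotimes and of all cells, evaluated at 40 evenly
spaced points on $[0, 1]$ (the grid range is pinned to pseudotime's
codomain; the evaluation range is not externally specified). The bandwidth
is Scott's rule, $\hat\sigma n^{-1/5}$, recorded in the output and
overridable. A window of 10 grid points rolls along the axis at stride 1
(40 − 10 + 1 = 31 windows) and one-sided Mann-Whitney tests compare the 10
target-density values against the 10 reference-density values in each
window, in both directions. The windowed test compares density values, as
described; a cell-pooling variant would test different units and is not
claimed equivalent.

**Direction calls.** A gene is called `pro_differentiation` when (i) some
window in the low-pseudotime region (first 10 windows) shows
target-over-reference density enrichment at `alpha = 0.05`, (ii) the shift
Z is negative, and (iii) the gene's BH-adjusted two-sided shift test is
significant at the same `alpha`; `pro_progenitor` is the mirrored call in
the high region. Condition (iii) goes beyond a bare window-plus-sign rule,
and deliberately so: the window statistic compares 10 *smooth, strongly
autocorrelated* KDE ordinates, so under the null a gene whose density
estimate merely wiggles upward across a region achieves complete
separation (p $\approx 5 \times 10^{-6}$) in some window — roughly half of
null genes would otherwise be callable on the window criterion alone.
Anchoring the call to the genome-wide-adjusted shift test restores a
per-gene false-positive rate well below 5% while leaving power at the
planted effect sizes untouched (both measured in the acceptance study).
Window p-values are reported unadjusted; the shift p is BH-adjusted across
genes.

## Integration

Genes present in both arms are joined; the cross-arm agreement is the
Spearman correlation between flow beta scores and pseudotime shift Z.
Candidates are ranked by the mean of the two within-arm effect-size ranks
(beta score and shift Z, ascending, so the strongest pro-differentiation
candidates rank first), with a concordance flag when the signs agree. Rank
averaging is used instead of a p-value combination because psi-P and the
shift p are dependent, differently calibrated quantities.

## Synthetic data generator

The generator is the package's study-conditions oracle, not a convenience
fixture. Defaults encode the conditions the recovery experiments assume:

* Library: 50 target genes x 4 guides, 72 safe-targeting and 16
  non-targeting controls (a control fraction close to the screened
  library's 216/620); the screened-library emulation used for the count
  checks is 101 genes x 4 + 216 controls = 620 guides. All spacers are
  random unique 20-mers.
* Cells: latent differentiation time $t \sim U(0,1)$. A knockout with
  latent-time effect $\delta < 0$ compresses its cells' time to
  $t(1+\delta)$ — cells fail to progress — and $\delta > 0$ compresses
  toward 1. Planted effects default to five pro-differentiation knockouts
  at $\delta = -0.3$ with reporter effect $-1.5$ log-units.
* Expression: progenitor markers fall and differentiation markers rise
  logistically in $t$ (midpoint 0.5, steepness 0.1; no functional form is
  externally specified, and a logistic is the field's default switch
  shape). Targeted genes are expressed flat and knocked down to 30%
  residual in cells carrying their guides. Counts are negative binomial
  (dispersion 0.15, typical of 10x data) around a lognormal per-cell depth
  (mean 2000 UMIs). A designated 5% of genes are mitochondrial with ~2.5%
  mean read share and a lognormal per-cell spread, so a realistic tail of
  cells fails the 5% QC gate.
* Guide capture: integrations per cell are Poisson(MOI = 0.3) conditioned
  positive (drug selection removes uninfected cells); capture UMIs per
  integration are Poisson with mean 15. About 14% of guide-carrying cells
  are multiplets, matching the truncated-Poisson expectation.
* Flow arm: two replicates of 30,000 cells; multi-guide cells are dropped
  before sorting (rare at this MOI). The reporter is a logistic function
  of latent time (amplitude 3 log-units) plus the guide's reporter effect
  and Gaussian noise (sd 0.5). Sorting gates take the bottom 30% (low),
  30-70% (medium) and top 13.5% (high) of the reporter distribution — the
  high-gate fraction matches the benchmarked day-3 KRT10-high population —
  with an unsorted sample drawn uniformly from all retained cells; the gap
  between the medium and high gates is deliberately unsampled, as in FACS
  practice. Reads per bin sample are multinomial at a fixed depth of
  200,000 UMIs, so per-sample totals are exactly conserved.
* `n_cells = 16800` yields ~200 single-guide cells per target after QC,
  the cells-per-target the recovery study assumes.

What the generator does **not** emulate: ambient RNA, collision doublets,
batch effects, guide-efficiency heterogeneity, read-level errors, or
branching trajectories. Passing recovery tests therefore demonstrate that
the statistics recover the planted structure under the stated noise model,
not robustness to those real-data pathologies.

## Numerical choices and degenerate inputs

* Mann-Whitney: exact distribution for tie-free pooled samples up to 20;
  tie-corrected normal approximation with continuity correction otherwise;
  complete tie degeneracy returns p = 1. Ties get average ranks.
* KDE: an automatic (Scott) bandwidth requires two distinct values; an
  explicit bandwidth admits any non-empty sample, including a single
  point.
* Permutation p-values use the add-one estimator and so never return 0.
* MDS eigenvalues below a relative tolerance of the leading one collapse
  to zero columns; the curve fit's node downsampling keeps at most 100
  nodes; principal-curve non-convergence returns the final iterate with
  `converged = FALSE`.
* All randomness flows through explicit integer seeds; stage sub-seeds are
  derived by hashing the stage name into the global seed (all arithmetic
  below $2^{31}$), so adding a stage never perturbs another stage's
  stream.

## Problem sizes used by the validation studies

The recovery study runs 20 independent end-to-end simulations at the
default conditions above (each ~17k cells, 288 guides, 160 genes) with a
30-iteration principal-curve budget — the fit's ordering plateaus within
~15 sweeps at these sizes — and 1000-draw permutation nulls. The RRA
calibration study uses 1000 null genes with 1000 permutations. The
sorted-bin recovery study plants a single strong reporter-lowering
knockout (reporter effect $-2$, $\delta = -0.4$) in each of 20 screens.
These study sizes are stated in `scripts/acceptance.R` and the test suite,
which recompute every quantity from scratch.

## Known limitations

* psi-P is a pseudo p-value by construction; treat flow direction calls as
  nominations, not calibrated discoveries.
* The windowed density statistic is anti-conservative in isolation (see
  the direction-call rationale); it is only ever used in conjunction with
  the adjusted shift test.
* The principal curve is single-branch; datasets with genuine branching
  need a different trajectory model upstream, and the pipeline accepts a
  precomputed pseudotime table for that purpose.
* With very few safe-targeting guides the permutation background is
  coarse and small permutation p-values saturate at the add-one floor;
  keep the control arm a substantial fraction of the library, as the
  screened library does.
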