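---
title: "Methods: mapping regulatory circuits from Perturb-seq screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping regulatory circuits from Perturb-seq screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `perturbcircuit`, the
choices we made where the design was genuinely open, what the synthetic
generator does and does not emulate, and the package's known limitations.

## The screen and its assumptions

The package targets pooled CRISPR knockout screens with a single-cell
RNA-seq readout in which a *focused* panel of regulators (tens of targets,
a few sgRNAs each, plus non-targeting controls) is perturbed in a
relatively homogeneous cell population. Three assumptions follow:

* each singlet cell carries exactly one perturbation, identified from its
  captured guide UMIs, and non-targeting cells define the transcriptional
  baseline;
* a perturbation's effect on a gene is an additive shift of log-scale
  expression, shared across that perturbation's cells (no per-cell effect
  heterogeneity beyond sampling noise);
* genes respond in co-regulated groups ("programs"), so the columns of the
  perturbation-by-gene coefficient matrix carry cluster structure.

## Quality control and guide assignment

Cells are retained when they have at least `min_genes = 200` detected
genes, at least `min_counts = 1000` total UMIs, and at most
`max_mito = 0.20` mitochondrial fraction. All three boundaries are
*inclusive for retention*: the filters exclude cells with *fewer than* 200
genes, totals *below* 1000, or *more than* 20% mitochondrial reads, so a
cell sitting exactly on a boundary stays.

The guide caller considers a guide a candidate when its UMI count reaches
`min_umi = 3`. A single candidate, or a top candidate at least
`dominance_ratio = 2` times the runner-up, makes a singlet; two or more
candidates with no dominant one make a doublet; no candidate leaves the
cell unassigned. Both parameters are exposed because capture chemistry
varies between platforms. Doublets and unassigned cells are dropped from
all downstream stages. sgRNAs are collapsed to their target gene by
default; the guide-level design can be requested by passing guide
identities as the perturbation labels.

## Differential expression

Each perturbation is compared with control cells by a two-sided Wilcoxon
rank-sum test on log-normalized expression
(`log1p(count / cell_total * 10^4)`), restricted to genes detected in
strictly more than half of the control cells. For groups of at most eight
cells without ties the exact rank-sum distribution is used; otherwise a
tie-corrected normal approximation with continuity correction. Log2 fold
changes are computed on the de-logged scale with a pseudocount of `1e-9`.
False-discovery control is Benjamini-Hochberg, by default within each
perturbation's family of tested genes (`fdr_family = "global"` pools all
perturbations instead); per-perturbation families match the convention of
reporting per-perturbation DE gene counts.

## Regulatory-matrix inference

For each highly variable gene the model is

$$\min_{b_0,\beta}\; \frac{1}{2n}\lVert y - b_0 - I_\Delta \beta\rVert_2^2
 + \lambda\Big(\alpha\lVert\beta\rVert_1 + \tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\Big)$$

with $I_\Delta$ the binary cell-by-perturbation indicator matrix. Two
conventions deserve comment:

* **Unpenalized intercept.** Without an intercept, $\beta$ confounds
  baseline expression with perturbation effects; the control cells' all-zero
  indicator rows make the intercept an estimate of the control mean (at
  $\lambda = 0$ it equals the control mean exactly).
* **$1/(2n)$ loss scaling**, so $\lambda$ is comparable across sample
  sizes.

The solver is cyclic coordinate descent with soft thresholding on
precomputed cross-products, vectorized across genes (all genes share one
design, so one $p \times p$ Gram matrix serves every regression).
Convergence is declared when the largest coefficient change in a sweep
falls below `tol`; non-convergence is flagged, not fatal.

Cells are split 80/10/10 into training/validation/test sets, stratified by
perturbation so every perturbation appears in training. One global
$\lambda$ (shared by all genes, selected on pooled validation MSE) yields
a single interpretable matrix; per-gene selection would let every gene
choose its own bias-variance trade-off and destroy cross-gene
comparability of coefficients.

**Lambda rule.** We select $\lambda$ by the one-standard-error rule: the
largest $\lambda$ whose pooled validation MSE is within one standard error
of the minimum, with the SE estimated from the spread of the individual
squared validation residuals. The validation-MSE curve of an indicator
design is nearly flat around its minimum — the handful of coefficients per
gene contributes little prediction variance — so the plain minimum
routinely keeps ~20% of truly inactive coefficients at small nonzero
values, while the 1-SE model is statistically indistinguishable in error
and drives the inactive set to exact zeros. `lambda_rule = "min"` restores
plain minimization.

$\alpha$ defaults to 0.5 (both penalties active, neither dominant) and is
exposed in the configuration.

Highly variable genes are selected by the binned mean-dispersion
convention the default thresholds come from: per-gene mean and dispersion
(variance/mean) on the de-logged scale, log-dispersion z-scored within 20
equal-width bins of `log1p(mean)`, retaining genes with
`0.0125 <= log1p(mean) <= 3` and normalized dispersion at least 0.5.

## Gene programs

Genes are clustered on their fitted coefficient columns via a k = 5
nearest-neighbour graph (neighbour lists mutualized by union, unit edge
weights, distance ties broken lexicographically so the graph is
deterministic) followed by Louvain community detection. Clusters smaller
than `min_program_size = 10` merge into the cluster with the most
correlated mean coefficient profile. Programs are labelled `P-0`,
`P-1`, ... in decreasing size; since size ranks are data-dependent,
analyses that need a specific planted program match programs by overlap
rather than by label.

**Distance metric.** The default is cosine distance, with Euclidean
available via `method`. The reason is geometric: genes of one program
share the *direction* of their perturbation response, but their magnitudes
spread along a continuum (biologically, and additionally through the
mean-dependent compression of the log transform). Under Euclidean
distance that continuum becomes a nearest-neighbour *chain*, and
modularity optimization cuts chains into arbitrary segments — we observed
planted programs splitting into two or three clusters. Cosine distance
collapses each response direction to a point and recovers planted
partitions with adjusted Rand index around 0.95 on the default benchmark.

A program's signature is its top `fraction = 0.25` of member genes by
regulatory weight, where the weight of a gene is its mean absolute
coefficient over the program's top three perturbations by mean member
loading (the aggregation is config-exposed; the notion "regulatory weight
within the program" does not pin down a formula, and restricting to the
program's own top perturbations prevents unrelated noise coefficients from
reordering genes).

Program activity per cell is the mean expression of signature genes minus
the mean of expression-bin-matched control genes (24 quantile bins, up to
100 controls per signature gene, sampled with a fixed seed, signature
genes excluded from the control pool). The subtraction removes per-cell
depth and global shifts exactly: adding a constant to every gene of a cell
leaves the score unchanged. A plain z-score mean (`method = "zmean"`) is
available. Per-perturbation program enrichment uses Welch's t-test against
control cells with BH correction across all (perturbation, program) pairs.

## Interaction indices

A perturbation's target vector on a fitness pathway holds its signed log2
fold changes masked at `fdr < 0.05`, zero elsewhere. Signed effects are
essential: antagonism *is* opposite signs on shared targets. The pathway
similarity of two perturbations is the $\Omega$-weighted cosine
$S(a,b) = a^\top\Omega\,b / \sqrt{(a^\top\Omega a)(b^\top\Omega b)}$ with
$\Omega$ assembled from PPI edge scores (identity diagonal, symmetrized
off-diagonal scores). $|S| \le 1$ is only guaranteed when $\Omega$ is
positive semidefinite, so negative eigenvalues are clipped to zero and the
diagonal rescaled to one; the object records whenever clipping changed an
eigenvalue by more than `1e-6`. Per-pathway similarities aggregate by a
weighted mean (equal weights by default, config-exposed) and map linearly
onto the 0-100 scale: SI $= 100\max(0, S)$, AI $= 100\max(0, -S)$, so at
most one of the two is positive, "none" sits at 0 and "full" at 100. The
exact aggregation that produced any particular published index value is
not derivable from a methods description alone; the linear clip is one
admissible choice, anchored at those endpoints. Zero-norm target vectors
make $S$ undefined and are reported as missing, never coerced to 0.

## Clinical translation

Bulk samples are scored by the mean of per-gene z-scored signature
expression (constant genes excluded; a rank-based alternative would be the
natural extension for strongly non-normal cohorts). Survival association
uses Cox proportional-hazards regression (Efron tie handling, Newton
iteration via the `survival` package), unadjusted or adjusted for age,
cytogenetic risk group (ordered categories, treatment contrasts) and
mutation flags; hazard ratios are reported per unit score with Wald 95%
intervals. Kaplan-Meier stratification cuts at the median score; samples
exactly at the cut go to the low stratum, so with an odd sample count the
larger group contains the median sample.

Specificity uses size-matched permutation: the unadjusted HR of the
signature is compared against `n_perm` uniform random gene sets of the
same size. Scores are standardized before every fit because a random
set's mean z-score has variance about $1/\text{size}$ while a co-regulated
signature's is near 1 — per-raw-unit HRs would not be comparable across
that difference. Null fits are unadjusted: the permutation targets the
signature's specificity, not the covariate model, and adjusted refits at
$10^4$ draws would dominate runtime. The empirical p uses the add-one
estimator $(1 + \#\{HR_{null} \le HR_{obs}\})/(n_{perm}+1)$, which cannot
return zero. Drug-sensitivity association is pairwise-complete Pearson
correlation of scores with per-drug AUC, BH-corrected across drugs;
negative correlations are labelled sensitizing because lower AUC means
higher sensitivity.

## The synthetic generator

`generate_truth()` plants the hidden state a screen analysis tries to
recover; `simulate_counts()`, `simulate_ppi()`, `simulate_pathways()`,
`simulate_cohort()` and `simulate_drug_response()` emit observable data
with that truth embedded. Defaults mirror the screen geometry the package
targets: 16 targets with 3 sgRNAs each plus non-targeting controls, 182
cells per guide, 500 control cells, 2,000 genes, 17 programs.

Design choices, fixed once and documented here:

* **Counts** are negative binomial with per-gene dispersion and log-normal
  library-size factors ($\sigma = 0.3$); NB is the standard descriptive
  model for UMI counts and exposes log-scale effects cleanly.
* **Effects**: each (program, target) pair draws one level uniformly from
  [0.3, 0.55] with ±0.05 per-gene jitter (per-gene magnitudes within
  [0.2, 0.6], signs random per pair). The level-plus-jitter hierarchy
  encodes that a program responds to a perturbation *as a unit*; fully
  independent per-gene magnitudes would create a magnitude continuum with
  no cluster structure to recover. Programs are wired to targets so every
  program has a distinct response profile (program $j$ responds to target
  $j \bmod T$, later programs to a pair of targets).
* **Program genes are the variable ones**: dispersion 0.4–0.8 versus
  0.05–0.2 for background genes, with baseline means (log-normal, clipped
  so `log1p` means stay inside the HVG window) overlapping the background
  distribution. This realizes, in generator form, the premise of HVG
  selection — that biologically co-regulated genes are overdispersed
  relative to housekeeping background at matched expression.
* **Doublets** carry two independently drawn guides; guide UMI counts are
  NB(mean 100, size 20), so the dominance rule has realistic material and
  recovers a planted doublet rate to within a few percent.
* **Cohorts**: a latent per-sample activity $a \sim N(0,1)$ loads on
  signature genes with strength 2 over unit noise; the hazard is
  proportional to $\exp(\log(\text{HR})\cdot s)$ with $s$ the standardized
  true score, so a mean-z scoring of the signature estimates the planted
  log-HR with slope 1. Censoring is independent of the score.
* **Seeds**: every stage's seed derives from one master seed through a
  counter-based stream split (`seed_stream()`), making the entire pipeline
  bit-reproducible from a single integer.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real data: ambient RNA and barcode swapping, batch
and cell-cycle structure, per-cell effect heterogeneity (e.g. partial
editing), mean-variance trends beyond NB, read-level artifacts, and
population structure in cohorts. Results on real screens additionally
depend on reference annotation and normalization choices outside this
package's scope.

## Problem sizes and numerical choices

The shipped demo simulates 6 targets × 3 guides × 120 cells plus 360
controls over 2,000 genes and runs the full pipeline in well under a
minute; the recovery benchmark used by the test suite runs the default
16-target screen (~9,200 cells) in about half a minute. Coordinate
descent uses `tol = 1e-8` on the maximum coefficient change with warm
starts down the λ path; the λ grid spans four decades below the smallest
all-zero λ in 30 log-spaced steps. Degenerate cases are handled
explicitly: all-tied genes get p = 1, zero-norm target vectors give
missing similarities, constant genes are excluded from z-scoring, empty
QC output warns instead of erroring, and distance or weight ties break
lexicographically so every graph and signature is deterministic.

## Known limitations

* The elastic net treats perturbations as additive and homogeneous within
  a label; epistasis between co-occurring guides (doublets) is excluded
  rather than modelled.
* One global λ trades per-gene optimality for cross-gene comparability;
  genes with unusually low noise are slightly over-shrunk.
* Louvain is run once per seed rather than consensus-clustered; program
  boundaries for genes between two programs are seed-stable but not
  guaranteed optimal.
* The SI/AI scale is anchored only at its endpoints; absolute index values
  are comparable within an analysis, not across datasets with different
  pathway sets or PPI sources.
* Cox models assume proportional hazards; no diagnostic is run
  automatically.
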