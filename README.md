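# perturbcircuit

Circuit-level analysis of pooled single-cell CRISPR (Perturb-seq) screens,
aimed at studies that knock out a focused panel of transcriptional or
chromatin regulators (for example the Menin-MLL, Polycomb, and HAT
complexes in acute myeloid leukemia models) and ask three questions:

1. **What does each perturbation do?** Infer a perturbation-by-gene
   *regulatory matrix* and cluster genes into co-regulated
   *transcriptional programs*.
2. **Which perturbations cooperate or oppose each other?** Score pairwise
   synergy and antagonism from their effects on fitness pathways, weighted
   by a protein-protein interaction network.
3. **Do the programs matter clinically?** Translate program signatures into
   survival associations and drug-sensitivity correlations in bulk patient
   cohorts.

Every stage is backed by a ground-truthed synthetic-data generator, so the
whole pipeline is testable end to end without any external download.

## The model

Cells pass QC (at least 200 detected genes, at least 1000 UMIs, at most
20% mitochondrial reads) and are assigned to perturbations from their
captured sgRNAs (UMI threshold plus dominance rule; doublets and
unassigned cells are excluded). For each highly variable gene *g*
(mean/dispersion selection with bounds 0.0125/3 and dispersion z-score at
least 0.5), the log-normalized expression **y** is regressed on the binary
cell-by-perturbation indicator matrix *I* with an elastic-net penalty:

    min_{b0, beta}  1/(2n) || y - b0 - I beta ||^2
                    + lambda ( alpha ||beta||_1 + (1 - alpha)/2 ||beta||_2^2 )

solved by cyclic coordinate descent with soft thresholding. Cells are
split 80/10/10 into training/validation/test strata; one global lambda is
chosen on the validation split (one-standard-error rule). The columns of
the fitted matrix **beta** are clustered with Louvain community detection
on a k = 5 nearest-neighbour graph to define gene programs; each program's
*signature* is its top 25% of genes by regulatory weight.

Pairwise perturbation interactions use the PPI-weighted inner product

    S(a, b) = <a, b>_Omega / sqrt( <a, a>_Omega <b, b>_Omega ),
    <a, b>_Omega = a' Omega b

where **a**, **b** are signed, FDR-masked log2 fold-change vectors on a
fitness pathway and Omega is the (positive-semidefinite-repaired) PPI
similarity matrix. The weighted mean of per-pathway similarities maps
linearly onto a Synergistic Index and an Antagonistic Index on a 0-100
scale. Clinically, signatures are scored in bulk cohorts by mean z-score,
associated with overall survival by covariate-adjusted Cox regression and
Kaplan-Meier stratification, checked for specificity against size-matched
random gene sets, and correlated with drug AUC values (lower AUC = higher
sensitivity, so negative correlations mark sensitizing programs).

## Worked example

The demo pipeline simulates a screen (6 targets x 3 sgRNAs x 120 cells
plus 360 non-targeting controls, 2,000 genes, 8 planted programs), then
runs QC, assignment, differential expression, regulatory-matrix inference,
program discovery, interaction scoring, and the clinical stage:

```r
library(perturbcircuit)
manifest <- run_pipeline(pipeline_config(list(master_seed = 17,
                                              output_dir = "demo_out")))
read.csv("demo_out/clinical.csv")
```

```
 program   n n_events hazard_ratio     ci_lo     ci_hi        cox_p adjusted
     P-0 300      213    0.5378091 0.4546112 0.6362328 4.706563e-13     TRUE
    logrank_p permutation_p n_permutations
 3.833266e-10   0.004975124            200
```

The largest program's activity score was planted as protective with a
hazard ratio of 0.5 per unit; the covariate-adjusted Cox fit recovers
HR = 0.54 (95% CI 0.45-0.64), the Kaplan-Meier strata separate
(log-rank p = 3.8e-10), and the signature is more prognostic than 199 of
200 size-matched random gene sets (permutation p = 0.005). The drug table
shows the planted sensitizing compound and null compounds at their
expected correlations:

```
         drug   n   pearson_r            p          fdr sensitizing
  DRUG_TARGET 300 -0.35122857 3.885031e-10 3.885031e-09        TRUE
 NULL_DRUG_01 300  0.01307482 8.215694e-01 9.132606e-01       FALSE
```

`demo_out/interactions.csv` holds the pairwise Synergistic/Antagonistic
Indices (in the demo, the strongest antagonistic pair scores AI = 53 and
the strongest synergistic pair SI = 48), and `demo_out/manifest.json`
records a content hash for every artifact — rerunning with the same
`master_seed` reproduces every hash bit for bit.

The same pipeline runs from the shell:

```sh
Rscript scripts/pipeline.R --config inst/extdata/demo_config.yaml --out demo_out --seed 17
```

Real data enter through the same readers the demo uses: a CellRanger-style
Matrix-Market triplet, a guide-capture TSV, GMT pathway files (curated
fitness sets ship in `inst/extdata/fitness_pathways.gmt`), a PPI edge TSV,
and cohort/drug CSVs; set `sim: null` in the config and point `paths:` at
the files.

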