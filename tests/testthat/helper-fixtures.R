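# fixtures shared across test files, built once per test run

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) assign(name, builder(), .fixture_env)
  get(name, .fixture_env)
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

auroc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# moderate screen for module-level tests
small_screen <- function() fixture("small_screen", function() {
  cfg <- sim_config(n_genes = 800L, n_targets = 6L, n_programs = 6L,
                    genes_per_program = 40L, cells_per_guide = 60L,
                    n_control_cells = 180L, doublet_rate = 0.05, seed = 101L)
  truth <- generate_truth(cfg)
  sim <- simulate_counts(truth)
  m <- filter_cells(compute_qc_metrics(sim$counts))
  asg <- assign_guides(sim$guides, cell_ids = rownames(m$counts))
  expr <- normalize_counts(m)
  list(cfg = cfg, truth = truth, sim = sim, counts = m, asg = asg, expr = expr)
})

# the full-scale recovery benchmark shared by the acceptance tests
benchmark <- function() fixture("benchmark", function() {
  cfg <- sim_config(seed = 2024L)
  truth <- generate_truth(cfg)
  sim <- simulate_counts(truth)
  m <- filter_cells(compute_qc_metrics(sim$counts))
  asg <- assign_guides(sim$guides, cell_ids = rownames(m$counts))
  expr <- normalize_counts(m)
  hvgs <- select_hvgs(expr)
  design <- perturbation_design(asg)
  R <- fit_regulatory_matrix(expr, design, hvgs, seed = 7L)
  graph <- build_gene_knn(R, k = 5)
  programs <- louvain_programs(graph, R, seed = 7L)
  list(cfg = cfg, truth = truth, sim = sim, counts = m, asg = asg,
       expr = expr, hvgs = hvgs, design = design, R = R,
       graph = graph, programs = programs)
})

# truth object with a small gene universe for cohort-level tests
cohort_truth <- function() fixture("cohort_truth", function() {
  generate_truth(sim_config(n_genes = 600L, n_targets = 4L, n_programs = 4L,
                            genes_per_program = 30L, cells_per_guide = 40L,
                            n_control_cells = 120L, seed = 77L))
})

cohort_signature <- function(truth, program = 0L, n = 15L) {
  names(truth$program_assignment)[
    which(truth$program_assignment == program)][seq_len(n)]
}

# hand-specified 10-cell QC fixture over 250 genes (10 mitochondrial):
# each cell is constructed to have an exactly known number of detected
# genes, total count, and mitochondrial count
qc_fixture_spec <- data.frame(
  cell = sprintf("cell%02d", 1:10),
  detected = c(200L, 199L, 250L, 250L, 150L, 240L, 220L, 201L, 230L, 250L),
  total = c(1000L, 1500L, 999L, 2000L, 5000L, 1200L, 1100L, 1000L, 1000L, 3000L),
  mito = c(200L, 0L, 0L, 402L, 0L, 120L, 55L, 190L, 0L, 300L)
)
# cells failing the default filters: cell02/cell05 (genes), cell03 (counts),
# cell04 (mito fraction 0.201); boundaries (cell01: 200 genes, 1000 counts,
# 20% mito) are retained
qc_fixture_fail <- c("cell02", "cell03", "cell04", "cell05")

qc_fixture <- function() {
  genes <- c(sprintf("G%03d", 1:260), sprintf("MT-%02d", 1:10))
  counts <- matrix(0L, nrow = 10, ncol = 270,
                   dimnames = list(qc_fixture_spec$cell, genes))
  for (i in 1:10) {
    d <- qc_fixture_spec$detected[i]
    tot <- qc_fixture_spec$total[i]
    mito <- qc_fixture_spec$mito[i]
    n_reg <- d - (mito > 0L)
    counts[i, seq_len(n_reg - 1L)] <- 1L
    counts[i, n_reg] <- tot - mito - (n_reg - 1L)
    if (mito > 0L) counts[i, "MT-01"] <- mito
  }
  counts
}
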