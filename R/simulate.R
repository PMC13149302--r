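#' Simulation configuration for a synthetic Perturb-seq screen
#'
#' Bundles every knob of the ground-truthed generator. Defaults reproduce the
#' structure of a focused epigenetic-regulator screen: 16 targets with 3
#' sgRNAs each plus non-targeting controls, 182 cells per guide, planted
#' transcriptional programs whose activity is shifted by subsets of
#' perturbations, and negative-binomial UMI counts with log-normal
#' library-size variation.
#'
#' @param n_genes total number of genes (>= 200).
#' @param n_targets number of perturbed target genes.
#' @param n_guides_per_target sgRNAs per target.
#' @param n_programs number of planted transcriptional programs P (>= 2,
#'   at most `n_genes / 5`).
#' @param genes_per_program genes assigned to each program; remaining genes
#'   form an unstructured background class.
#' @param effect_range magnitude range (log scale) for planted per-gene
#'   perturbation effects.
#' @param cells_per_guide cells captured per targeting guide (>= 20).
#' @param n_control_cells total cells across the non-targeting guides.
#' @param doublet_rate fraction of cells carrying a second guide, in [0, 0.5).
#' @param libsize_sigma sd of the log-normal per-cell library-size factor.
#' @param n_mito_genes genes named with the mitochondrial prefix so that QC
#'   metrics have a non-trivial mitochondrial fraction.
#' @param program_dispersion,background_dispersion NB dispersion ranges for
#'   program and background genes; program genes are the biologically
#'   variable (overdispersed) population, which is what makes them — and
#'   not the unstructured background — highly variable downstream.
#' @param control_label perturbation label for non-targeting control guides.
#' @param seed master seed; all generator randomness derives from it via
#'   [seed_stream()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_targets = 16L,
                       n_guides_per_target = 3L,
                       n_programs = 17L,
                       genes_per_program = 60L,
                       effect_range = c(0.2, 0.6),
                       cells_per_guide = 182L,
                       n_control_cells = 500L,
                       doublet_rate = 0.1,
                       libsize_sigma = 0.3,
                       n_mito_genes = 10L,
                       program_dispersion = c(0.4, 0.8),
                       background_dispersion = c(0.05, 0.2),
                       control_label = "NTC",
                       seed = 1L) {
  assert_that(is_count(n_genes, 200L), "n_genes must be a count >= 200")
  assert_that(is_count(n_programs, 2L), "n_programs must be a count >= 2")
  assert_that(n_programs <= n_genes / 5,
              "invalid config: n_programs (%d) exceeds n_genes/5", n_programs)
  assert_that(is_count(n_targets, 1L), "n_targets must be a positive count")
  assert_that(is_count(n_guides_per_target, 1L),
              "n_guides_per_target must be a positive count")
  assert_that(is.numeric(effect_range) && length(effect_range) == 2L &&
                all(effect_range > 0) && effect_range[1] <= effect_range[2],
              "effect_range must be an increasing pair of positive magnitudes")
  assert_that(is.numeric(doublet_rate) && doublet_rate >= 0 && doublet_rate < 0.5,
              "doublet_rate must lie in [0, 0.5)")
  assert_that(n_programs * genes_per_program + n_mito_genes <= n_genes,
              "n_programs * genes_per_program + n_mito_genes exceeds n_genes")
  assert_that(is_count(seed), "seed must be set")
  structure(list(
    n_genes = as.integer(n_genes),
    n_targets = as.integer(n_targets),
    n_guides_per_target = as.integer(n_guides_per_target),
    n_programs = as.integer(n_programs),
    genes_per_program = as.integer(genes_per_program),
    effect_range = as.numeric(effect_range),
    cells_per_guide = as.integer(cells_per_guide),
    n_control_cells = as.integer(n_control_cells),
    doublet_rate = doublet_rate,
    libsize_sigma = libsize_sigma,
    n_mito_genes = as.integer(n_mito_genes),
    program_dispersion = as.numeric(program_dispersion),
    background_dispersion = as.numeric(background_dispersion),
    control_label = control_label,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate the ground truth of a synthetic screen
#'
#' Draws the fixed, hidden state that the downstream analysis tries to
#' recover: the gene-to-program assignment, the block-structured
#' perturbation-by-gene effect matrix (log-scale shifts), per-gene baseline
#' means and negative-binomial dispersions.
#'
#' Programs are wired to perturbations so that every program has a distinct
#' response profile: program `j` responds to target `j mod T`, and programs
#' beyond the number of targets additionally respond to target `(j+1) mod T`.
#' Each (program, target) pair carries one random sign; per-gene magnitudes
#' are drawn uniformly from `effect_range`. Rows of the effect matrix for the
#' control label are exactly zero.
#'
#' @param config a [sim_config()].
#' @return A list of class `synthetic_truth` with elements `gene_ids`,
#'   `targets`, `guides` (data frame sgRNA -> target), `control_label`,
#'   `program_assignment` (integer per gene, `NA` = background),
#'   `beta_true` ((targets + control) x gene matrix), `baseline_mu`,
#'   `dispersion`, `program_targets`, `config`.
#' @export
generate_truth <- function(config) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  cfg <- config
  with_seed(seed_stream(cfg$seed, 1L), {
    n_plain <- cfg$n_genes - cfg$n_mito_genes
    gene_ids <- c(sprintf("G%05d", seq_len(n_plain)),
                  if (cfg$n_mito_genes > 0L) sprintf("MT-%02d", seq_len(cfg$n_mito_genes)))
    targets <- sprintf("TGT%02d", seq_len(cfg$n_targets))
    guides <- data.frame(
      sgrna_id = c(t(outer(targets, seq_len(cfg$n_guides_per_target),
                           function(t, i) sprintf("%s_sg%d", t, i))),
                   sprintf("%s_sg%d", cfg$control_label, seq_len(cfg$n_guides_per_target))),
      target_gene = c(rep(targets, each = cfg$n_guides_per_target),
                      rep(cfg$control_label, cfg$n_guides_per_target)),
      stringsAsFactors = FALSE
    )

    P <- cfg$n_programs
    program_assignment <- rep(NA_integer_, cfg$n_genes)
    names(program_assignment) <- gene_ids
    pool <- sample(seq_len(n_plain), P * cfg$genes_per_program)
    program_assignment[pool] <- rep(seq_len(P) - 1L, each = cfg$genes_per_program)

    # distinct perturbation-response profile per program
    program_targets <- lapply(seq_len(P) - 1L, function(j) {
      tg <- targets[(j %% cfg$n_targets) + 1L]
      if (j >= cfg$n_targets)
        tg <- c(tg, targets[((j + 1L) %% cfg$n_targets) + 1L])
      tg
    })
    names(program_targets) <- sprintf("program_%d", seq_len(P) - 1L)
    sign_of <- lapply(program_targets, function(tg) {
      stats::setNames(sample(c(-1, 1), length(tg), replace = TRUE), tg)
    })

    beta_true <- matrix(0, nrow = cfg$n_targets + 1L, ncol = cfg$n_genes,
                        dimnames = list(c(targets, cfg$control_label), gene_ids))
    # one magnitude per (program, target) with small per-gene jitter: a
    # program responds to a perturbation as a unit (a program-level shift),
    # its member genes scattering tightly around that level
    jitter <- 0.05
    for (j in seq_len(P)) {
      members <- which(program_assignment == j - 1L)
      for (tg in program_targets[[j]]) {
        level <- stats::runif(1, cfg$effect_range[1] + 2 * jitter,
                              cfg$effect_range[2] - jitter)
        mag <- pmin(pmax(level + stats::runif(length(members), -jitter, jitter),
                         cfg$effect_range[1]), cfg$effect_range[2])
        beta_true[tg, members] <- sign_of[[j]][tg] * mag
      }
    }

    baseline_mu <- numeric(cfg$n_genes)
    in_program <- !is.na(program_assignment)
    is_mito <- startsWith(gene_ids, "MT-")
    # program-gene means are kept within the window that the downstream
    # mean filters retain (log1p mean below ~3 at typical library sizes)
    baseline_mu[in_program] <-
      pmin(pmax(stats::rlnorm(sum(in_program), log(2), 0.4), 1.2), 5)
    # background means overlap the program-gene range so that mean-binned
    # dispersion has a within-bin reference population of quiet genes (the
    # matrix emulates a detected-gene panel, not the full transcriptome)
    baseline_mu[!in_program & !is_mito] <-
      pmin(stats::rlnorm(sum(!in_program & !is_mito), log(1.4), 0.7), 5)
    baseline_mu[is_mito] <- stats::rlnorm(sum(is_mito), log(4), 0.3)
    names(baseline_mu) <- gene_ids
    # program genes are the biologically variable ones: higher NB dispersion
    # makes them (and not the unstructured background) highly variable, the
    # structure the downstream HVG selection assumes
    dispersion <- stats::runif(cfg$n_genes, cfg$background_dispersion[1],
                               cfg$background_dispersion[2])
    dispersion[in_program] <- stats::runif(sum(in_program),
                                           cfg$program_dispersion[1],
                                           cfg$program_dispersion[2])
    names(dispersion) <- gene_ids

    structure(list(
      gene_ids = gene_ids,
      targets = targets,
      guides = guides,
      control_label = cfg$control_label,
      program_assignment = program_assignment,
      program_targets = program_targets,
      beta_true = beta_true,
      baseline_mu = baseline_mu,
      dispersion = dispersion,
      config = cfg
    ), class = "synthetic_truth")
  })
}

#' Simulate single-cell UMI counts and guide captures
#'
#' Each cell carries one primary guide (and, with probability `doublet_rate`,
#' a second, independently drawn guide). Counts for a cell with log-scale
#' shift vector `s` are drawn NB(mu * exp(s) * libfactor, dispersion), where
#' the library-size factor is log-normal. Captured-guide UMI counts are drawn
#' NB as well, so the downstream calling rule has realistic material to
#' threshold.
#'
#' @param truth a [generate_truth()] result.
#' @param cells_per_guide,n_control_cells,doublet_rate override the values in
#'   `truth$config` (defaults: take them from the config).
#' @param seed integer seed for this stage.
#' @return A list of class `perturb_sim` with `counts` (a
#'   [perturb_counts] object, cells x genes), `guides` (per-cell captured
#'   guide table: cell_id, sgrna_id, target_gene, umi_count) and
#'   `truth_labels` (per-cell true perturbation and doublet status).
#' @export
simulate_counts <- function(truth,
                            cells_per_guide = truth$config$cells_per_guide,
                            n_control_cells = truth$config$n_control_cells,
                            doublet_rate = truth$config$doublet_rate,
                            seed = seed_stream(truth$config$seed, 2L)) {
  assert_that(inherits(truth, "synthetic_truth"), "truth must be a synthetic_truth")
  assert_that(is_count(cells_per_guide, 20L), "cells_per_guide must be >= 20")
  assert_that(is.numeric(doublet_rate) && doublet_rate >= 0 && doublet_rate < 0.5,
              "doublet_rate must lie in [0, 0.5)")
  cfg <- truth$config
  guides <- truth$guides
  is_ctrl_guide <- guides$target_gene == truth$control_label
  n_ctrl_guides <- sum(is_ctrl_guide)

  with_seed(as.integer(seed), {
    per_guide <- ifelse(is_ctrl_guide,
                        diff(floor(n_control_cells * (0:n_ctrl_guides) / n_ctrl_guides))[
                          cumsum(is_ctrl_guide)],
                        cells_per_guide)
    primary <- rep(seq_len(nrow(guides)), times = per_guide)
    n_cells <- length(primary)
    cell_ids <- sprintf("CELL%06d-1", seq_len(n_cells))

    is_doublet <- stats::runif(n_cells) < doublet_rate
    secondary <- rep(NA_integer_, n_cells)
    secondary[is_doublet] <- sample.int(nrow(guides), sum(is_doublet), replace = TRUE)

    # per-cell log-scale shift: sum of the carried targets' effect rows
    shift <- truth$beta_true[guides$target_gene[primary], , drop = FALSE]
    if (any(is_doublet)) {
      shift[is_doublet, ] <- shift[is_doublet, , drop = FALSE] +
        truth$beta_true[guides$target_gene[secondary[is_doublet]], , drop = FALSE]
    }

    libfac <- exp(stats::rnorm(n_cells, 0, cfg$libsize_sigma))
    mu <- exp(shift) * rep(truth$baseline_mu, each = n_cells) * libfac
    size <- rep(1 / truth$dispersion, each = n_cells)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = size),
                     nrow = n_cells, ncol = cfg$n_genes,
                     dimnames = list(cell_ids, truth$gene_ids))
    counts <- as_cell_gene_matrix(counts)

    guide_rows <- data.frame(
      cell_id = c(cell_ids, cell_ids[is_doublet]),
      guide_idx = c(primary, secondary[is_doublet]),
      stringsAsFactors = FALSE
    )
    guide_rows <- guide_rows[order(guide_rows$cell_id, guide_rows$guide_idx), ]
    guide_tab <- data.frame(
      cell_id = guide_rows$cell_id,
      sgrna_id = guides$sgrna_id[guide_rows$guide_idx],
      target_gene = guides$target_gene[guide_rows$guide_idx],
      umi_count = pmax(1L, stats::rnbinom(nrow(guide_rows), mu = 100, size = 20)),
      stringsAsFactors = FALSE,
      row.names = NULL
    )

    truth_labels <- data.frame(
      cell_id = cell_ids,
      primary_target = guides$target_gene[primary],
      secondary_target = ifelse(is_doublet, guides$target_gene[secondary], NA_character_),
      is_doublet = is_doublet,
      stringsAsFactors = FALSE
    )

    structure(list(
      counts = perturb_counts(counts),
      guides = guide_tab,
      truth_labels = truth_labels
    ), class = "perturb_sim")
  })
}

#' Simulate a protein-protein interaction edge list
#'
#' Generates an undirected, weighted PPI over the program genes with planted
#' block structure: gene pairs within the same program are connected with
#' probability `within_program_edge_prob`, pairs across programs with
#' probability `between_prob`. Edge scores lie in (0, 1], with within-program
#' edges drawn from a higher score band.
#'
#' @param truth a [generate_truth()] result.
#' @param within_program_edge_prob,between_prob edge probabilities with
#'   `0 <= between_prob < within_program_edge_prob <= 1`.
#' @param seed integer seed.
#' @return A data frame (class `ppi_edges`) with columns `gene_a`, `gene_b`,
#'   `score`.
#' @export
simulate_ppi <- function(truth, within_program_edge_prob = 0.8,
                         between_prob = 0.02,
                         seed = seed_stream(truth$config$seed, 3L)) {
  assert_that(inherits(truth, "synthetic_truth"), "truth must be a synthetic_truth")
  assert_that(is.numeric(between_prob) && is.numeric(within_program_edge_prob) &&
                between_prob >= 0 && between_prob < within_program_edge_prob &&
                within_program_edge_prob <= 1,
              "need 0 <= between_prob < within_program_edge_prob <= 1")
  genes <- names(truth$program_assignment)[!is.na(truth$program_assignment)]
  prog <- truth$program_assignment[genes]
  with_seed(as.integer(seed), {
    idx <- utils::combn(length(genes), 2L)
    same <- prog[idx[1, ]] == prog[idx[2, ]]
    p_edge <- ifelse(same, within_program_edge_prob, between_prob)
    keep <- stats::runif(ncol(idx)) < p_edge
    score <- ifelse(same[keep],
                    stats::runif(sum(keep), 0.4, 1),
                    stats::runif(sum(keep), 0.05, 0.5))
    structure(data.frame(
      gene_a = genes[idx[1, keep]],
      gene_b = genes[idx[2, keep]],
      score = score,
      stringsAsFactors = FALSE
    ), class = c("ppi_edges", "data.frame"))
  })
}

#' Simulate synthetic fitness pathway gene sets
#'
#' Builds named gene sets in the style of curated fitness pathways
#' (apoptosis, cell cycle, checkpoint control): each set draws its core from
#' `n_core_programs` consecutive planted programs (so several perturbations
#' hit each pathway, the situation interaction scoring needs) and is padded
#' with random background genes.
#'
#' @param truth a [generate_truth()] result.
#' @param n_pathways number of sets.
#' @param size genes per set.
#' @param n_core_programs programs contributing core genes per set.
#' @param seed integer seed.
#' @return A named list of character vectors.
#' @export
simulate_pathways <- function(truth, n_pathways = 3L, size = 40L,
                              n_core_programs = 3L,
                              seed = seed_stream(truth$config$seed, 4L)) {
  assert_that(inherits(truth, "synthetic_truth"), "truth must be a synthetic_truth")
  base_names <- c("SYN_APOPTOSIS", "SYN_CELL_CYCLE", "SYN_CHECKPOINT")
  nm <- c(base_names, sprintf("SYN_PATH_%02d", seq_len(max(0L, n_pathways - 3L)) + 3L))[
    seq_len(n_pathways)]
  background <- names(truth$program_assignment)[is.na(truth$program_assignment)]
  P <- truth$config$n_programs
  with_seed(as.integer(seed), {
    sets <- lapply(seq_len(n_pathways), function(i) {
      progs <- ((i - 1L) * n_core_programs + seq_len(n_core_programs) - 1L) %% P
      members <- names(truth$program_assignment)[
        truth$program_assignment %in% progs & !is.na(truth$program_assignment)]
      n_core <- min(length(members), ceiling(0.75 * size))
      core <- sample(members, n_core)
      pad <- sample(background, max(0L, size - n_core))
      sort(c(core, pad))
    })
    names(sets) <- nm
    sets
  })
}

#' Simulate a bulk expression cohort with survival outcomes
#'
#' Each sample has a latent program activity `a ~ N(0, 1)`; signature genes
#' load on it with strength `loading` on top of gene-level baselines and unit
#' Gaussian noise, so that a mean z-score over the signature recovers the
#' standardized true score `s = a * loading / sqrt(loading^2 + 1)` almost
#' noiselessly. Survival times are exponential with hazard proportional to
#' `exp(log(hr_per_unit) * s + covariate effects)`; censoring is independent
#' of the score.
#'
#' @param truth a [generate_truth()] result (supplies the gene universe).
#' @param signature character vector of signature genes (or a
#'   `program_signature`).
#' @param n_samples cohort size.
#' @param hr_per_unit planted hazard ratio per unit of true program score.
#' @param censor_rate expected fraction of censored samples.
#' @param loading signature gene loading on the latent activity.
#' @param seed integer seed.
#' @return A list of class `survival_cohort` with `expr` (samples x genes),
#'   `time`, `event`, `covariates`, `true_score`, `sample_ids`.
#' @export
simulate_cohort <- function(truth, signature, n_samples = 500L,
                            hr_per_unit = 0.5, censor_rate = 0.3,
                            loading = 2,
                            seed = seed_stream(truth$config$seed, 5L)) {
  assert_that(inherits(truth, "synthetic_truth"), "truth must be a synthetic_truth")
  if (inherits(signature, "program_signature")) signature <- signature$genes
  assert_that(length(signature) > 0, "signature must be non-empty")
  assert_that(all(signature %in% truth$gene_ids),
              "signature must be a subset of the gene universe")
  assert_that(hr_per_unit > 0, "hr_per_unit must be positive")
  assert_that(is_fraction(censor_rate) && censor_rate < 1,
              "censor_rate must lie in [0, 1)")
  genes <- truth$gene_ids
  with_seed(as.integer(seed), {
    sample_ids <- sprintf("S%04d", seq_len(n_samples))
    a <- stats::rnorm(n_samples)
    s <- a * loading / sqrt(loading^2 + 1)
    base <- stats::rnorm(length(genes), 5, 1.5)
    expr <- matrix(stats::rnorm(n_samples * length(genes)),
                   nrow = n_samples, dimnames = list(sample_ids, genes))
    expr <- expr + rep(base, each = n_samples)
    expr[, signature] <- expr[, signature, drop = FALSE] + loading * a

    covariates <- data.frame(
      age = round(stats::rnorm(n_samples, 60, 10)),
      risk_group = factor(sample(c("favorable", "intermediate", "adverse"),
                                 n_samples, replace = TRUE,
                                 prob = c(0.25, 0.5, 0.25)),
                          levels = c("favorable", "intermediate", "adverse")),
      FLT3 = stats::rbinom(n_samples, 1, 0.30),
      NPM1 = stats::rbinom(n_samples, 1, 0.25),
      TP53 = stats::rbinom(n_samples, 1, 0.10),
      DNMT3A = stats::rbinom(n_samples, 1, 0.20),
      CEBPA = stats::rbinom(n_samples, 1, 0.10),
      RUNX1 = stats::rbinom(n_samples, 1, 0.10),
      row.names = sample_ids
    )
    lp <- log(hr_per_unit) * s +
      0.02 * (covariates$age - 60) +
      0.3 * (covariates$risk_group == "adverse") -
      0.2 * (covariates$risk_group == "favorable") +
      0.25 * covariates$TP53 - 0.2 * covariates$NPM1
    time <- stats::rexp(n_samples, rate = 0.1 * exp(lp))
    event <- rep(1L, n_samples)
    cens <- stats::runif(n_samples) < censor_rate
    time[cens] <- time[cens] * stats::runif(sum(cens))
    event[cens] <- 0L
    structure(list(
      expr = expr, time = time, event = event, covariates = covariates,
      true_score = s, hr_per_unit = hr_per_unit, sample_ids = sample_ids
    ), class = "survival_cohort")
  })
}

#' Simulate a drug-sensitivity (AUC) table
#'
#' One target drug's area-under-the-curve values are generated with a chosen
#' population Pearson correlation to the supplied per-sample program scores;
#' the remaining drugs are independent nulls. Lower AUC means higher
#' sensitivity, so a protective program yields negative correlations.
#'
#' @param scores numeric per-sample program scores (e.g. the `true_score` of
#'   a [simulate_cohort()] result).
#' @param r_target population correlation of the target drug with the score,
#'   `|r_target| < 1`.
#' @param n_null_drugs number of additional uncorrelated drugs.
#' @param auc_mean,auc_sd location/scale of the AUC values.
#' @param seed integer seed.
#' @return A samples x drugs numeric matrix; the correlated drug is named
#'   `DRUG_TARGET`.
#' @export
simulate_drug_response <- function(scores, r_target, n_null_drugs = 9L,
                                   auc_mean = 100, auc_sd = 30, seed = 1L) {
  assert_that(is.numeric(scores) && length(scores) >= 3,
              "scores must be a numeric vector")
  assert_that(is.numeric(r_target) && abs(r_target) < 1,
              "|r_target| must be < 1")
  with_seed(as.integer(seed), {
    n <- length(scores)
    z <- as.numeric(scale(scores))
    target <- r_target * z + sqrt(1 - r_target^2) * stats::rnorm(n)
    nulls <- matrix(stats::rnorm(n * n_null_drugs), nrow = n)
    auc <- cbind(target, nulls) * auc_sd + auc_mean
    colnames(auc) <- c("DRUG_TARGET", sprintf("NULL_DRUG_%02d", seq_len(n_null_drugs)))
    rownames(auc) <- names(scores)
    auc
  })
}
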