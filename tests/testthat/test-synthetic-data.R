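test_that("truth generation labels every gene and zeroes control effects", {
  cfg <- sim_config(n_genes = 200L, n_targets = 3L, n_programs = 2L,
                    genes_per_program = 20L, seed = 0L)
  truth <- generate_truth(cfg)

  labels <- truth$program_assignment
  expect_length(labels, 200L)
  expect_true(all(labels[!is.na(labels)] %in% c(0L, 1L)))
  expect_gt(sum(is.na(labels)), 0)  # a background class exists

  expect_true(all(truth$beta_true[truth$control_label, ] == 0))

  # block structure: a perturbation's nonzero entries sit in its programs
  for (j in seq_along(truth$program_targets)) {
    members <- names(labels)[!is.na(labels) & labels == j - 1L]
    for (tg in truth$program_targets[[j]]) {
      expect_true(all(truth$beta_true[tg, members] != 0))
    }
  }
  nz_cols <- colnames(truth$beta_true)[colSums(truth$beta_true != 0) > 0]
  expect_true(all(nz_cols %in% names(labels)[!is.na(labels)]))

  # planted magnitudes respect the configured range
  mags <- abs(truth$beta_true[truth$beta_true != 0])
  expect_true(all(mags >= cfg$effect_range[1] & mags <= cfg$effect_range[2]))
})

test_that("generators are bit-reproducible for a fixed seed", {
  cfg <- sim_config(n_genes = 300L, n_targets = 3L, n_programs = 3L,
                    genes_per_program = 15L, cells_per_guide = 25L,
                    n_control_cells = 40L, seed = 5L)
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_identical(t1, t2)

  s1 <- simulate_counts(t1, seed = 3L)
  s2 <- simulate_counts(t2, seed = 3L)
  expect_identical(s1, s2)

  p1 <- simulate_ppi(t1, seed = 4L)
  expect_identical(p1, simulate_ppi(t2, seed = 4L))

  c1 <- simulate_cohort(t1, cohort_signature(t1, n = 10L), n_samples = 60L,
                        seed = 8L)
  expect_identical(c1, simulate_cohort(t2, cohort_signature(t2, n = 10L),
                                       n_samples = 60L, seed = 8L))
})

test_that("invalid generator configurations are rejected", {
  expect_error(sim_config(n_genes = 100L), "n_genes")
  expect_error(sim_config(n_programs = 500L, n_genes = 2000L), "n_programs")
  expect_error(sim_config(doublet_rate = 0.6), "doublet_rate")
  truth <- cohort_truth()
  expect_error(simulate_counts(truth, doublet_rate = -0.1), "doublet_rate")
  expect_error(simulate_counts(truth, cells_per_guide = 5L), "cells_per_guide")
  expect_error(simulate_cohort(truth, character(0)), "non-empty")
  expect_error(simulate_cohort(truth, "NOT_A_GENE"), "subset")
  expect_error(simulate_drug_response(rnorm(50), r_target = 1.2), "r_target")
})

test_that("doublet_rate = 0 yields only singlet cells and 182x3 cells per target", {
  cfg <- sim_config(n_genes = 400L, n_targets = 2L, n_programs = 2L,
                    genes_per_program = 20L, cells_per_guide = 182L,
                    n_control_cells = 60L, doublet_rate = 0, seed = 9L)
  truth <- generate_truth(cfg)
  sim <- simulate_counts(truth)
  expect_true(all(!sim$truth_labels$is_doublet))
  per_target <- table(sim$truth_labels$primary_target)
  expect_equal(unname(per_target[truth$targets]), rep(546L, 2L),
               ignore_attr = TRUE)  # 182 cells/guide x 3 guides
})

test_that("null simulation (all effects zero) shows no perturbed-vs-control shift", {
  cfg <- sim_config(n_genes = 300L, n_targets = 2L, n_programs = 2L,
                    genes_per_program = 15L, cells_per_guide = 100L,
                    n_control_cells = 200L, doublet_rate = 0, seed = 13L)
  truth <- generate_truth(cfg)
  truth$beta_true[] <- 0
  sim <- simulate_counts(truth, seed = 14L)
  pert <- sim$truth_labels$cell_id[sim$truth_labels$primary_target == "TGT01"]
  ctrl <- sim$truth_labels$cell_id[sim$truth_labels$primary_target == "NTC"]
  genes <- colnames(sim$counts$counts)[1:100]
  counts <- as.matrix(sim$counts$counts[, genes])
  p <- vapply(genes, function(g) {
    suppressWarnings(stats::wilcox.test(counts[pert, g], counts[ctrl, g])$p.value)
  }, 0)
  # p-values behave uniformly: ~5% below 0.05, no mass at the extreme tail
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.05)
  expect_lt(mean(p < 0.001), 0.03)
})

test_that("marginal counts match negative-binomial moments at 10,000 cells", {
  cfg <- sim_config(n_genes = 300L, n_targets = 1L, n_programs = 2L,
                    genes_per_program = 15L, cells_per_guide = 20L,
                    n_control_cells = 10000L, doublet_rate = 0,
                    libsize_sigma = 0, seed = 21L)
  truth <- generate_truth(cfg)
  sim <- simulate_counts(truth, seed = 22L)
  ctrl <- sim$truth_labels$cell_id[sim$truth_labels$primary_target == "NTC"]
  counts <- sim$counts$counts[ctrl, ]
  mu <- truth$baseline_mu
  disp <- truth$dispersion
  v_expected <- mu + mu^2 * disp
  n <- length(ctrl)
  m_obs <- Matrix::colMeans(counts)
  v_obs <- (Matrix::colSums(counts^2) - n * m_obs^2) / (n - 1)
  well_expressed <- mu > 0.5
  rel_err <- abs(v_obs - v_expected) / v_expected
  expect_lt(stats::median(rel_err[well_expressed]), 0.10)
  expect_gt(mean(rel_err[well_expressed] < 0.10), 0.8)
})

test_that("planted program scores separate perturbed cells from control", {
  fx <- small_screen()
  truth <- fx$truth
  # designate the most strongly shifted program
  shift_of <- vapply(seq_along(truth$program_targets), function(j) {
    members <- names(truth$program_assignment)[
      !is.na(truth$program_assignment) & truth$program_assignment == j - 1L]
    max(abs(truth$beta_true[truth$program_targets[[j]], members, drop = FALSE]))
  }, 0)
  j <- which.max(shift_of)
  members <- names(truth$program_assignment)[
    !is.na(truth$program_assignment) & truth$program_assignment == j - 1L]
  tg <- truth$program_targets[[j]][1]
  scores <- score_units(fx$expr, members, seed = 31L)
  sing <- fx$asg[fx$asg$status == "singlet", ]
  s_pert <- scores[sing$cell_id[sing$perturbation == tg]]
  s_ctrl <- scores[sing$cell_id[sing$perturbation == "NTC"]]
  sign_tg <- sign(truth$beta_true[tg, members[1]])
  expect_gt(auroc(sign_tg * s_pert, sign_tg * s_ctrl), 0.9)
})

test_that("PPI simulation has planted block structure", {
  truth <- generate_truth(sim_config(n_genes = 200L, n_targets = 2L,
                                     n_programs = 2L, genes_per_program = 5L,
                                     seed = 3L))
  # full within-program connectivity, no between edges: exactly 2 * C(5,2)
  ppi <- simulate_ppi(truth, within_program_edge_prob = 1, between_prob = 0,
                      seed = 1L)
  expect_equal(nrow(ppi), 20L)
  prog <- truth$program_assignment
  expect_true(all(prog[ppi$gene_a] == prog[ppi$gene_b]))
  expect_true(all(ppi$score > 0 & ppi$score <= 1))

  truth2 <- generate_truth(sim_config(n_genes = 400L, n_targets = 2L,
                                      n_programs = 4L, genes_per_program = 25L,
                                      seed = 4L))
  ppi2 <- simulate_ppi(truth2, within_program_edge_prob = 0.6,
                       between_prob = 0.05, seed = 2L)
  same <- truth2$program_assignment[ppi2$gene_a] ==
    truth2$program_assignment[ppi2$gene_b]
  n_prog_pairs <- 4 * choose(25, 2)
  n_between_pairs <- choose(100, 2) - n_prog_pairs
  expect_gt(sum(same) / n_prog_pairs, sum(!same) / n_between_pairs)

  expect_error(simulate_ppi(truth, within_program_edge_prob = 0.3,
                            between_prob = 0.5), "between_prob")
})

test_that("cohort simulation plants a proportional-hazards signal", {
  truth <- cohort_truth()
  sig <- cohort_signature(truth)

  # censor_rate = 0: every event observed
  coh0 <- simulate_cohort(truth, sig, n_samples = 80L, censor_rate = 0,
                          seed = 41L)
  expect_true(all(coh0$event == 1L))
  expect_true(all(coh0$time > 0))

  # hr_per_unit = 0.5 at n = 500: fitted log-HR within 3 SE of log(0.5)
  coh <- simulate_cohort(truth, sig, n_samples = 500L, hr_per_unit = 0.5,
                         censor_rate = 0.3, seed = 42L)
  scores <- score_bulk(coh$expr, sig)
  fit <- cox_association(scores, coh, adjust = FALSE)
  expect_lt(abs(fit$coef - log(0.5)), 3 * fit$se)

  # null (hr = 1): CI covers 1 in at least 85% of 50 replicates
  covered <- vapply(1:50, function(i) {
    ch <- simulate_cohort(truth, sig, n_samples = 200L, hr_per_unit = 1,
                          censor_rate = 0.2, seed = 100L + i)
    f <- cox_association(score_bulk(ch$expr, sig), ch, adjust = FALSE)
    f$ci95[1] <= 1 && 1 <= f$ci95[2]
  }, NA)
  expect_gte(mean(covered), 0.85)
})

test_that("drug-response simulation hits the target correlation", {
  # planted r = -0.35 at n = 500 recovered within +-0.10
  set.seed(51)
  scores <- rnorm(500)
  auc <- simulate_drug_response(scores, r_target = -0.35, seed = 52L)
  expect_lt(abs(cor(scores, auc[, "DRUG_TARGET"]) - (-0.35)), 0.10)

  # r_target = 0: |sample r| < 0.15 in at least 95% of 100 replicates
  ok <- vapply(1:100, function(i) {
    a <- simulate_drug_response(scores, r_target = 0, n_null_drugs = 0L,
                                seed = i)
    abs(cor(scores, a[, "DRUG_TARGET"])) < 0.15
  }, NA)
  expect_gte(mean(ok), 0.95)

  # near-deterministic limit
  auc99 <- simulate_drug_response(scores, r_target = -0.99, seed = 53L)
  expect_lt(cor(scores, auc99[, "DRUG_TARGET"]), -0.97)
})
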