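as_norm <- function(values) {
  structure(list(values = methods::as(values, "CsparseMatrix"),
                 scale_factor = 1e4, normalization = "log1p_cp_scale"),
            class = "normalized_expression")
}

test_that("log-normalization follows the counts-per-scale formula", {
  counts <- matrix(c(100, 9900,
                     0,   500), nrow = 2, byrow = TRUE,
                   dimnames = list(c("a", "b"), c("G1", "G2")))
  norm <- normalize_counts(perturb_counts(counts), scale_factor = 1e4)
  expect_equal(norm$values["a", "G1"], log(101))   # 100/10000 * 1e4 -> log1p
  expect_equal(norm$values["a", "G2"], log(1 + 9900))
  expect_equal(norm$values["b", "G1"], 0)          # zero count stays zero
  expect_equal(norm$values["b", "G2"], log(1 + 1e4))

  # per-cell operation: other cells' values don't change a cell's result
  counts2 <- rbind(counts, c(7, 13))
  rownames(counts2) <- c("a", "b", "d")
  norm2 <- normalize_counts(perturb_counts(counts2))
  expect_equal(norm2$values["a", ], norm$values["a", ])

  zero <- matrix(c(1, 0, 2, 0), 2,
                 dimnames = list(c("a", "b"), c("G1", "G2")))
  zero["b", ] <- 0
  expect_error(normalize_counts(perturb_counts(zero)), "zero-count")
})

test_that("HVG selection applies mean bounds and binned dispersion", {
  set.seed(81)
  n <- 300L
  vals <- matrix(runif(n * 30, 0.5, 1.5), nrow = n)
  vals <- cbind(vals,
                rep(1.7, n),                   # constant -> dropped
                runif(n, 4.9, 5.1))            # mean log1p > 3 -> dropped
  colnames(vals) <- c(sprintf("G%02d", 1:30), "CONST", "HIGH")
  rownames(vals) <- sprintf("c%03d", 1:n)
  genes <- select_hvgs(as_norm(vals))
  expect_false("CONST" %in% genes)
  expect_false("HIGH" %in% genes)
  st <- attr(genes, "stats")
  expect_gt(st$mean_log1p[st$gene == "HIGH"], 3)

  expect_warning(select_hvgs(as_norm(vals[, 1:10])), "single")
})

test_that("planted program genes are selected as highly variable", {
  # strong within-program dispersion inflation relative to the background
  cfg <- sim_config(n_genes = 1500L, n_targets = 6L, n_programs = 6L,
                    genes_per_program = 30L, cells_per_guide = 60L,
                    n_control_cells = 180L, doublet_rate = 0.05,
                    program_dispersion = c(0.5, 0.9),
                    background_dispersion = c(0.05, 0.15), seed = 82L)
  truth <- generate_truth(cfg)
  sim <- simulate_counts(truth)
  expr <- normalize_counts(filter_cells(compute_qc_metrics(sim$counts)))
  hv <- select_hvgs(expr)
  planted <- names(truth$program_assignment)[!is.na(truth$program_assignment)]
  expect_gte(mean(planted %in% hv), 0.8)
})

test_that("coordinate descent matches the OLS and ridge closed forms", {
  set.seed(83)
  # 50 cells x 3 perturbations, singlet indicator design
  X <- matrix(0, 50, 3, dimnames = list(NULL, c("P1", "P2", "P3")))
  X[cbind(1:36, rep(1:3, each = 12))] <- 1  # 14 control cells left all-zero
  y <- rnorm(50) + X %*% c(0.5, -1, 0)
  fit <- fit_elastic_net(y, X, lambda = 0, alpha = 0.5, tol = 1e-12,
                         max_iter = 1e4)
  ols <- solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y))
  expect_lt(max(abs(c(fit$intercept, fit$beta) - ols)), 1e-6)
  # with an all-zero control block, the OLS intercept is the control mean
  expect_equal(fit$intercept, mean(y[37:50]), tolerance = 1e-8)

  # full-shrinkage limit
  f_inf <- fit_elastic_net(y, X, lambda = 1e6, alpha = 0.5)
  expect_true(all(f_inf$beta == 0))
  expect_equal(f_inf$intercept, mean(y))

  # ridge closed form, single predictor with intercept
  x1 <- rnorm(100); yr <- rnorm(100) + 0.5 * x1
  lam <- 0.7
  fr <- fit_elastic_net(yr, matrix(x1, ncol = 1), lambda = lam, alpha = 0,
                        tol = 1e-14, max_iter = 1e5)
  xc <- x1 - mean(x1); yc <- yr - mean(yr)
  expect_equal(unname(fr$beta), mean(xc * yc) / (mean(xc^2) + lam),
               tolerance = 1e-10)
})

test_that("coordinate descent agrees with an independent elastic-net solver", {
  skip_if_not_installed("glmnet")
  set.seed(84)
  X <- matrix(rbinom(200 * 5, 1, 0.2), 200, 5)
  y <- as.numeric(scale(rnorm(200) + X %*% rnorm(5)))
  for (alpha in c(0, 0.5, 1)) {
    fit <- fit_elastic_net(y, X, lambda = 0.1, alpha = alpha, tol = 1e-12,
                           max_iter = 5e4)
    ref <- glmnet::glmnet(X, y, alpha = alpha, lambda = 0.1,
                          standardize = FALSE, thresh = 1e-14)
    expect_lt(max(abs(fit$beta - as.numeric(ref$beta))), 2e-3)
    expect_lt(abs(fit$intercept - as.numeric(ref$a0)), 2e-3)
  }
})

test_that("the objective is non-increasing across coordinate-descent sweeps", {
  set.seed(85)
  X <- matrix(rbinom(120 * 4, 1, 0.3), 120, 4)
  y <- rnorm(120) + X %*% c(1, -0.5, 0, 0.2)
  objs <- vapply(1:12, function(k) {
    f <- suppressWarnings(
      fit_elastic_net(y, X, lambda = 0.05, alpha = 0.5, max_iter = k,
                      tol = 1e-14))
    elastic_net_objective(y, X, f$beta, f$intercept, 0.05, 0.5)
  }, 0)
  expect_true(all(diff(objs) <= 1e-12))
})

test_that("sparsity is monotone in lambda at fixed alpha", {
  set.seed(86)
  X <- matrix(rbinom(300 * 6, 1, 0.15), 300, 6)
  y <- rnorm(300) + X %*% c(0.8, -0.6, 0.3, 0, 0, 0)
  grid <- exp(seq(log(0.5), log(1e-4), length.out = 15))
  nnz <- vapply(grid, function(l) {
    sum(fit_elastic_net(y, X, lambda = l, alpha = 0.5)$beta != 0)
  }, 0L)
  expect_true(all(diff(nnz) >= 0))  # grid is descending in lambda
})

test_that("regulatory matrix fitting is identifiable, deterministic, and sparse under the null", {
  # noiseless two-perturbation toy: planted signs recovered exactly
  cells <- sprintf("c%03d", 1:60)
  X <- matrix(0, 60, 2, dimnames = list(cells, c("PA", "PB")))
  X[1:20, 1] <- 1; X[21:40, 2] <- 1
  vals <- matrix(1, 60, 4, dimnames = list(cells, c("up_a", "dn_a", "up_b", "flat")))
  vals[1:20, "up_a"] <- 2; vals[1:20, "dn_a"] <- 0.25
  vals[21:40, "up_b"] <- 3
  design <- structure(list(indicator = methods::as(X, "CsparseMatrix"),
                           perturbation_ids = c("PA", "PB"),
                           cell_ids = cells, control_label = "NTC"),
                      class = "perturbation_design")
  R <- fit_regulatory_matrix(as_norm(vals), design, colnames(vals),
                             lambda_grid = c(0.05, 0.01), seed = 1L)
  expect_gt(R$beta["PA", "up_a"], 0)
  expect_lt(R$beta["PA", "dn_a"], 0)
  expect_gt(R$beta["PB", "up_b"], 0)
  expect_equal(R$beta["PA", "flat"], 0)
  expect_equal(R$beta["PB", "flat"], 0)

  # permuting cell order with the same seed gives the identical matrix
  perm <- sample(60)
  design_p <- structure(list(indicator = design$indicator[perm, ],
                             perturbation_ids = c("PA", "PB"),
                             cell_ids = cells[perm], control_label = "NTC"),
                        class = "perturbation_design")
  R_p <- fit_regulatory_matrix(as_norm(vals[perm, ]), design_p,
                               colnames(vals), lambda_grid = c(0.05, 0.01),
                               seed = 1L)
  expect_identical(R$beta, R_p$beta)

  # pure-noise expression: the selected lambda zeroes >= 95% of entries
  set.seed(87)
  vals_null <- matrix(rnorm(60 * 50, mean = 2), 60, 50,
                      dimnames = list(cells, sprintf("G%02d", 1:50)))
  R0 <- fit_regulatory_matrix(as_norm(vals_null), design, colnames(vals_null),
                              seed = 2L)
  expect_gte(mean(R0$beta == 0), 0.95)
})

test_that("perturbation design encodes singlets and rejects empty columns", {
  fx <- small_screen()
  design <- perturbation_design(fx$asg)
  expect_setequal(design$perturbation_ids, fx$truth$targets)
  sing <- fx$asg[fx$asg$status == "singlet", ]
  expect_equal(nrow(design$indicator), nrow(sing))
  # control rows are all zero; each perturbed row has exactly one 1
  rs <- Matrix::rowSums(design$indicator)
  is_ctrl <- sing$perturbation == "NTC"
  expect_true(all(rs[is_ctrl] == 0))
  expect_true(all(rs[!is_ctrl] == 1))
  expect_error(
    fit_regulatory_matrix(fx$expr,
                          perturbation_design(fx$asg,
                                              perturbations = c(fx$truth$targets,
                                                                "ABSENT")),
                          select_hvgs(fx$expr), seed = 1L),
    "ABSENT")
})
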