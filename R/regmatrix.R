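#' Log-normalize a count matrix
#'
#' Per-cell library-size normalization followed by log transform:
#' `value = log(1 + count / total_counts_cell * scale_factor)`. Zeros map to
#' zero exactly, so sparsity is preserved.
#'
#' @param m a [perturb_counts] (QC-filtered; cells with zero totals error).
#' @param scale_factor counts-per-`scale_factor` target library size.
#' @return A list of class `normalized_expression` with `values` (sparse
#'   cells x genes, log scale), `scale_factor`, `normalization`.
#' @export
normalize_counts <- function(m, scale_factor = 1e4) {
  counts <- expression_values(m)
  totals <- Matrix::rowSums(counts)
  assert_that(all(totals > 0), "zero-count cells present; filter cells first")
  v <- Matrix::Diagonal(x = scale_factor / totals) %*% counts
  v <- methods::as(v, "CsparseMatrix")
  v@x <- log1p(v@x)
  dimnames(v) <- dimnames(counts)
  structure(list(values = v, scale_factor = scale_factor,
                 normalization = "log1p_cp_scale"),
            class = "normalized_expression")
}

#' @export
print.normalized_expression <- function(x, ...) {
  cat(sprintf("<normalized_expression> %d cells x %d genes (%s, scale %g)\n",
              nrow(x$values), ncol(x$values), x$normalization, x$scale_factor))
  invisible(x)
}

# column means / variances of expm1(values) for a sparse log-scale matrix
.expm1_moments <- function(v) {
  e <- v
  e@x <- expm1(e@x)
  n <- nrow(v)
  mu <- Matrix::colSums(e) / n
  e@x <- e@x^2
  var <- (Matrix::colSums(e) - n * mu^2) / (n - 1)
  list(mean = as.numeric(mu), var = as.numeric(var))
}

#' Select highly variable genes
#'
#' Mean/dispersion selection on the de-logged scale: per-gene mean and
#' dispersion (variance / mean) are computed on `expm1(values)`, the log
#' dispersion is z-scored within `n_bins` equal-width bins of `log1p(mean)`,
#' and genes are kept when `min_mean <= log1p(mean) <= max_mean` and the
#' normalized dispersion is at least `min_dispersion`. This is the binned
#' mean-variance convention from which the default thresholds
#' (0.0125 / 3 / 0.5) originate.
#'
#' @param expr a `normalized_expression`.
#' @param min_mean,max_mean bounds on `log1p` mean expression (inclusive).
#' @param min_dispersion minimum binned z-score of log dispersion.
#' @param n_bins number of mean bins (falls back to a single bin, with a
#'   warning, when fewer than 20 genes are available).
#' @return Character vector of selected genes; attribute `stats` holds the
#'   per-gene mean, dispersion and normalized dispersion.
#' @export
select_hvgs <- function(expr, min_mean = 0.0125, max_mean = 3,
                        min_dispersion = 0.5, n_bins = 20L) {
  assert_that(inherits(expr, "normalized_expression"),
              "expr must be a normalized_expression")
  mo <- .expm1_moments(expr$values)
  disp <- ifelse(mo$mean > 0, mo$var / mo$mean, NA_real_)
  log_disp <- suppressWarnings(log(disp))
  log_disp[!is.finite(log_disp)] <- NA_real_
  mean_log <- log1p(mo$mean)
  if (length(mean_log) < 20L) {
    warning("fewer than 20 genes; using a single dispersion bin")
    bins <- factor(rep(1L, length(mean_log)))
  } else {
    bins <- cut(mean_log, breaks = n_bins, include.lowest = TRUE)
  }
  bin_mean <- tapply(log_disp, bins, mean, na.rm = TRUE)
  bin_sd <- tapply(log_disp, bins, stats::sd, na.rm = TRUE)
  z <- (log_disp - bin_mean[bins]) / bin_sd[bins]
  z[is.na(z) & !is.na(log_disp)] <- 0  # singleton or zero-spread bins
  keep <- !is.na(log_disp) & !is.na(z) &
    mean_log >= min_mean & mean_log <= max_mean & z >= min_dispersion
  genes <- colnames(expr$values)[keep]
  attr(genes, "stats") <- data.frame(
    gene = colnames(expr$values), mean = mo$mean, mean_log1p = mean_log,
    dispersion = disp, dispersion_norm = as.numeric(z),
    selected = keep, stringsAsFactors = FALSE)
  genes
}

#' Build a cell-by-perturbation indicator design
#'
#' Binary design matrix with one column per (non-control) perturbation and
#' one row per singlet cell; entry 1 marks the cell's assigned perturbation.
#' Control singlets keep all-zero rows and thereby define the baseline that
#' the per-gene intercept estimates.
#'
#' @param assignment a [assign_guides()] result.
#' @param control_label the control perturbation label.
#' @param perturbations optional explicit column order.
#' @return A list of class `perturbation_design` with `indicator` (sparse
#'   cells x perturbations), `perturbation_ids`, `cell_ids`, `control_label`.
#' @export
perturbation_design <- function(assignment, control_label = "NTC",
                                perturbations = NULL) {
  sing <- assignment[assignment$status == "singlet", ]
  assert_that(nrow(sing) > 0, "no singlet cells")
  if (is.null(perturbations)) {
    perturbations <- sort(setdiff(unique(sing$perturbation), control_label))
  }
  j <- match(sing$perturbation, perturbations)
  nz <- !is.na(j)
  ind <- Matrix::sparseMatrix(
    i = which(nz), j = j[nz], x = 1,
    dims = c(nrow(sing), length(perturbations)),
    dimnames = list(sing$cell_id, perturbations))
  structure(list(indicator = ind, perturbation_ids = perturbations,
                 cell_ids = sing$cell_id, control_label = control_label),
            class = "perturbation_design")
}

#' Elastic-net objective value
#'
#' `1/(2n) * ||y - b0 - X beta||^2 + lambda * (alpha * ||beta||_1 +
#' (1 - alpha)/2 * ||beta||_2^2)` — the penalized least-squares objective
#' minimized by [fit_elastic_net()], with an unpenalized intercept and the
#' conventional `1/(2n)` loss scaling that makes `lambda` comparable across
#' sample sizes.
#'
#' @param y response vector.
#' @param X design matrix.
#' @param beta,b0 coefficients and intercept.
#' @param lambda,alpha penalty weight and L1/L2 mix.
#' @return Scalar objective value.
#' @export
elastic_net_objective <- function(y, X, beta, b0, lambda, alpha) {
  r <- y - b0 - as.numeric(X %*% beta)
  sum(r^2) / (2 * length(y)) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

# Cyclic coordinate descent with soft thresholding on precomputed
# cross-products, vectorized across response columns (genes).
# XtX: p x p, Xty: p x G, sx: column sums of X (length p), sum_y: length G.
.en_cd <- function(XtX, Xty, sx, sum_y, n, lambda, alpha,
                   beta = NULL, max_iter = 1000L, tol = 1e-8) {
  p <- nrow(XtX); G <- ncol(Xty)
  if (is.null(beta)) beta <- matrix(0, p, G)
  nj <- diag(XtX)
  thr <- lambda * alpha
  denom <- nj / n + lambda * (1 - alpha)
  b0 <- (sum_y - colSums(beta * sx)) / n
  iter <- 0L
  repeat {
    iter <- iter + 1L
    delta <- 0
    b0_new <- (sum_y - colSums(beta * sx)) / n
    delta <- max(delta, max(abs(b0_new - b0)))
    b0 <- b0_new
    for (j in seq_len(p)) {
      cross <- XtX[j, , drop = FALSE] %*% beta - nj[j] * beta[j, ]
      rho <- (Xty[j, ] - sx[j] * b0 - cross) / n
      bj <- sign(rho) * pmax(abs(rho) - thr, 0) / denom[j]
      delta <- max(delta, max(abs(bj - beta[j, ])))
      beta[j, ] <- bj
    }
    if (delta < tol || iter >= max_iter) break
  }
  list(beta = beta, intercept = as.numeric(b0),
       converged = delta < tol, n_iter = iter)
}

#' Fit one elastic-net regression by coordinate descent
#'
#' Minimizes [elastic_net_objective()] by cyclic coordinate descent with
#' soft thresholding; the intercept is unpenalized and re-estimated every
#' sweep. At `lambda = 0` the solution coincides with ordinary least
#' squares; at large `lambda` all coefficients are exactly zero and the
#' intercept equals `mean(y)`.
#'
#' @param y response vector (one gene's expression across cells).
#' @param design a [perturbation_design] or numeric design matrix.
#' @param lambda,alpha penalty weight (>= 0) and L1/L2 mix in \[0, 1\].
#' @param max_iter,tol sweep budget and convergence threshold on the largest
#'   coefficient change.
#' @return List with `beta` (named), `intercept`, `converged`, `n_iter`.
#'   Non-convergence is flagged (with a warning), not an error.
#' @export
fit_elastic_net <- function(y, design, lambda, alpha = 0.5,
                            max_iter = 1000L, tol = 1e-8) {
  X <- if (inherits(design, "perturbation_design")) design$indicator else design
  assert_that(length(y) == nrow(X), "length(y) must equal nrow(design)")
  assert_that(lambda >= 0 && is_fraction(alpha),
              "need lambda >= 0 and alpha in [0, 1]")
  XtX <- as.matrix(Matrix::crossprod(X))
  Xty <- as.matrix(Matrix::crossprod(X, y))
  fit <- .en_cd(XtX, Xty, as.numeric(Matrix::colSums(X)), sum(y), length(y),
                lambda, alpha, max_iter = max_iter, tol = tol)
  if (!fit$converged) {
    warning(sprintf("coordinate descent did not converge in %d sweeps", max_iter))
  }
  list(beta = stats::setNames(as.numeric(fit$beta), colnames(X)),
       intercept = fit$intercept[1], converged = fit$converged,
       n_iter = fit$n_iter)
}

# deterministic stratified train/validation/test split over cells
.split_cells <- function(strata, split, seed) {
  assert_that(abs(sum(split) - 1) < 1e-8 && length(split) == 3,
              "split must be three fractions summing to 1")
  part <- rep("train", length(strata))
  with_seed(seed, {
    for (s in unique(strata)) {
      ix <- which(strata == s)
      ix <- ix[sample.int(length(ix))]
      n <- length(ix)
      n_val <- floor(split[2] * n)
      n_test <- floor(split[3] * n)
      if (n - n_val - n_test < 1L) { n_val <- 0L; n_test <- max(0L, n - 1L) }
      part[ix[seq_len(n_val)]] <- "validation"
      if (n_test > 0) part[ix[n_val + seq_len(n_test)]] <- "test"
    }
  })
  part
}

# per-(group, gene) sufficient statistics for fast MSE over a split:
# groups = perturbation index + 1 (control = 1)
.group_stats <- function(Y, group, n_groups) {
  G <- factor(group, levels = seq_len(n_groups))
  ind <- Matrix::sparseMatrix(i = seq_along(group), j = as.integer(G), x = 1,
                              dims = c(length(group), n_groups))
  Sy <- as.matrix(Matrix::crossprod(ind, Y))
  Y2 <- Y
  if (methods::is(Y2, "CsparseMatrix")) Y2@x <- Y2@x^2 else Y2 <- Y2^2
  Syy <- as.matrix(Matrix::crossprod(ind, Y2))
  list(Sy = Sy, Syy = Syy, n = as.numeric(table(G)))
}

.split_mse <- function(beta, b0, gs) {
  # prediction for group j (row 1 = control) is b0 (+ beta[j-1, ])
  pred <- rbind(b0, sweep(beta, 2, b0, `+`))
  total <- sum(gs$Syy - 2 * pred * gs$Sy + gs$n * pred^2)
  total / (sum(gs$n) * ncol(beta))
}

#' Infer the perturbation-by-gene regulatory matrix
#'
#' Regresses each highly variable gene's log-normalized expression on the
#' binary perturbation indicators with an elastic-net penalty. Cells are
#' split (stratified by perturbation, seeded) into training, validation and
#' test sets; one global `lambda` shared by all genes is selected on the
#' descending `lambda` path by minimum pooled validation MSE, and test MSE
#' is reported but never used for selection. Cells are canonically sorted by
#' barcode first, so the result is invariant to input cell order.
#'
#' @param expr a `normalized_expression`.
#' @param design a [perturbation_design].
#' @param hvgs genes to model (e.g. from [select_hvgs()]).
#' @param lambda_grid optional descending penalty grid; by default 30
#'   log-spaced values from the smallest `lambda` that zeroes every
#'   coefficient down to 1e-4 of it.
#' @param n_lambda grid size when `lambda_grid` is `NULL`.
#' @param lambda_rule `"1se"` (default) selects the largest `lambda` whose
#'   pooled validation MSE is within one standard error of the minimum —
#'   the sparsest model statistically indistinguishable from the best —
#'   while `"min"` takes the minimum itself. The validation-MSE curve of
#'   indicator designs is nearly flat around its minimum, so the plain
#'   minimum retains many coefficients that are pure noise.
#' @param alpha L1/L2 mix (0.5 balances sparsity against shrinkage).
#' @param split train/validation/test fractions.
#' @param seed seed for the stratified split.
#' @param max_iter,tol coordinate-descent controls.
#' @return A list of class `regulatory_matrix`: `beta` (perturbations x
#'   genes), `intercepts`, `lambda`, `alpha`, `lambda_grid`,
#'   `validation_mse`, `test_mse`, `split` (per-cell partition), `seed`,
#'   `converged`.
#' @export
fit_regulatory_matrix <- function(expr, design, hvgs,
                                  lambda_grid = NULL, n_lambda = 30L,
                                  alpha = 0.5, split = c(0.8, 0.1, 0.1),
                                  seed = 1L, max_iter = 1000L, tol = 1e-8,
                                  lambda_rule = c("1se", "min")) {
  lambda_rule <- match.arg(lambda_rule)
  assert_that(inherits(design, "perturbation_design"),
              "design must be a perturbation_design")
  assert_that(length(hvgs) > 0, "hvgs must be non-empty")
  cells <- sort(intersect(design$cell_ids, rownames(expr$values)))
  assert_that(length(cells) > 0, "no shared cells between expr and design")
  X <- design$indicator[cells, , drop = FALSE]
  col_n <- Matrix::colSums(X)
  assert_that(all(col_n > 0),
              "perturbations with no cells: %s",
              paste(design$perturbation_ids[col_n == 0], collapse = ", "))
  Y <- expr$values[cells, hvgs, drop = FALSE]
  p <- ncol(X); Gn <- ncol(Y); n_all <- length(cells)

  # group index (1 = control / all-zero row, 1 + j = perturbation j)
  grp <- as.integer(1 + X %*% seq_len(p))
  strata <- c(design$control_label, design$perturbation_ids)[grp]
  part <- .split_cells(strata, split, seed)

  tr <- part == "train"; va <- part == "validation"; te <- part == "test"
  Xtr <- X[tr, , drop = FALSE]; Ytr <- Y[tr, , drop = FALSE]
  XtX <- as.matrix(Matrix::crossprod(Xtr))
  Xty <- as.matrix(Matrix::crossprod(Xtr, Ytr))
  col_n_train <- Matrix::colSums(Xtr)
  sum_y <- Matrix::colSums(Ytr)
  n <- sum(tr)
  nj <- diag(XtX)
  ybar <- sum_y / n

  if (is.null(lambda_grid)) {
    lambda_max <- max(abs(Xty - outer(nj, ybar))) / (n * max(alpha, 1e-3))
    lambda_grid <- exp(seq(log(lambda_max), log(lambda_max * 1e-4),
                           length.out = n_lambda))
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)

  gs_val <- if (any(va)) .group_stats(Y[va, , drop = FALSE], grp[va], p + 1L)
  gs_test <- if (any(te)) .group_stats(Y[te, , drop = FALSE], grp[te], p + 1L)

  beta <- NULL
  fits <- vector("list", length(lambda_grid))
  val_mse <- rep(NA_real_, length(lambda_grid))
  for (k in seq_along(lambda_grid)) {
    fit <- .en_cd(XtX, Xty, as.numeric(col_n_train), sum_y, n, lambda_grid[k],
                  alpha, beta = beta, max_iter = max_iter, tol = tol)
    beta <- fit$beta  # warm start down the path
    fits[[k]] <- fit
    if (!is.null(gs_val)) val_mse[k] <- .split_mse(fit$beta, fit$intercept, gs_val)
  }
  if (all(is.na(val_mse))) {
    best <- length(lambda_grid)
    mse_se <- NA_real_
  } else {
    # SE of the pooled validation MSE estimate at the minimizing lambda,
    # from the spread of the individual squared residuals; the 1-SE rule
    # then takes the sparsest model within that uncertainty
    Yva <- as.matrix(Y[va, , drop = FALSE])
    gva <- grp[va]
    best_min <- which.min(val_mse)
    fit <- fits[[best_min]]
    pred <- rbind(fit$intercept, sweep(fit$beta, 2, fit$intercept, `+`))
    sq <- (Yva - pred[gva, , drop = FALSE])^2
    mse_se <- stats::sd(sq) / sqrt(length(sq))
    best <- if (lambda_rule == "1se") {
      which(val_mse <= val_mse[best_min] + mse_se)[1L]
    } else {
      best_min
    }
  }
  chosen <- fits[[best]]
  test_mse <- if (!is.null(gs_test)) {
    .split_mse(chosen$beta, chosen$intercept, gs_test)
  } else NA_real_

  dimnames(chosen$beta) <- list(design$perturbation_ids, hvgs)
  structure(list(
    beta = chosen$beta,
    intercepts = stats::setNames(chosen$intercept, hvgs),
    lambda = lambda_grid[best], alpha = alpha,
    lambda_grid = lambda_grid, validation_mse = val_mse,
    validation_mse_se = mse_se, lambda_rule = lambda_rule,
    test_mse = test_mse,
    split = stats::setNames(part, cells), split_fractions = split,
    seed = as.integer(seed), converged = chosen$converged
  ), class = "regulatory_matrix")
}

#' @export
print.regulatory_matrix <- function(x, ...) {
  cat(sprintf(paste0("<regulatory_matrix> %d perturbations x %d genes ",
                     "(lambda = %.4g, alpha = %.2f, %.1f%% nonzero)\n"),
              nrow(x$beta), ncol(x$beta), x$lambda, x$alpha,
              100 * mean(x$beta != 0)))
  invisible(x)
}
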