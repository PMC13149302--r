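#' Genes expressed in more than half of control cells
#'
#' The differential-expression stage only tests genes detected (count > 0)
#' in strictly more than `min_frac` of control cells; this mirrors the
#' control-expression filter applied before per-perturbation testing.
#'
#' @param m a [perturb_counts], `normalized_expression`, or cells x genes
#'   matrix.
#' @param control_cells character vector of control cell barcodes (>= 2).
#' @param min_frac detection fraction that must be strictly exceeded.
#' @return Character vector of retained genes; attribute `frac` carries the
#'   per-gene detection fraction in control cells.
#' @export
control_expressed_genes <- function(m, control_cells, min_frac = 0.5) {
  x <- expression_values(m)
  assert_that(length(control_cells) >= 2, "need at least 2 control cells")
  assert_that(all(control_cells %in% rownames(x)),
              "control cells missing from the matrix")
  frac <- Matrix::colSums(x[control_cells, , drop = FALSE] > 0) /
    length(control_cells)
  genes <- colnames(x)[frac > min_frac]
  attr(genes, "frac") <- stats::setNames(as.numeric(frac), colnames(x))
  genes
}

# extract a cells/samples x genes numeric matrix from any container
expression_values <- function(m) {
  if (inherits(m, "perturb_counts")) return(m$counts)
  if (inherits(m, "normalized_expression")) return(m$values)
  assert_that(is.matrix(m) || methods::is(m, "Matrix"),
              "expected a matrix-like object")
  m
}

# Two-sided Mann-Whitney/Wilcoxon rank-sum p-value for one gene.
# Exact distribution when both groups have <= `exact_max` observations and
# there are no ties; tie-corrected normal approximation with continuity
# correction otherwise.
rank_sum_p <- function(x, y, exact_max = 8L) {
  n1 <- length(x); n2 <- length(y)
  v <- c(x, y)
  r <- rank(v)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(v)
  has_ties <- any(ties > 1)
  if (!has_ties && n1 <= exact_max && n2 <= exact_max) {
    p <- if (u > n1 * n2 / 2) {
      stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    } else {
      stats::pwilcox(u, n1, n2)
    }
    return(min(2 * p, 1))
  }
  sigma2 <- (n1 * n2 / 12) *
    ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  if (sigma2 <= 0) return(1)  # fully tied gene
  z <- u - n1 * n2 / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Wilcoxon rank-sum differential expression for one perturbation
#'
#' Two-sided rank-sum test of each gene between perturbed and control cells
#' on log-normalized expression, with the log2 fold change computed on the
#' de-logged scale: `log2((mean(expm1(x_pert)) + pc) / (mean(expm1(x_ctrl)) + pc))`.
#'
#' @param expr `normalized_expression` (or cells x genes log-scale matrix).
#' @param perturbation_cells,control_cells barcode vectors (>= 3 cells each).
#' @param genes genes to test (default: all columns).
#' @param pseudocount pseudocount `pc` on the natural scale.
#' @param perturbation optional label recorded in the output.
#' @return Data frame with columns `perturbation`, `gene`,
#'   `log2_fold_change`, `p_value`.
#' @export
wilcoxon_de <- function(expr, perturbation_cells, control_cells,
                        genes = NULL, pseudocount = 1e-9,
                        perturbation = NA_character_) {
  x <- expression_values(expr)
  assert_that(length(perturbation_cells) >= 3 && length(control_cells) >= 3,
              "need at least 3 cells per group")
  if (is.null(genes)) genes <- colnames(x)
  xp <- as.matrix(x[perturbation_cells, genes, drop = FALSE])
  xc <- as.matrix(x[control_cells, genes, drop = FALSE])
  mp <- colMeans(expm1(xp))
  mc <- colMeans(expm1(xc))
  lfc <- log2((mp + pseudocount) / (mc + pseudocount))
  p <- vapply(seq_along(genes), function(j) {
    xj <- xp[, j]; yj <- xc[, j]
    if (all(xj == xj[1]) && all(yj == xj[1])) return(1)  # degenerate gene
    rank_sum_p(xj, yj)
  }, 0)
  lfc[p == 1 & mp == mc] <- 0
  data.frame(perturbation = perturbation, gene = genes,
             log2_fold_change = as.numeric(lfc), p_value = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR control (delegates to [stats::p.adjust()]); rejects
#' missing or out-of-range p-values instead of propagating them.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return FDR-adjusted values, capped at 1.
#' @export
bh_adjust <- function(p) {
  assert_that(is.numeric(p) && !anyNA(p), "p-values must be numeric and non-missing")
  assert_that(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential expression for every perturbation against control
#'
#' Applies the control-expression filter, runs [wilcoxon_de()] per
#' perturbation, and BH-adjusts p-values (by default within each
#' perturbation's family of tested genes).
#'
#' @param expr `normalized_expression` for the singlet cells.
#' @param assignment a [assign_guides()] result (singlets are used).
#' @param control_label perturbation label of control cells.
#' @param perturbations which perturbations to test (default: all non-control
#'   singlet labels).
#' @param min_frac control detection fraction genes must strictly exceed.
#' @param fdr_family `"per_perturbation"` (default) or `"global"`.
#' @return Data frame of class `de_table`: `perturbation`, `gene`,
#'   `log2_fold_change`, `p_value`, `fdr`, `frac_control_expressed`.
#' @export
de_analysis <- function(expr, assignment, control_label = "NTC",
                        perturbations = NULL, min_frac = 0.5,
                        fdr_family = c("per_perturbation", "global")) {
  fdr_family <- match.arg(fdr_family)
  x <- expression_values(expr)
  sing <- assignment[assignment$status == "singlet", ]
  sing <- sing[sing$cell_id %in% rownames(x), ]
  ctrl <- sing$cell_id[sing$perturbation == control_label]
  assert_that(length(ctrl) >= 3, "need at least 3 control singlet cells")
  genes <- control_expressed_genes(x, ctrl, min_frac = min_frac)
  frac <- attr(genes, "frac")
  if (is.null(perturbations)) {
    perturbations <- sort(setdiff(unique(sing$perturbation), control_label))
  }
  rows <- lapply(perturbations, function(p) {
    cells <- sing$cell_id[sing$perturbation == p]
    de <- wilcoxon_de(x, cells, ctrl, genes = genes, perturbation = p)
    if (fdr_family == "per_perturbation") de$fdr <- bh_adjust(de$p_value)
    de
  })
  out <- do.call(rbind, rows)
  if (fdr_family == "global") out$fdr <- bh_adjust(out$p_value)
  out$frac_control_expressed <- as.numeric(frac[out$gene])
  class(out) <- c("de_table", "data.frame")
  out
}
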