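#' Perturbation count matrix container
#'
#' Thin wrapper around a sparse cells x genes UMI count matrix with an
#' optional per-cell QC table (`n_genes_detected`, `total_counts`,
#' `pct_mito`).
#'
#' @param counts cells x genes matrix of non-negative integers (coerced to
#'   sparse `dgCMatrix`); rownames are cell barcodes, colnames gene symbols.
#' @param per_cell optional per-cell QC data frame as produced by
#'   [compute_qc_metrics()].
#' @return An object of class `perturb_counts`.
#' @export
perturb_counts <- function(counts, per_cell = NULL) {
  counts <- as_cell_gene_matrix(counts)
  assert_that((nrow(counts) == 0 || !is.null(rownames(counts))) &&
                (ncol(counts) == 0 || !is.null(colnames(counts))),
              "counts must carry cell and gene identifiers as dimnames")
  structure(list(counts = counts, per_cell = per_cell),
            class = "perturb_counts")
}

#' @export
dim.perturb_counts <- function(x) dim(x$counts)

#' @export
print.perturb_counts <- function(x, ...) {
  cat(sprintf("<perturb_counts> %d cells x %d genes (%s QC metrics)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$per_cell)) "no" else "with"))
  invisible(x)
}

#' Compute per-cell QC metrics
#'
#' Populates the number of detected genes, the total UMI count, and the
#' mitochondrial fraction (over genes whose symbol starts with
#' `mito_prefix`) for every cell. Idempotent.
#'
#' @param m a [perturb_counts] object or a cells x genes count matrix.
#' @param mito_prefix gene-symbol prefix identifying mitochondrial genes.
#' @return The [perturb_counts] object with `per_cell` filled in.
#' @export
compute_qc_metrics <- function(m, mito_prefix = "MT-") {
  if (!inherits(m, "perturb_counts")) m <- perturb_counts(m)
  counts <- m$counts
  assert_that(nrow(counts) > 0 && ncol(counts) > 0, "empty count matrix")
  total <- Matrix::rowSums(counts)
  detected <- Matrix::rowSums(counts > 0)
  mito <- startsWith(colnames(counts), mito_prefix)
  mito_counts <- if (any(mito)) Matrix::rowSums(counts[, mito, drop = FALSE]) else 0
  pct_mito <- ifelse(total > 0, mito_counts / total, 0)
  m$per_cell <- data.frame(
    n_genes_detected = as.integer(detected),
    total_counts = as.numeric(total),
    pct_mito = as.numeric(pct_mito),
    row.names = rownames(counts)
  )
  m
}

#' Filter cells on QC thresholds
#'
#' Retains cells with at least `min_genes` detected genes, at least
#' `min_counts` total UMIs, and at most `max_mito` mitochondrial fraction.
#' All three boundaries are inclusive for retention: the screen's filters
#' exclude cells with *fewer than* 200 genes, totals *below* 1000, or *more
#' than* 20% mitochondrial reads.
#'
#' @param m a [perturb_counts] with QC metrics computed.
#' @param min_genes,min_counts,max_mito retention thresholds.
#' @return The filtered [perturb_counts]; attribute `removed` holds the
#'   number of cells failing each criterion (non-exclusively) and in total.
#' @export
filter_cells <- function(m, min_genes = 200L, min_counts = 1000L,
                         max_mito = 0.20) {
  assert_that(inherits(m, "perturb_counts"), "m must be a perturb_counts")
  assert_that(!is.null(m$per_cell), "run compute_qc_metrics() first")
  qc <- m$per_cell
  fail_genes <- qc$n_genes_detected < min_genes
  fail_counts <- qc$total_counts < min_counts
  fail_mito <- qc$pct_mito > max_mito
  keep <- !(fail_genes | fail_counts | fail_mito)
  if (!any(keep)) warning("all cells removed by QC filters")
  out <- perturb_counts(m$counts[keep, , drop = FALSE],
                        per_cell = qc[keep, , drop = FALSE])
  attr(out, "removed") <- c(n_genes = sum(fail_genes),
                            total_counts = sum(fail_counts),
                            pct_mito = sum(fail_mito),
                            total = sum(!keep))
  out
}

#' Assign cells to perturbations from captured guides
#'
#' A guide is a calling candidate when its UMI count is at least `min_umi`.
#' A cell whose best candidate dominates the runner-up by at least
#' `dominance_ratio` (or that has a single candidate) is a singlet and is
#' assigned that guide's target; a cell with two or more candidates and no
#' dominant one is a doublet; a cell with no candidate (or absent from the
#' guide table) is unassigned. Doublets and unassigned cells are excluded
#' from downstream analyses.
#'
#' @param guide_table data frame with columns `cell_id`, `sgrna_id`,
#'   `target_gene`, `umi_count` (one row per captured guide per cell).
#' @param min_umi minimum UMI count for a guide to be considered.
#' @param dominance_ratio fold-dominance of the top guide required to call a
#'   singlet in the presence of other candidates.
#' @param cell_ids optional vector of all cell barcodes; cells missing from
#'   `guide_table` are reported as unassigned.
#' @return A data frame of class `guide_assignment` with one row per cell:
#'   `cell_id`, `status` (singlet/doublet/unassigned), `sgrna_id`,
#'   `perturbation` (target gene or control label; `NA` unless singlet),
#'   `umi_count`, `n_candidates`.
#' @export
assign_guides <- function(guide_table, min_umi = 3L, dominance_ratio = 2,
                          cell_ids = NULL) {
  need <- c("cell_id", "sgrna_id", "target_gene", "umi_count")
  assert_that(all(need %in% names(guide_table)),
              "guide_table must have columns %s", paste(need, collapse = ", "))
  assert_that(all(guide_table$umi_count >= 0), "guide UMI counts must be >= 0")

  gt <- guide_table[order(guide_table$cell_id, -guide_table$umi_count,
                          guide_table$sgrna_id), ]
  by_cell <- split(seq_len(nrow(gt)), gt$cell_id)
  res <- lapply(by_cell, function(ix) {
    umi <- gt$umi_count[ix]
    cand <- which(umi >= min_umi)
    if (length(cand) == 0L) {
      return(list(status = "unassigned", sgrna_id = NA_character_,
                  perturbation = NA_character_, umi_count = NA_real_,
                  n_candidates = 0L))
    }
    top <- cand[1L]
    second <- if (length(cand) >= 2L) umi[cand[2L]] else 0
    if (length(cand) == 1L || umi[top] >= dominance_ratio * second) {
      list(status = "singlet", sgrna_id = gt$sgrna_id[ix[top]],
           perturbation = gt$target_gene[ix[top]],
           umi_count = umi[top], n_candidates = length(cand))
    } else {
      list(status = "doublet", sgrna_id = NA_character_,
           perturbation = NA_character_, umi_count = umi[top],
           n_candidates = length(cand))
    }
  })
  out <- data.frame(
    cell_id = names(by_cell),
    status = vapply(res, `[[`, "", "status"),
    sgrna_id = vapply(res, `[[`, "", "sgrna_id"),
    perturbation = vapply(res, `[[`, "", "perturbation"),
    umi_count = vapply(res, `[[`, 0, "umi_count"),
    n_candidates = vapply(res, `[[`, 0L, "n_candidates"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(cell_ids)) {
    missing <- setdiff(cell_ids, out$cell_id)
    if (length(missing)) {
      out <- rbind(out, data.frame(
        cell_id = missing, status = "unassigned", sgrna_id = NA_character_,
        perturbation = NA_character_, umi_count = NA_real_, n_candidates = 0L,
        stringsAsFactors = FALSE))
    }
    out <- out[match(cell_ids, out$cell_id), ]
    rownames(out) <- NULL
  }
  class(out) <- c("guide_assignment", "data.frame")
  out
}

#' Summarize cells per target and per guide
#'
#' @param assignment a [assign_guides()] result.
#' @param targets optional vector of all targets; targets without singlet
#'   cells are reported with zero counts rather than dropped.
#' @return A list with `per_target` and `per_guide` count tables and
#'   `summary` (median/min/max cells per target and per guide).
#' @export
coverage_summary <- function(assignment, targets = NULL) {
  assert_that(inherits(assignment, "guide_assignment"),
              "assignment must come from assign_guides()")
  sing <- assignment[assignment$status == "singlet", ]
  tab_t <- table(factor(sing$perturbation,
                        levels = union(targets, unique(sing$perturbation))))
  tab_g <- table(sing$sgrna_id)
  per_target <- data.frame(target = names(tab_t), n_cells = as.integer(tab_t),
                           stringsAsFactors = FALSE, row.names = NULL)
  per_guide <- data.frame(sgrna_id = names(tab_g), n_cells = as.integer(tab_g),
                          stringsAsFactors = FALSE, row.names = NULL)
  list(
    per_target = per_target,
    per_guide = per_guide,
    summary = c(
      median_per_target = stats::median(per_target$n_cells),
      min_per_target = min(per_target$n_cells),
      max_per_target = max(per_target$n_cells),
      median_per_guide = stats::median(per_guide$n_cells),
      min_per_guide = min(per_guide$n_cells),
      max_per_guide = max(per_guide$n_cells)
    )
  )
}
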