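#' Build a k-nearest-neighbour graph over genes
#'
#' Genes are points in perturbation-effect space (the columns of the
#' regulatory matrix); each gene is connected to its `k` nearest neighbours
#' and the directed neighbour lists are mutualized by union into an
#' undirected, unit-weight graph. Distance ties are broken by gene-id
#' lexicographic order so the graph is deterministic.
#'
#' Cosine distance is the default: genes of one program share the
#' *direction* of their perturbation response while their magnitudes spread
#' over a continuum, and Euclidean distance turns such a continuum into a
#' nearest-neighbour chain that community detection then fragments.
#'
#' @param R a `regulatory_matrix` (or a perturbations x genes matrix).
#' @param k neighbours per gene (needs at least `k + 1` genes).
#' @param method `"cosine"` (default) or `"euclidean"` distance between
#'   effect profiles.
#' @return An [igraph::graph] with one vertex per gene.
#' @export
build_gene_knn <- function(R, k = 5L, method = c("cosine", "euclidean")) {
  method <- match.arg(method)
  beta <- if (inherits(R, "regulatory_matrix")) R$beta else R
  genes <- colnames(beta)
  assert_that(!is.null(genes), "beta must have gene column names")
  assert_that(ncol(beta) >= k + 1, "need at least k + 1 genes")
  d <- if (method == "euclidean") {
    as.matrix(stats::dist(t(beta)))
  } else {
    nrm <- sqrt(colSums(beta^2))
    nrm[nrm == 0] <- 1
    1 - crossprod(beta) / outer(nrm, nrm)
  }
  ord_genes <- order(genes)  # lexicographic tie-break
  edges <- lapply(seq_along(genes), function(i) {
    o <- ord_genes[order(d[i, ord_genes])]
    nb <- setdiff(o, i)[seq_len(k)]
    cbind(i, nb)
  })
  em <- do.call(rbind, edges)
  em <- t(apply(em, 1L, sort))
  em <- unique(em)  # union of directed neighbour lists
  g <- igraph::graph_from_edgelist(
    cbind(genes[em[, 1]], genes[em[, 2]]), directed = FALSE)
  g <- g + igraph::vertices(setdiff(genes, igraph::V(g)$name))
  igraph::E(g)$weight <- 1
  g
}

#' Cluster genes into transcriptional programs
#'
#' Louvain community detection on the gene kNN graph. Clusters smaller than
#' `min_program_size` are merged into the cluster whose mean
#' perturbation-effect profile is most correlated with theirs. Programs are
#' labelled `P-0`, `P-1`, ... in decreasing size; per-gene weights are the
#' mean absolute regulatory coefficient over the program's top-loading
#' perturbations (the `n_top` perturbations with the largest mean |beta|
#' across member genes).
#'
#' @param graph gene graph from [build_gene_knn()].
#' @param R the `regulatory_matrix` (or beta matrix) used to build the
#'   graph; needed for small-cluster merging and gene weights.
#' @param resolution Louvain resolution parameter.
#' @param seed seed for the (stochastic) Louvain phases.
#' @param min_program_size smallest admissible program.
#' @param n_top perturbations used for the weight of each program.
#' @return A list of class `gene_programs`: `programs` (named list with
#'   `program_id`, `members`, `weights`, `top_perturbations`, `size`) and
#'   `membership` (named program label per gene).
#' @export
louvain_programs <- function(graph, R, resolution = 1.0, seed = 1L,
                             min_program_size = 10L, n_top = 3L) {
  assert_that(igraph::vcount(graph) > 0, "empty graph")
  beta <- if (inherits(R, "regulatory_matrix")) R$beta else R
  genes <- igraph::V(graph)$name
  assert_that(all(genes %in% colnames(beta)),
              "graph vertices missing from the regulatory matrix")
  comm <- with_seed(seed, igraph::cluster_louvain(graph, resolution = resolution))
  memb <- stats::setNames(igraph::membership(comm), genes)

  # merge undersized clusters into the most correlated larger cluster
  repeat {
    sizes <- table(memb)
    small <- names(sizes)[sizes < min_program_size]
    if (length(small) == 0 || length(sizes) == 1) break
    small <- small[order(sizes[small])][1]
    centroids <- vapply(names(sizes),
                        function(cl) rowMeans(beta[, names(memb)[memb == cl],
                                                   drop = FALSE]),
                        numeric(nrow(beta)))
    others <- setdiff(names(sizes), small)
    cors <- vapply(others, function(cl) {
      suppressWarnings(stats::cor(centroids[, small], centroids[, cl]))
    }, 0)
    cors[is.na(cors)] <- -Inf
    target <- others[which.max(cors)]
    memb[memb == small] <- target
  }

  sizes <- sort(table(memb), decreasing = TRUE)
  labels <- stats::setNames(sprintf("P-%d", seq_along(sizes) - 1L), names(sizes))
  memb_lab <- stats::setNames(labels[as.character(memb)], names(memb))

  programs <- lapply(seq_along(sizes), function(i) {
    members <- sort(names(memb_lab)[memb_lab == labels[i]])
    loading <- rowMeans(abs(beta[, members, drop = FALSE]))
    top <- names(sort(loading, decreasing = TRUE))[seq_len(min(n_top, length(loading)))]
    weights <- colMeans(abs(beta[top, members, drop = FALSE]))
    list(program_id = unname(labels[i]), members = members,
         weights = weights, top_perturbations = top,
         size = length(members))
  })
  names(programs) <- unname(labels)
  structure(list(programs = programs, membership = memb_lab),
            class = "gene_programs")
}

#' @export
print.gene_programs <- function(x, ...) {
  sz <- vapply(x$programs, `[[`, 0L, "size")
  cat(sprintf("<gene_programs> %d programs over %d genes (sizes %s)\n",
              length(sz), length(x$membership),
              paste(sz, collapse = ", ")))
  invisible(x)
}

#' Extract a program signature
#'
#' The signature is the top `fraction` of a program's member genes ranked by
#' regulatory weight (`ceiling(fraction * size)` genes); weight ties are
#' broken by gene-id lexicographic order, so the selection is deterministic.
#'
#' @param program one element of `gene_programs$programs`.
#' @param fraction fraction of member genes to keep, in (0, 1].
#' @return A list of class `program_signature` with `program_id`, `genes`
#'   (ordered by decreasing weight), `fraction`.
#' @export
program_signature <- function(program, fraction = 0.25) {
  assert_that(is.numeric(fraction) && fraction > 0 && fraction <= 1,
              "fraction must lie in (0, 1]")
  w <- program$weights
  assert_that(all(is.finite(w)), "program weights must be finite")
  n <- ceiling(fraction * length(w))
  ord <- order(-w, names(w))
  structure(list(program_id = program$program_id,
                 genes = names(w)[ord][seq_len(n)],
                 fraction = fraction),
            class = "program_signature")
}

#' Score program activity per cell or sample
#'
#' Expression-bin-matched control scoring: the score of a unit is the mean
#' expression of the signature genes minus the mean of a control gene set
#' drawn, per signature gene, from the same average-expression bin
#' (`n_ctrl` controls per signature gene, quantile bins, seeded). The
#' subtraction removes depth and global shifts: adding a constant to every
#' gene of a unit leaves the score unchanged.
#'
#' @param expr `normalized_expression` or units x genes matrix.
#' @param sig a [program_signature()] (or character vector of genes).
#' @param n_bins number of expression bins.
#' @param n_ctrl control genes sampled per signature gene.
#' @param seed seed for control sampling.
#' @param method `"binctrl"` (default) or `"zmean"` (mean per-gene z-score,
#'   no control pool).
#' @param bins optional precomputed bin assignment (named integer per gene),
#'   e.g. to keep bins fixed across perturbed copies of a matrix.
#' @return Named numeric vector of per-unit scores. Errors when fewer than
#'   half the signature genes are present.
#' @export
score_units <- function(expr, sig, n_bins = 24L, n_ctrl = 100L, seed = 1L,
                        method = c("binctrl", "zmean"), bins = NULL) {
  method <- match.arg(method)
  x <- expression_values(expr)
  genes <- if (inherits(sig, "program_signature")) sig$genes else sig
  assert_that(length(genes) > 0, "empty signature")
  present <- intersect(genes, colnames(x))
  missing <- setdiff(genes, colnames(x))
  if (length(missing)) {
    message(sprintf("%d of %d signature genes absent from the matrix",
                    length(missing), length(genes)))
  }
  assert_that(length(present) >= length(genes) / 2,
              "fewer than 50%% of signature genes present")
  if (method == "zmean") {
    xs <- as.matrix(x[, present, drop = FALSE])
    sds <- apply(xs, 2, stats::sd)
    keep <- sds > 0
    z <- scale(xs[, keep, drop = FALSE])
    return(stats::setNames(rowMeans(z), rownames(x)))
  }
  avg <- Matrix::colMeans(x)
  if (is.null(bins)) {
    qs <- unique(stats::quantile(avg, probs = seq(0, 1, length.out = n_bins + 1)))
    bins <- as.integer(cut(avg, breaks = qs, include.lowest = TRUE))
    names(bins) <- colnames(x)
  }
  # control genes come from the same expression bin but never from the
  # signature itself (self-contamination would cancel the signal)
  ctrl <- with_seed(seed, {
    unique(unlist(lapply(present, function(g) {
      pool <- setdiff(names(bins)[bins == bins[g]], present)
      if (length(pool) == 0) pool <- setdiff(names(bins), present)
      sample(pool, min(n_ctrl, length(pool)))
    })))
  })
  sig_mean <- Matrix::rowMeans(x[, present, drop = FALSE])
  ctrl_mean <- Matrix::rowMeans(x[, ctrl, drop = FALSE])
  stats::setNames(as.numeric(sig_mean - ctrl_mean), rownames(x))
}

#' Per-perturbation program enrichment
#'
#' For every (perturbation, program) pair: the difference in mean program
#' score between the perturbation's singlet cells and control cells
#' (`delta_score`), a Welch two-sided t-test p-value, and BH adjustment
#' across all pairs. Degenerate pairs (zero variance in both groups) get
#' p = 1 when the means agree exactly and p = 0 otherwise.
#'
#' @param scores units x programs matrix of program scores (columns named by
#'   program id), or a named list of per-unit score vectors.
#' @param assignment a [assign_guides()] result.
#' @param control_label control perturbation label.
#' @return Data frame with `perturbation`, `program`, `delta_score`, `p`,
#'   `fdr`.
#' @export
program_enrichment <- function(scores, assignment, control_label = "NTC") {
  if (is.list(scores) && !is.data.frame(scores)) {
    scores <- do.call(cbind, scores)
  }
  assert_that(is.matrix(scores) && !is.null(colnames(scores)),
              "scores must be a units x programs matrix with program names")
  sing <- assignment[assignment$status == "singlet", ]
  sing <- sing[sing$cell_id %in% rownames(scores), ]
  ctrl_cells <- sing$cell_id[sing$perturbation == control_label]
  assert_that(length(ctrl_cells) >= 3, "need >= 3 control cells")
  perts <- sort(setdiff(unique(sing$perturbation), control_label))
  rows <- list()
  for (p in perts) {
    cells <- sing$cell_id[sing$perturbation == p]
    if (length(cells) < 3) next
    for (pr in colnames(scores)) {
      a <- scores[cells, pr]; b <- scores[ctrl_cells, pr]
      delta <- mean(a) - mean(b)
      pv <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
      } else {
        stats::t.test(a, b)$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        perturbation = p, program = pr, delta_score = delta, p = pv,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out
}
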