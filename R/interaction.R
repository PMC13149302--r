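#' Build the PPI similarity matrix Omega
#'
#' Omega is the identity plus symmetrized protein-protein interaction scores
#' restricted to a gene space, defining the weighted inner product
#' `<a, b> = a' Omega b`. Because raw score matrices need not be positive
#' semidefinite, negative eigenvalues are clipped to zero and the diagonal
#' re-normalized to one (`psd_repair = TRUE`), which guarantees the
#' Cauchy-Schwarz bound `|S| <= 1` for the similarity built on it.
#'
#' @param edges data frame with `gene_a`, `gene_b`, `score` (scores in
#'   (0, 1]); self-edges are ignored with a warning, genes outside
#'   `gene_space` are dropped.
#' @param gene_space character vector defining the (ordered) pathway gene
#'   space.
#' @param psd_repair clip negative eigenvalues and rescale to unit diagonal.
#' @return A list of class `similarity_omega` with `genes`, `omega`
#'   (symmetric, unit diagonal), and `repaired` (`TRUE` when clipping
#'   changed any eigenvalue by more than 1e-6).
#' @export
build_omega <- function(edges, gene_space, psd_repair = TRUE) {
  assert_that(length(gene_space) > 0, "gene_space must be non-empty")
  assert_that(all(c("gene_a", "gene_b", "score") %in% names(edges)),
              "edges must have columns gene_a, gene_b, score")
  assert_that(all(edges$score > 0 & edges$score <= 1),
              "edge scores must lie in (0, 1]")
  gene_space <- unique(gene_space)
  self <- edges$gene_a == edges$gene_b
  if (any(self)) {
    warning(sprintf("ignoring %d self-edge(s)", sum(self)))
    edges <- edges[!self, , drop = FALSE]
  }
  keep <- edges$gene_a %in% gene_space & edges$gene_b %in% gene_space
  edges <- edges[keep, , drop = FALSE]
  n <- length(gene_space)
  omega <- diag(1, n)
  dimnames(omega) <- list(gene_space, gene_space)
  if (nrow(edges)) {
    ia <- match(edges$gene_a, gene_space)
    ib <- match(edges$gene_b, gene_space)
    omega[cbind(ia, ib)] <- edges$score
    omega[cbind(ib, ia)] <- edges$score
  }
  repaired <- FALSE
  if (psd_repair) {
    eig <- eigen(omega, symmetric = TRUE)
    if (min(eig$values) < 0) {
      clipped <- pmax(eig$values, 0)
      repaired <- any(abs(clipped - eig$values) > 1e-6)
      omega <- eig$vectors %*% (clipped * t(eig$vectors))
      d <- diag(omega)
      d[d <= 0] <- 1
      omega <- omega / sqrt(outer(d, d))
      diag(omega) <- 1
      omega <- (omega + t(omega)) / 2
      dimnames(omega) <- list(gene_space, gene_space)
    }
  }
  structure(list(genes = gene_space, omega = omega, repaired = repaired),
            class = "similarity_omega")
}

#' Build a perturbation's target vector on a pathway
#'
#' The signed effect profile of one perturbation restricted to a pathway:
#' `value_g = log2FC_g` when gene `g` is in the pathway and significant at
#' `fdr < fdr_cut`, 0 otherwise. Signs are kept because antagonism is
#' defined by opposite effects on shared targets.
#'
#' @param de a `de_table` (rows for one or more perturbations).
#' @param perturbation which perturbation's rows to use.
#' @param pathway character vector of pathway genes (defines the vector's
#'   gene space and order).
#' @param fdr_cut significance cutoff.
#' @return Named numeric vector over `pathway`; attribute `flagged` is
#'   `TRUE` when the vector is all zero (no significant pathway targets or
#'   no tested pathway genes).
#' @export
target_vector <- function(de, perturbation, pathway, fdr_cut = 0.05) {
  assert_that(length(pathway) > 0, "pathway must be non-empty")
  rows <- de[de$perturbation == perturbation & de$gene %in% pathway, ]
  v <- stats::setNames(numeric(length(pathway)), pathway)
  if (nrow(rows)) {
    sig <- rows$fdr < fdr_cut
    v[rows$gene[sig]] <- rows$log2_fold_change[sig]
  }
  attr(v, "flagged") <- all(v == 0)
  v
}

#' PPI-weighted similarity between two effect vectors
#'
#' `S(a, b) = <a, b>_Omega / sqrt(<a, a>_Omega <b, b>_Omega)` with
#' `<a, b>_Omega = a' Omega b`. For positive semidefinite Omega this lies in
#' \[-1, 1\]; with Omega = I it reduces to cosine similarity. A zero-norm
#' vector makes S undefined and returns `NA` (reported as missing, not 0).
#'
#' @param a,b named numeric vectors over `omega`'s gene space.
#' @param omega a [build_omega()] result (or a PSD matrix).
#' @return Scalar similarity in \[-1, 1\], or `NA` if undefined.
#' @export
weighted_similarity <- function(a, b, omega) {
  W <- if (inherits(omega, "similarity_omega")) omega$omega else omega
  genes <- rownames(W)
  if (!is.null(genes) && !is.null(names(a))) {
    assert_that(all(genes %in% names(a)) && all(genes %in% names(b)),
                "vectors must cover omega's gene space")
    a <- a[genes]; b <- b[genes]
  }
  assert_that(length(a) == nrow(W) && length(b) == nrow(W),
              "vector length must match omega")
  aa <- as.numeric(a %*% W %*% a)
  bb <- as.numeric(b %*% W %*% b)
  if (aa <= 0 || bb <= 0) return(NA_real_)
  s <- as.numeric(a %*% W %*% b) / sqrt(aa * bb)
  max(-1, min(1, s))
}

#' Synergistic and Antagonistic Indices from per-pathway similarities
#'
#' Aggregates defined per-pathway similarities by a weighted mean and maps
#' the aggregate linearly onto the 0-100 index scale: the Synergistic Index
#' is `100 * max(0, S_aggregate)`, the Antagonistic Index
#' `100 * max(0, -S_aggregate)`; at most one of the two is positive.
#'
#' @param per_pathway_S named numeric vector of per-pathway similarities
#'   (`NA` = undefined on that pathway).
#' @param pathway_weights optional non-negative weights (default: equal).
#' @return A list of class `interaction_scores`: `per_pathway_S`,
#'   `S_aggregate`, `synergistic_index`, `antagonistic_index` (all `NA` when
#'   every pathway is undefined).
#' @export
interaction_indices <- function(per_pathway_S, pathway_weights = NULL) {
  assert_that(length(per_pathway_S) >= 1, "need at least one pathway S")
  if (is.null(pathway_weights)) {
    pathway_weights <- rep(1, length(per_pathway_S))
  }
  assert_that(length(pathway_weights) == length(per_pathway_S) &&
                all(pathway_weights >= 0),
              "weights must be non-negative, one per pathway")
  ok <- !is.na(per_pathway_S) & pathway_weights > 0
  s_agg <- if (any(ok)) {
    sum(per_pathway_S[ok] * pathway_weights[ok]) / sum(pathway_weights[ok])
  } else NA_real_
  structure(list(
    per_pathway_S = per_pathway_S,
    S_aggregate = s_agg,
    synergistic_index = if (is.na(s_agg)) NA_real_ else 100 * max(0, s_agg),
    antagonistic_index = if (is.na(s_agg)) NA_real_ else 100 * max(0, -s_agg)
  ), class = "interaction_scores")
}

#' All pairwise interaction indices from a DE table
#'
#' Convenience wrapper tying the interaction stage together: builds one
#' Omega per pathway from the PPI edge list, forms every perturbation's
#' signed target vector per pathway, computes all pairwise weighted
#' similarities, and aggregates them into SI/AI.
#'
#' @param de a `de_table`.
#' @param pathways named list of pathway gene sets.
#' @param ppi PPI edge data frame (`gene_a`, `gene_b`, `score`).
#' @param fdr_cut significance cutoff for target vectors.
#' @param pathway_weights optional aggregation weights.
#' @param perturbations optional subset/order of perturbations.
#' @return Data frame with one row per unordered pair: `pert_a`, `pert_b`,
#'   one `S_<pathway>` column per pathway, `S_aggregate`,
#'   `synergistic_index`, `antagonistic_index`.
#' @export
compute_interactions <- function(de, pathways, ppi, fdr_cut = 0.05,
                                 pathway_weights = NULL,
                                 perturbations = NULL) {
  assert_that(length(pathways) > 0 && !is.null(names(pathways)),
              "pathways must be a named list")
  if (is.null(perturbations)) perturbations <- sort(unique(de$perturbation))
  omegas <- lapply(pathways, function(gs) build_omega(ppi, gs))
  vecs <- lapply(names(pathways), function(pw) {
    lapply(perturbations, function(p) {
      target_vector(de, p, pathways[[pw]], fdr_cut = fdr_cut)
    })
  })
  names(vecs) <- names(pathways)
  pairs <- utils::combn(perturbations, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    ia <- match(pairs[1, k], perturbations)
    ib <- match(pairs[2, k], perturbations)
    s_pw <- vapply(names(pathways), function(pw) {
      weighted_similarity(vecs[[pw]][[ia]], vecs[[pw]][[ib]], omegas[[pw]])
    }, 0)
    idx <- interaction_indices(s_pw, pathway_weights)
    out <- data.frame(pert_a = pairs[1, k], pert_b = pairs[2, k],
                      stringsAsFactors = FALSE)
    for (pw in names(pathways)) out[[paste0("S_", pw)]] <- s_pw[[pw]]
    out$S_aggregate <- idx$S_aggregate
    out$synergistic_index <- idx$synergistic_index
    out$antagonistic_index <- idx$antagonistic_index
    out
  })
  do.call(rbind, rows)
}
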