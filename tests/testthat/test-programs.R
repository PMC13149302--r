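block_beta <- function() {
  # two well-separated blocks of identical columns
  beta <- cbind(matrix(rep(c(5, 0, 0), 6), nrow = 3),
                matrix(rep(c(0, 0, -4), 6), nrow = 3))
  dimnames(beta) <- list(c("PA", "PB", "PC"), sprintf("G%02d", 1:12))
  beta
}

test_that("kNN graph respects block structure and the complete-graph limit", {
  beta <- block_beta()
  g <- build_gene_knn(beta, k = 3)
  el <- igraph::as_edgelist(g)
  blk <- function(x) ifelse(x %in% sprintf("G%02d", 1:6), 1L, 2L)
  expect_true(all(blk(el[, 1]) == blk(el[, 2])))  # no cross-block edges

  g_full <- build_gene_knn(beta, k = 11)
  expect_equal(igraph::ecount(g_full), choose(12, 2))  # complete graph
})

test_that("kNN neighbour lists match a brute-force all-pairs oracle", {
  set.seed(91)
  beta <- matrix(rnorm(5 * 20), nrow = 5,
                 dimnames = list(sprintf("P%d", 1:5), sprintf("g%02d", 1:20)))
  for (method in c("euclidean", "cosine")) {
    g <- build_gene_knn(beta, k = 4, method = method)
    d <- if (method == "euclidean") {
      as.matrix(stats::dist(t(beta)))
    } else {
      nr <- sqrt(colSums(beta^2))
      1 - crossprod(beta) / outer(nr, nr)
    }
    adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    genes <- colnames(beta)
    for (i in seq_along(genes)) {
      nb <- names(sort(d[genes[i], setdiff(genes, genes[i])]))[1:4]
      expect_true(all(adj[genes[i], nb] == 1),
                  label = sprintf("%s neighbours of gene %d present", method, i))
    }
    # union mutualization: every directed neighbour produces an edge
    expect_gte(igraph::ecount(g), 20 * 4 / 2)
  }
})

test_that("Louvain recovers disconnected cliques and is deterministic", {
  beta <- block_beta()
  g <- build_gene_knn(beta, k = 3)
  pr <- louvain_programs(g, beta, seed = 4L, min_program_size = 2L)
  expect_length(pr$programs, 2L)  # two disconnected cliques -> two programs
  expect_equal(unname(sort(vapply(pr$programs, `[[`, 0L, "size"))), c(6L, 6L))
  # labels are assigned in decreasing size and partition the genes
  expect_setequal(names(pr$membership), colnames(beta))

  pr2 <- louvain_programs(g, beta, seed = 4L, min_program_size = 2L)
  expect_identical(pr$membership, pr2$membership)

  # undersized clusters merge into the most correlated neighbour
  pr_min <- louvain_programs(g, beta, seed = 4L, min_program_size = 7L)
  expect_length(pr_min$programs, 1L)
})

test_that("program signatures take the top weight fraction deterministically", {
  w <- stats::setNames(seq(340, 1) / 100, sprintf("g%03d", 1:340))
  prog <- list(program_id = "P-0", members = names(w), weights = w,
               top_perturbations = "PA", size = 340L)
  sig <- program_signature(prog, fraction = 0.25)
  expect_length(sig$genes, 85L)  # ceiling(0.25 * 340)
  expect_equal(sig$genes, names(w)[1:85])

  expect_equal(program_signature(prog, fraction = 1)$genes, names(w))
  expect_error(program_signature(prog, fraction = 0), "fraction")

  # weight ties break lexicographically, independent of input order
  wt <- stats::setNames(c(1, 1, 1, 1), c("gB", "gD", "gA", "gC"))
  pt <- list(program_id = "P-1", members = names(wt), weights = wt, size = 4L)
  ps <- program_signature(pt, fraction = 0.5)
  wt2 <- wt[c(3, 1, 4, 2)]
  pt2 <- list(program_id = "P-1", members = names(wt2), weights = wt2, size = 4L)
  expect_equal(ps$genes, program_signature(pt2, fraction = 0.5)$genes)
  expect_equal(ps$genes, c("gA", "gB"))
})

test_that("bin-matched scoring is calibrated, shift-sensitive, and depth-invariant", {
  set.seed(92)
  n <- 500L
  genes <- sprintf("g%03d", 1:200)
  vals <- matrix(rnorm(n * 200, mean = 1.5, sd = 0.4), nrow = n,
                 dimnames = list(sprintf("c%03d", 1:n), genes))
  sig <- sample(genes, 20)

  # signature statistically identical to the pool: mean score ~ 0
  sc0 <- score_units(vals, sig, seed = 1L)
  expect_lt(abs(mean(sc0)), 0.05)

  # +1 to every signature gene in half the cells: score difference ~ 1
  # (bins held fixed at the unshifted matrix so bin membership is stable)
  avg0 <- colMeans(vals)
  qs0 <- unique(stats::quantile(avg0, probs = seq(0, 1, length.out = 25)))
  bins0 <- stats::setNames(as.integer(cut(avg0, qs0, include.lowest = TRUE)),
                           genes)
  vals1 <- vals
  vals1[1:250, sig] <- vals1[1:250, sig] + 1
  sc1 <- score_units(vals1, sig, seed = 1L, bins = bins0)
  expect_equal(mean(sc1[1:250]) - mean(sc1[251:500]), 1, tolerance = 0.1)

  # identical cells get identical scores
  vals2 <- vals[rep(1L, 10), ]
  rownames(vals2) <- sprintf("dup%02d", 1:10)
  sc2 <- score_units(vals2, sig, seed = 1L)
  expect_equal(max(sc2) - min(sc2), 0)

  # adding a constant to every gene of a cell cancels out (fixed bins)
  avg <- colMeans(vals)
  qs <- unique(stats::quantile(avg, probs = seq(0, 1, length.out = 25)))
  bins <- stats::setNames(as.integer(cut(avg, qs, include.lowest = TRUE)), genes)
  shifted <- vals
  shifted[3, ] <- shifted[3, ] + 7
  sa <- score_units(vals, sig, seed = 1L, bins = bins)
  sb <- score_units(shifted, sig, seed = 1L, bins = bins)
  expect_equal(sb[3], sa[3], tolerance = 1e-10)
  expect_error(score_units(vals[, 1:5], sig, seed = 1L), "50%")
})

test_that("program enrichment tests perturbations against control", {
  set.seed(93)
  cells <- c(sprintf("p%03d", 1:300), sprintf("n%03d", 1:300))
  asg <- data.frame(cell_id = cells,
                    status = "singlet",
                    sgrna_id = "sg",
                    perturbation = rep(c("TGTX", "NTC"), each = 300),
                    stringsAsFactors = FALSE)
  class(asg) <- c("guide_assignment", "data.frame")
  scores <- cbind(
    "P-0" = c(rnorm(300, 0.4, 1), rnorm(300, 0, 1)),  # derepressed program
    "P-1" = rnorm(600))                                # unaffected program
  rownames(scores) <- cells
  enr <- program_enrichment(scores, asg)
  expect_equal(nrow(enr), 2L)
  hit <- enr[enr$program == "P-0", ]
  expect_lt(hit$fdr, 0.05)
  expect_lt(abs(hit$delta_score - 0.4), 0.3)

  # swapping the group labels negates delta
  asg_sw <- asg
  asg_sw$perturbation <- rep(c("NTC", "TGTX"), each = 300)
  enr_sw <- program_enrichment(scores, asg_sw)
  expect_equal(enr_sw$delta_score, -enr$delta_score)
  expect_equal(enr_sw$p, enr$p, tolerance = 1e-12)

  # degenerate variance fast path
  scores_c <- cbind("P-0" = rep(1, 600))
  rownames(scores_c) <- cells
  enr_c <- program_enrichment(scores_c, asg)
  expect_equal(enr_c$p, 1)
  expect_equal(enr_c$delta_score, 0)
})

test_that("planted program derepression is detected with high power", {
  # effect 0.43 on the program score at ~546 perturbed vs ~450 control cells
  set.seed(94)
  detected <- vapply(1:20, function(i) {
    cells <- c(sprintf("p%03d", 1:546), sprintf("n%03d", 1:450))
    asg <- data.frame(cell_id = cells, status = "singlet", sgrna_id = "sg",
                      perturbation = c(rep("TGTX", 546), rep("NTC", 450)),
                      stringsAsFactors = FALSE)
    class(asg) <- c("guide_assignment", "data.frame")
    scores <- cbind("P-0" = c(rnorm(546, 0.43, 1), rnorm(450, 0, 1)))
    rownames(scores) <- cells
    program_enrichment(scores, asg)$fdr < 0.05
  }, NA)
  expect_gte(mean(detected), 0.9)
})
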