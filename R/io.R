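#' Write a count matrix as a Matrix-Market triplet
#'
#' CellRanger-style layout: `matrix.mtx` stores genes x cells (1-based
#' Matrix-Market coordinates on disk), `barcodes.tsv` one cell barcode per
#' line, `features.tsv` one gene symbol per line.
#'
#' @param m a [perturb_counts] (internally cells x genes).
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_counts_mtx <- function(m, dir) {
  assert_that(inherits(m, "perturb_counts"), "m must be a perturb_counts")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  Matrix::writeMM(Matrix::t(m$counts), paths[1])
  writeLines(rownames(m$counts), paths[2])
  writeLines(colnames(m$counts), paths[3])
  invisible(paths)
}

# read a Matrix-Market file, transparently handling gzip compression
.read_mm <- function(path) {
  if (grepl("\\.gz$", path)) {
    tmp <- tempfile(fileext = ".mtx")
    on.exit(unlink(tmp))
    writeLines(readLines(gzfile(path)), tmp)
    path <- tmp
  }
  Matrix::readMM(path)
}

.read_lines_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) readLines(gzfile(path)) else readLines(path)
}

#' Read a CellRanger-style Matrix-Market triplet
#'
#' Expects genes x cells on disk (1-based Matrix-Market indices) and returns
#' the internal cells x genes representation. Plain or gzip-compressed
#' files are accepted. Dimension mismatches raise a format error naming the
#' offending file.
#'
#' @param mtx_path,barcodes_path,features_path the triplet's paths.
#' @return A [perturb_counts] (QC metrics not yet computed).
#' @export
read_counts_mtx <- function(mtx_path, barcodes_path, features_path) {
  for (p in c(mtx_path, barcodes_path, features_path)) {
    assert_that(file.exists(p), "input file not found: %s", p)
  }
  mm <- .read_mm(mtx_path)
  barcodes <- .read_lines_maybe_gz(barcodes_path)
  features <- .read_lines_maybe_gz(features_path)
  if (nrow(mm) != length(features)) {
    abort("format error: %s lists %d genes but %s declares %d rows",
          features_path, length(features), mtx_path, nrow(mm))
  }
  if (ncol(mm) != length(barcodes)) {
    abort("format error: %s lists %d barcodes but %s declares %d columns",
          barcodes_path, length(barcodes), mtx_path, ncol(mm))
  }
  counts <- Matrix::t(mm)
  dimnames(counts) <- list(barcodes, features)
  perturb_counts(counts)
}

#' Read / write the per-cell guide capture table
#'
#' Tab-separated with header `cell_id`, `sgrna_id`, `target_gene`,
#' `umi_count`.
#'
#' @param path file path.
#' @rdname guide_io
#' @return `read_guides()`: the guide data frame.
#' @export
read_guides <- function(path) {
  assert_that(file.exists(path), "input file not found: %s", path)
  gt <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "sgrna_id", "target_gene", "umi_count")
  assert_that(all(need %in% names(gt)),
              "guide table must have columns %s", paste(need, collapse = ", "))
  gt
}

#' @param guides guide data frame.
#' @rdname guide_io
#' @export
write_guides <- function(guides, path) {
  utils::write.table(guides, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write GMT gene-set files
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes. Duplicate set names are an error.
#'
#' @param path file path.
#' @rdname gmt_io
#' @return `read_gmt()`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  assert_that(file.exists(path), "input file not found: %s", path)
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  lines <- lines[lengths(lines) >= 3]
  nm <- vapply(lines, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    abort("duplicate gene-set names in %s: %s", path,
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(lines, function(x) x[-(1:2)])
  names(sets) <- nm
  sets
}

#' @param sets named list of gene sets.
#' @param descriptions optional per-set description column.
#' @rdname gmt_io
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  assert_that(!is.null(names(sets)), "sets must be named")
  if (is.null(descriptions)) descriptions <- rep("synthetic", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a PPI edge list
#'
#' Tab-separated with header `gene_a`, `gene_b`, `score`; scores must lie
#' in (0, 1].
#'
#' @param path file path.
#' @rdname ppi_io
#' @return `read_ppi()`: the edge data frame.
#' @export
read_ppi <- function(path) {
  assert_that(file.exists(path), "input file not found: %s", path)
  edges <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "score")
  assert_that(all(need %in% names(edges)),
              "PPI table must have columns %s", paste(need, collapse = ", "))
  assert_that(all(edges$score > 0 & edges$score <= 1),
              "PPI scores must lie in (0, 1]")
  structure(edges, class = c("ppi_edges", "data.frame"))
}

#' @param edges edge data frame.
#' @rdname ppi_io
#' @export
write_ppi <- function(edges, path) {
  utils::write.table(as.data.frame(edges)[, c("gene_a", "gene_b", "score")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.cohort_covariate_names <- c("age", "risk_group", "FLT3", "NPM1", "TP53",
                             "DNMT3A", "CEBPA", "RUNX1")

#' Read / write a survival cohort CSV
#'
#' One row per sample: `sample_id`, `time`, `event`, the clinical covariates
#' (age, cytogenetic risk group, mutation flags), then one column per gene.
#' Times must be positive and events 0/1.
#'
#' @param path file path.
#' @rdname cohort_io
#' @return `read_cohort()`: a `survival_cohort`.
#' @export
read_cohort <- function(path) {
  assert_that(file.exists(path), "input file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "time", "event")
  assert_that(all(need %in% names(df)),
              "cohort must have columns %s", paste(need, collapse = ", "))
  assert_that(all(df$time > 0), "survival times must be positive")
  assert_that(all(df$event %in% c(0, 1)), "events must be 0/1")
  covars <- intersect(.cohort_covariate_names, names(df))
  gene_cols <- setdiff(names(df), c(need, covars))
  covariates <- df[, covars, drop = FALSE]
  if ("risk_group" %in% covars) {
    covariates$risk_group <- factor(covariates$risk_group,
                                    levels = c("favorable", "intermediate",
                                               "adverse"))
  }
  rownames(covariates) <- df$sample_id
  expr <- as.matrix(df[, gene_cols, drop = FALSE])
  rownames(expr) <- df$sample_id
  structure(list(expr = expr, time = df$time, event = as.integer(df$event),
                 covariates = covariates, true_score = NULL,
                 sample_ids = df$sample_id),
            class = "survival_cohort")
}

#' @param cohort a `survival_cohort`.
#' @rdname cohort_io
#' @export
write_cohort <- function(cohort, path) {
  df <- data.frame(sample_id = cohort$sample_ids, time = cohort$time,
                   event = cohort$event, stringsAsFactors = FALSE)
  df <- cbind(df, cohort$covariates)
  df <- cbind(df, as.data.frame(cohort$expr, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a drug AUC table
#'
#' CSV with `sample_id` then one column per drug.
#'
#' @param path file path.
#' @rdname drug_io
#' @return `read_drug_auc()`: samples x drugs matrix.
#' @export
read_drug_auc <- function(path) {
  assert_that(file.exists(path), "input file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  assert_that("sample_id" %in% names(df), "drug table needs a sample_id column")
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  rownames(m) <- df$sample_id
  m
}

#' @param auc samples x drugs matrix.
#' @rdname drug_io
#' @export
write_drug_auc <- function(auc, path) {
  df <- data.frame(sample_id = rownames(auc), as.data.frame(auc,
                                                            check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
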