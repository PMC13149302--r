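.default_config <- function() {
  list(
    master_seed = 1L,
    output_dir = "perturbcircuit_out",
    sim = list(n_genes = 2000L, n_targets = 6L, n_guides_per_target = 3L,
               n_programs = 8L, genes_per_program = 40L,
               cells_per_guide = 120L, n_control_cells = 360L,
               doublet_rate = 0.05),
    paths = list(counts_mtx = NULL, barcodes = NULL, features = NULL,
                 guides = NULL, ppi = NULL, pathways = NULL,
                 cohort = NULL, drug_auc = NULL),
    qc = list(min_genes = 200L, min_counts = 1000L, max_mito = 0.20,
              mito_prefix = "MT-"),
    assign = list(min_umi = 3L, dominance_ratio = 2),
    de = list(min_frac = 0.5, fdr_family = "per_perturbation"),
    fit = list(alpha = 0.5, n_lambda = 30L, split = c(0.8, 0.1, 0.1)),
    programs = list(k = 5L, resolution = 1.0, min_program_size = 10L,
                    signature_fraction = 0.25),
    scoring = list(n_bins = 24L, n_ctrl = 100L, method = "binctrl"),
    interaction = list(fdr_cut = 0.05),
    clinical = list(program = "P-0", n_samples = 300L, hr_per_unit = 0.5,
                    censor_rate = 0.3, n_perm = 200L, adjust = TRUE,
                    r_target = -0.35, n_null_drugs = 9L)
  )
}

#' Assemble and validate a pipeline configuration
#'
#' Merges user overrides (an R list, or a YAML file path) into the default
#' configuration. Unknown keys — at the top level or within a section — are
#' rejected, so a typo cannot silently fall back to a default. When
#' `sim` is disabled (`sim = NULL`) every required input path must be set
#' and exist.
#'
#' @param config named list of overrides, or a YAML file path.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    assert_that(file.exists(config), "config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- .default_config()
  unknown <- setdiff(names(config), names(defaults))
  assert_that(length(unknown) == 0,
              "unknown config keys: %s", paste(unknown, collapse = ", "))
  merged <- defaults
  for (key in names(config)) {
    if (is.list(defaults[[key]]) && !is.null(config[[key]])) {
      bad <- setdiff(names(config[[key]]), names(defaults[[key]]))
      assert_that(length(bad) == 0, "unknown config keys under %s: %s",
                  key, paste(bad, collapse = ", "))
      merged[[key]] <- utils::modifyList(defaults[[key]], config[[key]])
    } else {
      merged[[key]] <- config[[key]]
    }
  }
  if ("sim" %in% names(config) && is.null(config$sim)) merged["sim"] <- list(NULL)
  if (is.null(merged$sim)) {
    need <- c("counts_mtx", "barcodes", "features", "guides", "ppi", "pathways")
    for (key in need) {
      p <- merged$paths[[key]]
      assert_that(!is.null(p), "config error: paths$%s required when sim is off", key)
      assert_that(file.exists(p), "config error: missing input path %s", p)
    }
  }
  structure(merged, class = c("pipeline_config", "list"))
}

# stable hash of the configuration (paths and output location excluded)
.config_hash <- function(config) {
  core <- config[setdiff(names(config), c("output_dir", "paths"))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(core), tmp)
  unname(tools::md5sum(tmp))
}

.file_record <- function(path) {
  list(file = basename(path), md5 = unname(tools::md5sum(path)),
       bytes = unname(file.size(path)))
}

#' Run the full circuit-mapping pipeline
#'
#' Executes, as configured: input simulation (or loading), QC and guide
#' assignment, differential expression, regulatory-matrix inference, program
#' discovery and scoring, pairwise interaction indices, and the clinical
#' stage (cohort scoring, Cox association, KM stratification, permutation
#' specificity, drug correlation). Every artifact is written under
#' `output_dir` with its content hash recorded in `manifest.json`, alongside
#' the effective configuration, its hash, and per-stage timings and record
#' counts; a rerun with the same configuration and master seed reproduces
#' every artifact hash. A stage failure stops the run after writing a
#' manifest of the stages completed so far.
#'
#' @param config a [pipeline_config()] (or a list / YAML path coerced by it).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed_of <- function(stream) seed_stream(config$master_seed, stream)
  manifest <- list(config = config[setdiff(names(config), "paths")],
                   config_hash = .config_hash(config),
                   master_seed = config$master_seed,
                   stages = list())
  state <- new.env(parent = emptyenv())

  log_stage <- function(name, records, outputs = character()) {
    manifest$stages[[name]] <<- list(
      records = records,
      elapsed_s = round(as.numeric(Sys.time()) - state$t0, 3),
      outputs = lapply(outputs, .file_record))
    message(sprintf("[%s] %d records (%.1fs)", name, records,
                    manifest$stages[[name]]$elapsed_s))
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  run_stage <- function(name, body) {
    state$t0 <- as.numeric(Sys.time())
    tryCatch(body(), error = function(e) {
      manifest$stages[[name]] <<- list(error = conditionMessage(e))
      write_manifest()
      abort("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  in_dir <- file.path(out_dir, "inputs")

  run_stage("simulate", function() {
    if (is.null(config$sim)) {
      state$paths <- config$paths
      log_stage("simulate", 0L)
      return()
    }
    sim_args <- config$sim
    sim_args$seed <- seed_of(10L)
    truth <- generate_truth(do.call(sim_config, sim_args))
    sim <- simulate_counts(truth, seed = seed_of(11L))
    ppi <- simulate_ppi(truth, seed = seed_of(12L))
    pathways <- simulate_pathways(truth, seed = seed_of(13L))
    dir.create(in_dir, recursive = TRUE, showWarnings = FALSE)
    mtx <- write_counts_mtx(sim$counts, in_dir)
    write_guides(sim$guides, file.path(in_dir, "guides.tsv"))
    write_ppi(ppi, file.path(in_dir, "ppi.tsv"))
    write_gmt(pathways, file.path(in_dir, "pathways.gmt"))
    state$truth <- truth
    state$paths <- list(counts_mtx = mtx[1], barcodes = mtx[2],
                        features = mtx[3],
                        guides = file.path(in_dir, "guides.tsv"),
                        ppi = file.path(in_dir, "ppi.tsv"),
                        pathways = file.path(in_dir, "pathways.gmt"))
    log_stage("simulate", nrow(sim$counts$counts),
              unlist(state$paths, use.names = FALSE))
  })

  run_stage("load", function() {
    p <- state$paths
    state$counts <- read_counts_mtx(p$counts_mtx, p$barcodes, p$features)
    state$guides <- read_guides(p$guides)
    state$ppi <- read_ppi(p$ppi)
    state$pathways <- read_gmt(p$pathways)
    log_stage("load", nrow(state$counts$counts))
  })

  run_stage("qc", function() {
    m <- compute_qc_metrics(state$counts, mito_prefix = config$qc$mito_prefix)
    m <- filter_cells(m, min_genes = config$qc$min_genes,
                      min_counts = config$qc$min_counts,
                      max_mito = config$qc$max_mito)
    state$counts <- m
    path <- file.path(out_dir, "qc_metrics.csv")
    utils::write.csv(cbind(cell_id = rownames(m$per_cell), m$per_cell), path,
                     row.names = FALSE, quote = FALSE)
    log_stage("qc", nrow(m$counts), path)
  })

  run_stage("assign", function() {
    asg <- assign_guides(state$guides, min_umi = config$assign$min_umi,
                         dominance_ratio = config$assign$dominance_ratio,
                         cell_ids = rownames(state$counts$counts))
    state$assignment <- asg
    state$coverage <- coverage_summary(asg)
    path <- file.path(out_dir, "assignment.csv")
    utils::write.csv(asg, path, row.names = FALSE, quote = FALSE)
    log_stage("assign", nrow(asg), path)
  })

  run_stage("diffexpr", function() {
    state$expr <- normalize_counts(state$counts)
    de <- de_analysis(state$expr, state$assignment,
                      min_frac = config$de$min_frac,
                      fdr_family = config$de$fdr_family)
    state$de <- de
    path <- file.path(out_dir, "de.csv")
    utils::write.csv(de, path, row.names = FALSE, quote = FALSE)
    log_stage("diffexpr", nrow(de), path)
  })

  run_stage("fit", function() {
    hvgs <- select_hvgs(state$expr)
    design <- perturbation_design(state$assignment)
    R <- fit_regulatory_matrix(state$expr, design, hvgs,
                               alpha = config$fit$alpha,
                               n_lambda = config$fit$n_lambda,
                               split = config$fit$split,
                               seed = seed_of(20L))
    state$regmatrix <- R
    path <- file.path(out_dir, "regulatory_matrix.csv")
    utils::write.csv(data.frame(perturbation = rownames(R$beta),
                                as.data.frame(R$beta, check.names = FALSE),
                                check.names = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    log_stage("fit", length(R$beta), path)
  })

  run_stage("programs", function() {
    g <- build_gene_knn(state$regmatrix, k = config$programs$k)
    progs <- louvain_programs(g, state$regmatrix,
                              resolution = config$programs$resolution,
                              seed = seed_of(21L),
                              min_program_size = config$programs$min_program_size)
    state$programs <- progs
    state$signatures <- lapply(progs$programs, program_signature,
                               fraction = config$programs$signature_fraction)
    path <- file.path(out_dir, "programs.csv")
    tab <- do.call(rbind, lapply(progs$programs, function(p) {
      data.frame(program = p$program_id, gene = p$members,
                 weight = as.numeric(p$weights[p$members]),
                 in_signature = p$members %in%
                   state$signatures[[p$program_id]]$genes,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
    log_stage("programs", length(progs$programs), path)
  })

  run_stage("score", function() {
    scores <- vapply(state$signatures, function(sig) {
      score_units(state$expr, sig, n_bins = config$scoring$n_bins,
                  n_ctrl = config$scoring$n_ctrl, seed = seed_of(22L),
                  method = config$scoring$method)
    }, numeric(nrow(state$expr$values)))
    state$scores <- scores
    enr <- program_enrichment(scores, state$assignment)
    state$enrichment <- enr
    path <- file.path(out_dir, "program_enrichment.csv")
    utils::write.csv(enr, path, row.names = FALSE, quote = FALSE)
    log_stage("score", nrow(enr), path)
  })

  run_stage("interact", function() {
    inter <- compute_interactions(state$de, state$pathways, state$ppi,
                                  fdr_cut = config$interaction$fdr_cut)
    state$interactions <- inter
    path <- file.path(out_dir, "interactions.csv")
    utils::write.csv(inter, path, row.names = FALSE, quote = FALSE)
    log_stage("interact", nrow(inter), path)
  })

  run_stage("clinical", function() {
    cl <- config$clinical
    sig <- state$signatures[[cl$program]]
    if (is.null(sig)) sig <- state$signatures[[1L]]
    if (!is.null(config$sim)) {
      sig_genes <- intersect(sig$genes, state$truth$gene_ids)
      cohort <- simulate_cohort(state$truth, sig_genes,
                                n_samples = cl$n_samples,
                                hr_per_unit = cl$hr_per_unit,
                                censor_rate = cl$censor_rate,
                                seed = seed_of(30L))
      drug_auc <- simulate_drug_response(cohort$true_score,
                                         r_target = cl$r_target,
                                         n_null_drugs = cl$n_null_drugs,
                                         seed = seed_of(31L))
      rownames(drug_auc) <- cohort$sample_ids
    } else {
      if (is.null(config$paths$cohort)) {
        log_stage("clinical", 0L)
        return()
      }
      cohort <- read_cohort(config$paths$cohort)
      drug_auc <- if (!is.null(config$paths$drug_auc)) {
        read_drug_auc(config$paths$drug_auc)
      }
    }
    scores <- score_bulk(cohort$expr, sig)
    cox <- cox_association(scores, cohort, adjust = cl$adjust)
    km <- km_stratify(scores, cohort)
    perm <- permutation_specificity(cohort, sig, n_perm = cl$n_perm,
                                    seed = seed_of(32L))
    res <- data.frame(
      program = sig$program_id, n = cox$n, n_events = cox$n_events,
      hazard_ratio = cox$hazard_ratio, ci_lo = cox$ci95[1],
      ci_hi = cox$ci95[2], cox_p = cox$p, adjusted = cox$adjusted,
      logrank_p = km$p, permutation_p = perm$empirical_p,
      n_permutations = length(perm$null_hr), stringsAsFactors = FALSE)
    path <- file.path(out_dir, "clinical.csv")
    utils::write.csv(res, path, row.names = FALSE, quote = FALSE)
    outputs <- path
    if (!is.null(drug_auc)) {
      dc <- drug_correlation(scores, drug_auc)
      dpath <- file.path(out_dir, "drug_correlation.csv")
      utils::write.csv(dc, dpath, row.names = FALSE, quote = FALSE)
      outputs <- c(outputs, dpath)
      state$drug <- dc
    }
    state$clinical <- res
    log_stage("clinical", 1L, outputs)
  })

  write_manifest()
  manifest$stages <- manifest$stages
  invisible(manifest)
}
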