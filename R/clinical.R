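#' Score a program signature in bulk samples
#'
#' Per-sample mean of per-gene z-scored (across samples) signature
#' expression. Constant genes cannot be z-scored and are excluded with a
#' message; if every covered signature gene is constant all scores are 0.
#'
#' @param expr samples x genes numeric matrix.
#' @param sig a [program_signature()] or character vector (>= 50% of genes
#'   must be present in `expr`).
#' @return Named numeric vector of per-sample scores.
#' @export
score_bulk <- function(expr, sig) {
  genes <- if (inherits(sig, "program_signature")) sig$genes else sig
  assert_that(length(genes) > 0, "empty signature")
  present <- intersect(genes, colnames(expr))
  assert_that(length(present) >= length(genes) / 2,
              "fewer than 50%% of signature genes present")
  xs <- as.matrix(expr[, present, drop = FALSE])
  sds <- apply(xs, 2, stats::sd)
  if (any(sds == 0)) {
    message(sprintf("excluding %d constant gene(s) from z-scoring", sum(sds == 0)))
  }
  keep <- sds > 0
  if (!any(keep)) {
    return(stats::setNames(rep(0, nrow(expr)), rownames(expr)))
  }
  z <- scale(xs[, keep, drop = FALSE])
  stats::setNames(rowMeans(z), rownames(expr))
}

# covariate-adjusted model frame for a survival_cohort
.cohort_frame <- function(scores, cohort) {
  df <- data.frame(time = cohort$time, event = cohort$event,
                   score = as.numeric(scores[cohort$sample_ids]))
  cbind(df, cohort$covariates)
}

#' Cox proportional-hazards association of a program score with survival
#'
#' Fits `Surv(time, event) ~ score (+ covariates)` by Cox partial likelihood
#' (Efron tie handling) and reports the hazard ratio per unit score with its
#' Wald 95% CI and p-value. With `adjust = TRUE` the fit includes age,
#' cytogenetic risk group (treatment contrasts) and the mutation flags
#' carried by the cohort.
#'
#' @param scores named per-sample scores.
#' @param cohort a `survival_cohort` (or a list/data frame with `time`,
#'   `event`, `covariates`, `sample_ids`).
#' @param adjust include covariates.
#' @return A list of class `survival_result`: `hazard_ratio`, `ci95`, `p`,
#'   `coef`, `se`, `n`, `n_events`, `adjusted`, `converged`, `fit`.
#' @export
cox_association <- function(scores, cohort, adjust = TRUE) {
  df <- .cohort_frame(scores, cohort)
  assert_that(sum(df$event) >= 10, "need at least 10 events")
  fml <- if (adjust) {
    covars <- setdiff(names(df), c("time", "event", "score"))
    stats::as.formula(paste("survival::Surv(time, event) ~ score +",
                            paste(covars, collapse = " + ")))
  } else {
    survival::Surv(time, event) ~ score
  }
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|singular", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  sm <- summary(fit)
  co <- sm$coefficients["score", ]
  structure(list(
    hazard_ratio = unname(exp(co["coef"])),
    ci95 = unname(exp(co["coef"] + c(-1, 1) * stats::qnorm(0.975) * co["se(coef)"])),
    p = unname(co["Pr(>|z|)"]),
    coef = unname(co["coef"]), se = unname(co["se(coef)"]),
    n = nrow(df), n_events = sum(df$event),
    adjusted = adjust, converged = converged, fit = fit
  ), class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat(sprintf("HR = %.3f (95%% CI %.3f-%.3f), p = %.3g, n = %d (%d events, %s)\n",
              x$hazard_ratio, x$ci95[1], x$ci95[2], x$p, x$n, x$n_events,
              if (x$adjusted) "adjusted" else "unadjusted"))
  invisible(x)
}

#' Kaplan-Meier stratification by program score
#'
#' Splits samples into high/low strata at a score cut (default: the median;
#' samples exactly at the cut go to the low stratum, so with an odd number
#' of distinct scores the larger group contains the median sample) and
#' compares the strata by the two-group log-rank test.
#'
#' @param scores named per-sample scores.
#' @param cohort a `survival_cohort`.
#' @param cut `"median"` or a numeric cut point.
#' @return List with `groups` (factor high/low), `fit` (a
#'   [survival::survfit] object for the two strata), `chisq`, `p`.
#' @export
km_stratify <- function(scores, cohort, cut = "median") {
  df <- .cohort_frame(scores, cohort)
  cutoff <- if (identical(cut, "median")) stats::median(df$score) else cut
  groups <- factor(ifelse(df$score > cutoff, "high", "low"),
                   levels = c("low", "high"))
  assert_that(nlevels(droplevels(groups)) == 2,
              "all scores on one side of the cut; stratification impossible")
  sd <- survival::survdiff(survival::Surv(time, event) ~ groups, data = df)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ groups, data = df)
  list(groups = stats::setNames(groups, cohort$sample_ids),
       fit = fit, chisq = unname(sd$chisq), p = p)
}

#' Size-matched permutation specificity of a prognostic signature
#'
#' Compares the signature's unadjusted hazard ratio with the null
#' distribution of HRs from `n_perm` uniform random gene sets of the same
#' size drawn from `candidate_pool`. All scores (observed and null) are
#' standardized before fitting, so every HR is per standard deviation of
#' its own score — a random set's mean z-score has variance ~1/size while a
#' co-regulated signature's is near 1, and per-raw-unit HRs would not be
#' comparable across that difference. The empirical p-value uses the
#' add-one estimator `(1 + #\{null HR <= observed HR\}) / (n_perm + 1)`, so
#' a protective signature (small HR) gets a small p. Null fits that fail to
#' converge are dropped and counted.
#'
#' @param cohort a `survival_cohort`.
#' @param sig a [program_signature()] or character gene vector.
#' @param n_perm number of random gene sets (>= 1).
#' @param seed seed for the draws.
#' @param candidate_pool genes to draw from (default: all cohort genes;
#'   must be at least 10x the signature size).
#' @return List with `observed_hr`, `null_hr` (vector), `empirical_p`,
#'   `n_dropped`.
#' @export
permutation_specificity <- function(cohort, sig, n_perm = 10000L, seed = 1L,
                                    candidate_pool = NULL) {
  assert_that(is_count(n_perm, 1L), "n_perm must be a positive count")
  genes <- if (inherits(sig, "program_signature")) sig$genes else sig
  if (is.null(candidate_pool)) candidate_pool <- colnames(cohort$expr)
  assert_that(length(candidate_pool) >= 10 * length(genes),
              "candidate pool must be at least 10x the signature size")
  # z-score the pool once; every draw's score is then a row mean
  xs <- as.matrix(cohort$expr[, candidate_pool, drop = FALSE])
  sds <- apply(xs, 2, stats::sd)
  xs <- xs[, sds > 0, drop = FALSE]
  z <- scale(xs)
  surv <- survival::Surv(cohort$time, cohort$event)
  hr_of <- function(sc) {
    if (stats::sd(sc) == 0) return(NA_real_)
    sc <- as.numeric(scale(sc))
    fit <- tryCatch(
      survival::coxph(surv ~ sc, ties = "efron"),
      warning = function(w) NULL, error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    unname(exp(stats::coef(fit)[1]))
  }
  observed <- hr_of(score_bulk(cohort$expr, genes)[cohort$sample_ids])
  m <- length(genes)
  null_hr <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(ncol(z), m)
      hr_of(rowMeans(z[, idx, drop = FALSE]))
    }, 0)
  })
  dropped <- sum(is.na(null_hr))
  null_hr <- null_hr[!is.na(null_hr)]
  list(observed_hr = observed,
       null_hr = null_hr,
       empirical_p = (1 + sum(null_hr <= observed)) / (length(null_hr) + 1),
       n_dropped = dropped)
}

#' Correlate program scores with drug sensitivity
#'
#' Pearson correlation of per-sample program scores with each drug's AUC
#' (pairwise-complete), with two-sided p-values and BH adjustment across
#' drugs. Lower AUC means higher sensitivity, so negative correlations mark
#' drugs to which high-program samples are sensitized.
#'
#' @param scores named per-sample scores.
#' @param drug_auc samples x drugs AUC matrix (may contain `NA`).
#' @param min_pairs minimum paired observations per drug; drugs below it, or
#'   with constant AUC, are flagged and get `NA` statistics.
#' @return Data frame: `drug`, `n`, `pearson_r`, `p`, `fdr`, `sensitizing`,
#'   `flagged`.
#' @export
drug_correlation <- function(scores, drug_auc, min_pairs = 20L) {
  assert_that(is.matrix(drug_auc) && !is.null(colnames(drug_auc)),
              "drug_auc must be a samples x drugs matrix")
  common <- intersect(names(scores), rownames(drug_auc))
  assert_that(length(common) >= min_pairs, "too few paired samples")
  s <- scores[common]
  rows <- lapply(colnames(drug_auc), function(d) {
    auc <- drug_auc[common, d]
    ok <- !is.na(auc) & !is.na(s)
    n <- sum(ok)
    if (n < min_pairs || stats::sd(auc[ok]) == 0 || stats::sd(s[ok]) == 0) {
      return(data.frame(drug = d, n = n, pearson_r = NA_real_, p = NA_real_,
                        flagged = TRUE, stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(s[ok], auc[ok], method = "pearson")
    data.frame(drug = d, n = n, pearson_r = unname(ct$estimate),
               p = ct$p.value, flagged = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  ok <- !out$flagged
  if (any(ok)) out$fdr[ok] <- bh_adjust(out$p[ok])
  out$sensitizing <- !is.na(out$pearson_r) & out$pearson_r < 0
  out[, c("drug", "n", "pearson_r", "p", "fdr", "sensitizing", "flagged")]
}
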