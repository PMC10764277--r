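# Association module: abundance filters and transformation, longitudinal
# linear mixed models for WLZ and treatment effects, metatranscriptome
# preprocessing (DNA-conditioned zeroing, CPM filter, TMM), negative-binomial
# differential expression, the GSEA ranking metric and BH FDR adjustment.

#' Abundance/prevalence filter for MAG DNA abundance
#'
#' Keeps a MAG iff its abundance is strictly greater than `min_tpm` in
#' strictly more than `min_prev` of samples.
#'
#' @param dna_tpm MAGs x samples TPM matrix.
#' @param min_tpm,min_prev thresholds (both strict).
#' @return character vector of surviving MAG ids.
#' @export
filterMagsTpm <- function(dna_tpm, min_tpm = 5, min_prev = 0.40) {
  if (is.null(dna_tpm) || nrow(dna_tpm) == 0) return(character(0))
  prev <- rowMeans(dna_tpm > min_tpm)
  rownames(dna_tpm)[prev > min_prev]
}

#' Variance-stabilizing transformation of count data
#'
#' Median-of-ratios size-factor normalization followed by a shifted log2
#' (`log2(count / sizefactor + 1)`): monotone within sample, finite on zeros,
#' and flattening the mean-variance trend of overdispersed counts relative to
#' an unnormalized log transform.
#'
#' @param counts features x samples non-negative count matrix.
#' @return matrix of the same shape (`vst` layer); size factors attached as
#'   attribute `sizeFactors`.
#' @export
varianceStabilize <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  zero <- colSums(counts) == 0
  if (any(zero))
    stop("size factor undefined for sample '",
         colnames(counts)[which(zero)[1]], "' (no positive counts)")
  lg <- rowMeans(log(counts))
  if (!any(is.finite(lg)))  # no all-positive gene: positive-cell geomeans
    lg <- apply(counts, 1, function(x)
      if (any(x > 0)) mean(log(x[x > 0])) else -Inf)
  usable <- is.finite(lg)
  sf <- vapply(seq_len(ncol(counts)), function(j) {
    r <- log(counts[usable, j]) - lg[usable]
    r <- r[is.finite(r)]
    if (!length(r))
      stop("size factor undefined for sample '", colnames(counts)[j],
           "' (no counts on reference features)")
    exp(stats::median(r))
  }, 0)
  out <- log2(sweep(counts, 2, sf, "/") + 1)
  attr(out, "sizeFactors") <- stats::setNames(sf, colnames(counts))
  out
}

checkLmmInputs <- function(response, fixed, group) {
  if (length(unique(response)) <= 1L)
    stop("degenerate model: response is constant")
  if (length(response) != nrow(fixed) || length(response) != length(group))
    stop("response, fixed covariates and grouping must have equal length")
  mm <- stats::model.matrix(~ ., data = fixed)
  if (qr(mm)$rank < ncol(mm))
    stop("rank deficiency: singular fixed-effect design")
  invisible(TRUE)
}

#' Random-intercept linear mixed model for one feature
#'
#' Fits `response ~ fixed covariates + (1 | group)` by REML and returns
#' fixed-effect estimates with Satterthwaite t-statistics and p-values.
#' When the between-group variance is estimated at the boundary (zero), the
#' fixed-effect estimates coincide with ordinary least squares.
#'
#' @param response numeric response per sample (e.g. WLZ).
#' @param fixed data.frame of fixed-effect covariates.
#' @param group grouping factor (participant id).
#' @return data.frame (one row per fixed effect, intercept included):
#'   `term`, `estimate`, `se`, `df`, `t`, `p`; attributes `converged` and
#'   `varcomp` (random-intercept and residual variance).
#' @export
fitLmm <- function(response, fixed, group) {
  fixed <- as.data.frame(fixed)
  checkLmmInputs(response, fixed, group)
  dat <- data.frame(.y = response, fixed, .pid = factor(group),
                    check.names = FALSE)
  rhs <- paste(c(sprintf("`%s`", names(fixed)), "(1 | .pid)"), collapse = " + ")
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(stats::as.formula(paste(".y ~", rhs)), data = dat,
                   REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))))
  sm <- summary(fit)
  co <- sm$coefficients
  out <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                    se = co[, "Std. Error"], df = co[, "df"],
                    t = co[, "t value"], p = co[, "Pr(>|t|)"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  attr(out, "varcomp") <- stats::setNames(vc$vcov, vc$grp)
  attr(out, "converged") <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0
  out
}

#' Group x time interaction mixed model for one feature
#'
#' Fits `value ~ group + week + group:week + (1 | PID)`; the interaction
#' coefficient captures the difference in the feature's rate of change
#' between the two groups (e.g. treatment arms, or WLZ-response quartiles).
#'
#' @param feature_values numeric vector per sample.
#' @param meta data.frame with columns named by `group_var`, `week_var` and
#'   `id_var`.
#' @param group_var,week_var,id_var metadata column names.
#' @param ref_level optional reference (control) level of the grouping
#'   factor; coefficients then measure the other level relative to it.
#' @return data.frame as in [fitLmm()], with terms `beta1` (group main
#'   effect), `beta2` (week) and `beta3` (interaction) labelled in a
#'   `coef` column.
#' @export
fitGroupTimeModel <- function(feature_values, meta, group_var = "arm",
                              week_var = "study_week", id_var = "PID",
                              ref_level = NULL) {
  g <- droplevels(factor(meta[[group_var]]))
  if (nlevels(g) != 2L)
    stop("invalid design: grouping variable must have exactly two levels")
  if (!is.null(ref_level)) g <- stats::relevel(g, ref = ref_level)
  fixed <- data.frame(group = g, week = meta[[week_var]])
  fixed$gw <- (as.integer(fixed$group) - 1) * fixed$week
  out <- fitLmm(feature_values, fixed, meta[[id_var]])
  out$coef <- c("intercept", "beta1", "beta2", "beta3")[
    match(out$term, c("(Intercept)", paste0("group", levels(g)[2]),
                      "week", "gw"))]
  out
}

#' Zero transcript counts of MAGs with low DNA abundance
#'
#' Per sample, all transcripts of any MAG whose DNA abundance is strictly
#' below `floor` TPM in that sample are set to zero.
#'
#' @param transcript_counts transcripts x samples count matrix.
#' @param dna_tpm MAGs x samples TPM matrix (same sample columns).
#' @param transcript_map data.frame with `transcript_id` and `mag`.
#' @param floor TPM floor (strict `<`).
#' @return modified count matrix.
#' @export
zeroLowDnaTranscripts <- function(transcript_counts, dna_tpm, transcript_map,
                                  floor = 0.5) {
  tx <- rownames(transcript_counts)
  mag <- transcript_map$mag[match(tx, transcript_map$transcript_id)]
  if (any(is.na(mag)))
    stop("transcripts with unknown MAG of origin: ",
         paste(utils::head(tx[is.na(mag)], 3), collapse = ", "))
  missing_mag <- setdiff(unique(mag), rownames(dna_tpm))
  if (length(missing_mag))
    stop("MAGs absent from the DNA table: ",
         paste(utils::head(missing_mag, 3), collapse = ", "))
  if (floor <= 0) return(transcript_counts)
  low <- dna_tpm[mag, colnames(transcript_counts), drop = FALSE] < floor
  transcript_counts[low] <- 0L
  transcript_counts
}

#' Counts-per-million abundance/prevalence filter for transcripts
#'
#' Keeps a transcript iff its CPM is at least `min_cpm` in at least
#' `min_prev` of samples (both thresholds inclusive).
#'
#' @param transcript_counts transcripts x samples count matrix.
#' @param min_cpm,min_prev inclusive thresholds.
#' @return character vector of surviving transcript ids.
#' @export
cpmFilter <- function(transcript_counts, min_cpm = 5, min_prev = 0.35) {
  lib <- colSums(transcript_counts)
  if (any(lib == 0))
    stop("zero library size in sample '",
         colnames(transcript_counts)[which(lib == 0)[1]], "'")
  cpm <- sweep(transcript_counts, 2, lib, "/") * 1e6
  prev <- rowMeans(cpm >= min_cpm)
  rownames(transcript_counts)[prev >= min_prev]
}

#' TMM scaling factors
#'
#' Trimmed mean of M-values against a reference sample (log-ratio trim 0.3,
#' abundance trim 0.05), normalized to geometric mean 1.
#'
#' @param counts features x samples count matrix (>= 2 samples).
#' @return named numeric vector of per-sample factors.
#' @export
tmmFactors <- function(counts) {
  if (ncol(counts) < 2L) stop("TMM requires >= 2 samples")
  expressed <- rowSums(counts > 0)
  if (sum(expressed > 0) < 2L) {
    warning("degenerate count table (fewer than two expressed features); factors set to 1")
    return(stats::setNames(rep(1, ncol(counts)), colnames(counts)))
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = 0.3, sumTrim = 0.05)
  stats::setNames(f, colnames(counts))
}

#' Negative-binomial differential expression
#'
#' TMM-normalized negative-binomial generalized linear models with trended
#' per-gene dispersion estimation, tested by the quasi-likelihood F-test for
#' the requested coefficient of the `~ group * week` design. log-fold changes
#' are in log2 units. Non-estimable genes are reported at p = 1.
#'
#' @param counts filtered transcripts x samples count matrix.
#' @param meta sample metadata with the `group_var` and `week_var` columns.
#' @param coef which coefficient to test: `"interaction"` (group x week,
#'   the rate-of-change contrast), `"group"` or `"week"`.
#' @param group_var,week_var metadata column names.
#' @param ref_level optional reference (control) level of the group factor.
#' @return data.frame `feature`, `logFC`, `F`, `p` ordered as the input rows.
#' @export
nbDifferentialExpression <- function(counts, meta, coef = "interaction",
                                     group_var = "arm",
                                     week_var = "study_week",
                                     ref_level = NULL) {
  g <- droplevels(factor(meta[[group_var]]))
  if (!is.null(ref_level)) g <- stats::relevel(g, ref = ref_level)
  w <- meta[[week_var]]
  design <- stats::model.matrix(~ g * w)
  colnames(design) <- c("intercept", "group", "week", "interaction")
  y <- edgeR::DGEList(counts = counts)
  y <- edgeR::calcNormFactors(y, method = "TMM",
                              logratioTrim = 0.3, sumTrim = 0.05)
  y <- edgeR::estimateDisp(y, design, trend.method = "locfit")
  fit <- edgeR::glmQLFit(y, design)
  test <- edgeR::glmQLFTest(fit, coef = coef)
  tab <- test$table
  p <- tab$PValue
  p[!is.finite(p)] <- 1
  data.frame(feature = rownames(counts), logFC = tab$logFC, F = tab$F, p = p,
             stringsAsFactors = FALSE)
}

#' GSEA ranking metric
#'
#' `sign(logFC) x -log10(p)`, with p clipped at 1e-300.
#'
#' @param logFC log fold change (any base; only the sign is used).
#' @param p p-values in (0, 1\].
#' @return numeric ranking metric.
#' @export
rankingMetric <- function(logFC, p) {
  if (any(p > 1, na.rm = TRUE)) stop("p-values must be <= 1")
  if (any(p <= 0, na.rm = TRUE))
    warning("p-values at or below 0 clipped to 1e-300")
  p <- pmin(pmax(p, 1e-300), 1)
  sign(logFC) * (-log10(p))
}

#' Build a deterministic ranked list
#'
#' Orders features by decreasing metric, breaking ties by feature id so that
#' downstream enrichment analysis is deterministic.
#'
#' @param features character ids.
#' @param metric numeric ranking metric.
#' @return named numeric vector sorted in decreasing order.
#' @export
rankFeatures <- function(features, metric) {
  stopifnot(length(features) == length(metric), !anyDuplicated(features))
  ord <- order(-metric, features)
  stats::setNames(metric[ord], features[ord])
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param pvalues numeric vector in \[0, 1\] (NAs preserved).
#' @return q-values matched to the input order.
#' @export
bhAdjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' MAG abundance vs WLZ association across a cohort
#'
#' Applies the TPM abundance/prevalence filter, variance-stabilizes the
#' count layer, and fits `WLZ ~ MAG + study week + (1 | PID)` per surviving
#' MAG, with the MAG's variance-stabilized abundance standardized so that
#' coefficients are per-SD and comparable across MAGs. BH q-values are
#' appended.
#'
#' @param cohort a [SyntheticCohort-class], or a list with elements `tpm`,
#'   `counts` (MAGs x samples) and `meta`.
#' @param min_tpm,min_prev filter thresholds (see [filterMagsTpm()]).
#' @return data.frame per MAG: `feature`, `estimate`, `se`, `t`, `p`, `q`.
#' @export
magWlzAssociation <- function(cohort, min_tpm = 5, min_prev = 0.40) {
  if (methods::is(cohort, "SyntheticCohort")) {
    tpm <- dnaTpm(cohort); counts <- dnaCounts(cohort); meta <- sampleMeta(cohort)
  } else {
    tpm <- cohort$tpm; counts <- cohort$counts; meta <- cohort$meta
  }
  keep <- filterMagsTpm(tpm, min_tpm, min_prev)
  vst <- varianceStabilize(counts)[keep, , drop = FALSE]
  rows <- lapply(keep, function(m) {
    x <- as.numeric(scale(vst[m, ]))
    fit <- fitLmm(meta$WLZ, data.frame(mag = x, week = meta$study_week),
                  meta$PID)
    r <- fit[fit$term == "mag", ]
    data.frame(feature = m, estimate = r$estimate, se = r$se, t = r$t,
               p = r$p, stringsAsFactors = FALSE)
  })
  out <- bindRows(rows)
  if (!is.null(out)) out$q <- bhAdjust(out$p)
  out
}

#' Treatment-group x study-week models across MAGs
#'
#' Fits [fitGroupTimeModel()] to the variance-stabilized abundance of each
#' surviving MAG and returns the interaction (`beta3`) and group (`beta1`)
#' statistics with BH q-values.
#'
#' @inheritParams magWlzAssociation
#' @param ref_level optional reference (control) arm.
#' @return data.frame per MAG: `feature`, `beta1`, `t1`, `p1`, `beta3`,
#'   `t3`, `p3`, `q3`.
#' @export
magTreatmentModels <- function(cohort, min_tpm = 5, min_prev = 0.40,
                               ref_level = NULL) {
  if (methods::is(cohort, "SyntheticCohort")) {
    tpm <- dnaTpm(cohort); counts <- dnaCounts(cohort); meta <- sampleMeta(cohort)
  } else {
    tpm <- cohort$tpm; counts <- cohort$counts; meta <- cohort$meta
  }
  keep <- filterMagsTpm(tpm, min_tpm, min_prev)
  vst <- varianceStabilize(counts)[keep, , drop = FALSE]
  rows <- lapply(keep, function(m) {
    fit <- fitGroupTimeModel(vst[m, ], meta, ref_level = ref_level)
    b1 <- fit[which(fit$coef == "beta1"), ]
    b3 <- fit[which(fit$coef == "beta3"), ]
    data.frame(feature = m, beta1 = b1$estimate, t1 = b1$t, p1 = b1$p,
               beta3 = b3$estimate, t3 = b3$t, p3 = b3$p,
               stringsAsFactors = FALSE)
  })
  out <- bindRows(rows)
  if (!is.null(out)) out$q3 <- bhAdjust(out$p3)
  out
}
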