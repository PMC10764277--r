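# Pipeline module: orchestrates simulate -> annotate -> phenotype ->
# associate -> enrich -> pul as a reproducible end-to-end run with a strict
# config, per-stage outputs, checksums and a machine-readable report.

runConfigDefaults <- function() {
  list(
    outdir = NULL,
    seed = 1L,
    stages = c("simulate", "annotate", "phenotype", "associate", "enrich",
               "pul"),
    min_tpm = 5, min_prev_tpm = 0.40,
    min_cpm = 5, min_prev_cpm = 0.35,
    dna_floor = 0.5,
    set_floor = 10L,
    mag_set_floor = 3L,
    q_assoc = 0.05,
    q_gsea = 0.1,
    min_identity = 0.9,
    mash_cap = 0.1,
    neighbor_min_size = 4L,
    n_perm = 1000L,
    n_trees = 200L,
    pul_n_puls = 5L,
    pul_n_genomes = 6L,
    force = FALSE
  )
}

#' Pipeline run configuration
#'
#' Assembles and validates the end-to-end run configuration. Thresholds
#' default to the printed study values: MAG abundance filter above 5 TPM in
#' over 40% of samples, transcript filter at or above 5 CPM in 35%, zeroing
#' below 0.5 TPM DNA abundance, >= 10-gene pathway sets, association q < 0.05
#' and enrichment q < 0.1, 90% identity and 0.1 Mash distance caps. Unknown
#' keys are rejected before any stage runs.
#'
#' @param simulation a [simulationConfig()] (defaults to the standard study
#'   conditions with the run's seed).
#' @param ... overrides of the defaults (see Details in the vignette).
#' @return object of class `RunConfig`.
#' @export
runConfig <- function(simulation = NULL, ...) {
  cfg <- runConfigDefaults()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("validation error: unknown configuration key(s): ",
         paste(unknown, collapse = ", "))
  if (length(dots) && (is.null(names(dots)) || any(!nzchar(names(dots)))))
    stop("validation error: all configuration overrides must be named")
  cfg[names(dots)] <- dots
  bad_stage <- setdiff(cfg$stages, runConfigDefaults()$stages)
  if (length(bad_stage))
    stop("validation error: unknown stage(s): ", paste(bad_stage, collapse = ", "))
  for (k in c("min_tpm", "min_cpm", "dna_floor", "q_assoc", "q_gsea"))
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L || cfg[[k]] < 0)
      stop("validation error: '", k, "' must be a single non-negative number")
  for (k in c("min_prev_tpm", "min_prev_cpm", "min_identity"))
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0 || cfg[[k]] > 1)
      stop("validation error: '", k, "' must lie in [0, 1]")
  cfg$simulation <- if (is.null(simulation))
    simulationConfig(seed = cfg$seed) else simulation
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The optional `simulation:` block is forwarded to [simulationConfig()];
#' all remaining top-level keys are [runConfig()] overrides (unknown keys
#' are rejected).
#'
#' @param path YAML file.
#' @return a `RunConfig`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulation)) {
    sim <- do.call(simulationConfig, y$simulation)
    y$simulation <- NULL
  }
  do.call(runConfig, c(list(simulation = sim), y))
}

configHash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

# Write stage outputs unless an up-to-date manifest already covers them.
writeStage <- function(outdir, stage, files, hash, force) {
  if (is.null(outdir)) return(list(written = FALSE, checksums = NULL))
  sdir <- file.path(outdir, stage)
  manifest <- file.path(sdir, "manifest.json")
  if (!force && file.exists(manifest)) {
    old <- tryCatch(jsonlite::read_json(manifest), error = function(e) NULL)
    if (!is.null(old) && identical(old$config_hash, hash) &&
        all(file.exists(file.path(sdir, names(old$checksums %||% list())))))
      return(list(written = FALSE, skipped = TRUE,
                  checksums = unlist(old$checksums)))
  }
  dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(files)) {
    p <- file.path(sdir, nm)
    files[[nm]](p)
    paths <- c(paths, p)
  }
  sums <- tools::md5sum(paths)
  names(sums) <- basename(names(sums))
  jsonlite::write_json(list(stage = stage, config_hash = hash,
                            checksums = as.list(sums)),
                       manifest, auto_unbox = TRUE)
  list(written = TRUE, skipped = FALSE, checksums = sums)
}

#' Run the full pipeline end to end
#'
#' Executes the enabled stages in order (simulate, annotate, phenotype,
#' associate, enrich, pul) against synthetic inputs, writes per-stage outputs
#' with checksums when `outdir` is set, and returns a machine-readable report
#' including recovery metrics against the generator's ground truth. The same
#' configuration and seed always produce identical report checksums. A failed
#' run leaves an `INCOMPLETE` marker in `outdir`.
#'
#' @param config a [runConfig()].
#' @return named list (`RunReport`): resolved config hash, per-stage results,
#'   recovery metrics and output checksums.
#' @export
runEndToEnd <- function(config) {
  if (!inherits(config, "RunConfig"))
    config <- do.call(runConfig, as.list(config))
  hash <- configHash(config)
  simcfg <- config$simulation
  outdir <- config$outdir
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeLines(c("INCOMPLETE", "run in progress or failed"),
               file.path(outdir, "INCOMPLETE"))
  }
  report <- list(config_hash = hash, seed = config$seed, stages = list(),
                 metrics = list(), checksums = list())
  need <- function(stage, what, ok) {
    if (!ok) stop("stage '", stage, "': missing input (", what, ")")
  }
  st <- function(name) name %in% config$stages

  pangenome <- mags <- cohort <- annotations <- phen <- assoc <- NULL
  treat <- ranked_tx <- NULL

  # ---- simulate ----
  if (st("simulate")) {
    pangenome <- generateReferenceCollection(simcfg)
    mags <- deriveMags(pangenome, simcfg)
    cohort <- simulateCohort(pangenome, simcfg, mags)
    ws <- writeStage(outdir, "simulate", list(
      "truth_bpm.tsv" = function(p) writeCountTable(truthBpm(pangenome), p),
      "dna_tpm.tsv" = function(p) writeCountTable(dnaTpm(cohort), p),
      "meta.tsv" = function(p) writeSampleMeta(sampleMeta(cohort), p)
    ), hash, config$force)
    report$stages$simulate <- list(
      n_ref_genomes = length(refGenomes(pangenome)),
      n_mags = length(mags), n_samples = ncol(dnaTpm(cohort)),
      skipped_write = isTRUE(ws$skipped))
    report$checksums <- c(report$checksums, as.list(ws$checksums %||% list()))
  }

  # ---- annotate ----
  if (st("annotate")) {
    need("annotate", "simulated MAGs", !is.null(mags))
    ann_rows <- list()
    recovered <- total <- 0L
    for (m in mags) {
      sim <- simulateAlignmentHits(m, pangenome,
                                   seed = substreamSeed(simcfg$seed, m$mag_id))
      ann <- annotateGenome(m$genes$gene_id, sim$hits, sim$refmap)
      ann$genome <- m$mag_id
      # score recovery on genes with an in-scope true role
      truth_role <- m$genes$role[match(ann$query_id, m$genes$gene_id)]
      scored <- !is.na(truth_role)
      total <- total + sum(scored)
      recovered <- recovered + sum(scored & !is.na(ann$role) &
                                     ann$role == truth_role)
      ann_rows[[m$mag_id]] <- ann
    }
    annotations <- bindRows(ann_rows)
    ws <- writeStage(outdir, "annotate", list(
      "annotations.tsv" = function(p) writeAnnotations(annotations, p)
    ), hash, config$force)
    report$stages$annotate <- list(n_records = nrow(annotations),
                                   skipped_write = isTRUE(ws$skipped))
    report$metrics$annotation_role_recovery <-
      if (total) recovered / total else NA_real_
    report$checksums <- c(report$checksums, as.list(ws$checksums %||% list()))
  }

  # ---- phenotype ----
  if (st("phenotype")) {
    need("phenotype", "annotations", !is.null(annotations))
    need("phenotype", "pangenome", !is.null(pangenome))
    ref_roles <- rolePresenceMatrix(refGenomes(pangenome))
    ann_long <- data.frame(genome = annotations$genome,
                           role = annotations$role,
                           stringsAsFactors = FALSE)
    mag_roles <- rolePresenceMatrix(ann_long, roles = colnames(ref_roles))
    sketches <- c(
      lapply(refGenomes(pangenome), function(g)
        minhashSketch(g$genes$seq, g$genome_id)),
      lapply(mags, function(m) minhashSketch(m$genes$seq, m$mag_id)))
    groups <- assignNeighborGroups(sketches, max_distance = config$mash_cap,
                                   min_size = config$neighbor_min_size)
    phen <- predictPhenotypes(ref_roles, truthBpm(pangenome), mag_roles,
                              pathwayDefinitions(pangenome), groups,
                              n_trees = config$n_trees, seed = config$seed)
    truth <- truthBpm(pangenome)[vapply(mags, `[[`, "", "source_genome"), ,
                                 drop = FALSE]
    rownames(truth) <- names(mags)
    acc <- mean(phen$bpm == truth[rownames(phen$bpm), colnames(phen$bpm)])
    rule_acc <- mean(phen$rule_bpm == truth[rownames(phen$bpm), colnames(phen$bpm)])
    ws <- writeStage(outdir, "phenotype", list(
      "consensus_bpm.tsv" = function(p) writeCountTable(phen$bpm, p),
      "calls.tsv" = function(p) {
        utils::write.table(phen$calls, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      }
    ), hash, config$force)
    report$stages$phenotype <- list(n_calls = nrow(phen$calls),
                                    skipped_write = isTRUE(ws$skipped))
    report$metrics$consensus_phenotype_accuracy <- acc
    report$metrics$rule_phenotype_accuracy <- rule_acc
    report$checksums <- c(report$checksums, as.list(ws$checksums %||% list()))
  }

  # ---- associate ----
  if (st("associate")) {
    need("associate", "cohort", !is.null(cohort))
    assoc <- magWlzAssociation(cohort, config$min_tpm, config$min_prev_tpm)
    treat <- magTreatmentModels(cohort, config$min_tpm, config$min_prev_tpm,
                                ref_level = simcfg$arms[2])
    beta1 <- cohortTruth(cohort)$beta1
    planted <- intersect(names(beta1), assoc$feature)
    report$metrics$beta1_recovery_error <- if (length(planted))
      mean(abs(assoc$estimate[match(planted, assoc$feature)] - beta1[planted]))
      else NA_real_
    ws <- writeStage(outdir, "associate", list(
      "wlz_association.tsv" = function(p)
        utils::write.table(assoc, p, sep = "\t", quote = FALSE, row.names = FALSE),
      "treatment_models.tsv" = function(p)
        utils::write.table(treat, p, sep = "\t", quote = FALSE, row.names = FALSE)
    ), hash, config$force)
    report$stages$associate <- list(
      n_mags_tested = nrow(assoc),
      n_significant = sum(assoc$q < config$q_assoc),
      skipped_write = isTRUE(ws$skipped))
    report$checksums <- c(report$checksums, as.list(ws$checksums %||% list()))
  }

  # ---- enrich ----
  if (st("enrich")) {
    need("enrich", "association results", !is.null(assoc) && !is.null(treat))
    need("enrich", "cohort", !is.null(cohort))
    # (a) WLZ-associated MAG sets against the treatment-response ranking
    mag_sets <- list(
      wlz_positive = assoc$feature[assoc$q < config$q_assoc & assoc$estimate > 0],
      wlz_negative = assoc$feature[assoc$q < config$q_assoc & assoc$estimate < 0])
    ranked_mags <- rankFeatures(treat$feature, treat$t3)
    mag_gsea <- gseaPreranked(ranked_mags, mag_sets, n_perm = config$n_perm,
                              seed = config$seed,
                              min_size = config$mag_set_floor)
    # (b) pathway transcript sets against the differential-expression ranking
    sig_mags <- assoc$feature[assoc$q < config$q_assoc]
    tmap <- transcriptMap(cohort)
    rna <- rnaCounts(cohort)
    rna <- zeroLowDnaTranscripts(rna, dnaTpm(cohort), tmap, config$dna_floor)
    rna <- rna[rowSums(rna) > 0, , drop = FALSE]
    keep_tx <- cpmFilter(rna, config$min_cpm, config$min_prev_cpm)
    keep_tx <- intersect(keep_tx, tmap$transcript_id[tmap$mag %in% sig_mags])
    tx_gsea <- NULL
    if (length(keep_tx) >= 2) {
      de <- nbDifferentialExpression(rna[keep_tx, , drop = FALSE],
                                     sampleMeta(cohort),
                                     coef = "interaction",
                                     ref_level = simcfg$arms[2])
      ranked_tx <- rankFeatures(de$feature, rankingMetric(de$logFC, de$p))
      ann_ok <- annotations[!is.na(annotations$role), , drop = FALSE]
      sets <- list()
      defs <- pathwayDefinitions(pangenome)
      bpm_for_sets <- if (!is.null(phen)) phen$bpm else NULL
      for (p in names(defs)) {
        roles <- unique(unlist(defs[[p]]))
        member <- ann_ok$query_id[ann_ok$role %in% roles]
        if (!is.null(bpm_for_sets)) {
          flt <- filterGenesToIntactPathways(
            data.frame(genome = ann_ok$genome, gene_id = ann_ok$query_id,
                       role = ann_ok$role, stringsAsFactors = FALSE),
            bpm_for_sets, defs[p])
          member <- intersect(member, flt$gene_id)
        }
        sets[[p]] <- unique(member)
      }
      tx_gsea <- gseaPreranked(ranked_tx, sets, n_perm = config$n_perm,
                               seed = config$seed, min_size = config$set_floor)
    }
    planted_paths <- cohortTruth(cohort)$de_pathways
    planted_q <- if (!is.null(tx_gsea) && nrow(tx_gsea))
      suppressWarnings(min(tx_gsea$q[tx_gsea$set %in% planted_paths],
                           na.rm = TRUE)) else NA_real_
    if (!is.finite(planted_q)) planted_q <- NA_real_
    ws <- writeStage(outdir, "enrich", list(
      "mag_gsea.tsv" = function(p)
        utils::write.table(mag_gsea, p, sep = "\t", quote = FALSE,
                           row.names = FALSE),
      "pathway_gsea.tsv" = function(p)
        utils::write.table(tx_gsea %||% data.frame(), p, sep = "\t",
                           quote = FALSE, row.names = FALSE)
    ), hash, config$force)
    report$stages$enrich <- list(
      n_mag_sets = nrow(mag_gsea),
      n_pathway_sets = if (is.null(tx_gsea)) 0L else nrow(tx_gsea),
      skipped_write = isTRUE(ws$skipped))
    wp <- mag_gsea[mag_gsea$set == "wlz_positive", ]
    report$metrics$wlz_positive_set_NES <-
      if (nrow(wp) && !wp$skipped) wp$NES else NA_real_
    report$metrics$wlz_positive_set_q <-
      if (nrow(wp) && !wp$skipped) wp$q else NA_real_
    report$metrics$planted_pathway_min_q <- planted_q
    report$checksums <- c(report$checksums, as.list(ws$checksums %||% list()))
  }

  # ---- pul ----
  if (st("pul")) {
    study <- simulatePulStudy(n_puls = config$pul_n_puls,
                              n_genomes = config$pul_n_genomes,
                              seed = substreamSeed(config$seed, "pulstage"))
    prof <- conservationMatrix(study$ref_puls, study$queries,
                               min_identity = config$min_identity)
    codes <- c(conserved = 1, structurally_distinct = 0.5, absent = 0)
    truth_prof <- matrix(codes[study$categories],
                         nrow(study$categories), ncol(study$categories),
                         dimnames = dimnames(study$categories))
    acc <- mean(prof[rownames(truth_prof), colnames(truth_prof)] == truth_prof)
    corr <- correlateProfilesWithAssociation(prof, study$beta1)
    ws <- writeStage(outdir, "pul", list(
      "conservation_matrix.tsv" = function(p) writeCountTable(prof, p)
    ), hash, config$force)
    report$stages$pul <- list(n_puls = length(study$ref_puls),
                              n_genomes = length(study$queries),
                              skipped_write = isTRUE(ws$skipped))
    report$metrics$pul_category_accuracy <- acc
    report$metrics$pul_association_r <- corr$r
    report$checksums <- c(report$checksums, as.list(ws$checksums %||% list()))
  }

  if (!is.null(outdir)) {
    rp <- file.path(outdir, "report.json")
    jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    report$checksums$report.json <- unname(tools::md5sum(rp))
    unlink(file.path(outdir, "INCOMPLETE"))
  }
  report
}
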