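# Generator contracts: determinism, truth consistency, degradation
# statistics, cohort structure, PUL variant planting.

test_that("reference collection is deterministic and truth-consistent", {
  cfg <- smallConfig(seed = 42)
  pg1 <- generateReferenceCollection(cfg)
  pg2 <- generateReferenceCollection(cfg)
  expect_identical(refGenomes(pg1), refGenomes(pg2))
  expect_identical(truthBpm(pg1), truthBpm(pg2))

  # truth BPM is recomputable from emitted gene content (independent oracle)
  expect_identical(unname(truthBpm(pg1)),
                   unname(naiveBpm(refGenomes(pg1), pathwayDefinitions(pg1))))

  # prevalences lie inside the configured band
  prev <- colMeans(truthBpm(pg1))
  expect_true(all(prev >= cfg$prevalence_range[1] - 1e-9))
  expect_true(all(prev <= cfg$prevalence_range[2] + 1e-9))

  # every pathway role exists in at least one genome (validity invariant)
  expect_true(validObject(pg1))
})

test_that("invalid simulation configs are rejected", {
  expect_error(simulationConfig(n_ref_genomes = 0), "n_ref_genomes")
  expect_error(simulationConfig(n_phenotypes = 0), "n_phenotypes")
  expect_error(simulationConfig(mag_completeness = 1.2), "fractions")
  expect_error(simulationConfig(timepoints = c(0, 4, 4)), "increasing")
})

test_that("genome degradation matches its sampling model", {
  cfg <- smallConfig(seed = 3)
  pg <- generateReferenceCollection(cfg)
  g <- refGenomes(pg)[[1]]

  # identity case: completeness 1, no contamination, no fragmentation
  mag <- degradeGenomeToMag(g, 1, 0, 0, seed = 1)
  expect_identical(sort(mag$genes$gene_id), sort(g$genes$gene_id))
  expect_true(all(mag$genes$origin == "retained"))

  expect_error(degradeGenomeToMag(g, 1.5, 0, 0), "invalid parameter")

  # binomial oracle on a large synthetic genome over 50 seeds
  big <- list(genome_id = "BIG", genes = data.frame(
    gene_id = sprintf("BIG_%04d", 1:1000), role = NA_character_,
    family = "F", seq = strrep("ACDEFGHIK", 10), stringsAsFactors = FALSE))
  kept <- vapply(1:50, function(s)
    nrow(degradeGenomeToMag(big, 0.9, 0, 0, seed = s)$genes), 0)
  ci <- qbinom(c(0.005, 0.995), 1000, 0.9)
  expect_true(all(kept >= ci[1] & kept <= ci[2]))
  # mean retention close to completeness (binomial test at alpha = 0.01)
  bt <- binom.test(sum(kept), 50 * 1000, p = 0.9)
  expect_gt(bt$p.value, 0.01)

  # fragmentation rate: fraction of retained genes emitted as two fragments
  frag <- vapply(1:50, function(s) {
    m <- degradeGenomeToMag(big, 1, 0, 0.1, seed = s)$genes
    sum(m$origin == "fragment") / 2 / 1000
  }, 0)
  expect_gt(mean(frag), 0.08)
  expect_lt(mean(frag), 0.12)

  # contaminants carry provenance
  magc <- degradeGenomeToMag(g, 0.9, 0.2, 0, seed = 2,
                             donors = refGenomes(pg))
  cont <- magc$genes[magc$genes$origin == "contaminant", ]
  expect_true(all(cont$source_genome != g$genome_id))
})

test_that("cohort has the declared longitudinal structure", {
  cfg <- smallConfig(seed = 9)
  pg <- generateReferenceCollection(cfg)
  co <- simulateCohort(pg, cfg)
  meta <- sampleMeta(co)
  # each participant appears exactly len(timepoints) times
  expect_true(all(table(meta$PID) == length(cfg$timepoints)))
  expect_identical(colnames(dnaTpm(co)), meta$sample_id)
  expect_identical(colnames(rnaCounts(co)), meta$sample_id)
  cnt <- rnaCounts(co)
  expect_true(all(cnt >= 0 & cnt == round(cnt)))
  expect_true(all(dnaTpm(co) >= 0))
  expect_error(simulateCohort(pg, smallConfig(n_participants = 0)),
               "participants")
  # fixed seed -> identical cohort
  co2 <- simulateCohort(pg, cfg)
  expect_identical(dnaTpm(co), dnaTpm(co2))
  expect_identical(rnaCounts(co), rnaCounts(co2))
})

test_that("a planted abundance-WLZ effect dominates the association ranking", {
  hits <- vapply(1:10, function(s) {
    cfg <- simulationConfig(n_ref_genomes = 15L, n_phenotypes = 6L,
                            n_mags = 12L, n_participants = 25L,
                            timepoints = c(0, 4, 8, 12),
                            effect_sizes = list(beta1 = c(0.5), beta3 = numeric(0)),
                            seed = s)
    pg <- generateReferenceCollection(cfg)
    co <- simulateCohort(pg, cfg)
    a <- magWlzAssociation(co)
    a$feature[which.max(abs(a$t))] == names(cohortTruth(co)$beta1)
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("PUL variant planting honours its mode contracts", {
  ref <- makeReferencePul("PULX", "REF", n_cazymes = 3, seed = 5)
  expect_null(plantPulVariants(ref, "absent", seed = 1))
  expect_error(plantPulVariants(ref, "weird", seed = 1), "invalid parameter")

  v <- plantPulVariants(ref, "conserved", seed = 2)
  expect_identical(v$orfs$role_class, pulOrfs(ref)$role_class)
  ids <- mapply(proteinIdentity, pulOrfs(ref)$seq, v$orfs$seq)
  expect_true(all(ids > 0.9))
  expect_true(is.na(v$defect))

  # structurally distinct: exactly one defect, recorded in provenance
  for (s in 1:6) {
    vd <- plantPulVariants(ref, "structurally_distinct", seed = s)
    expect_false(is.na(vd$defect))
    expect_match(vd$defect, "deleted|fragmented|inserted")
    delta <- nrow(vd$orfs) - nrow(pulOrfs(ref))
    expect_true(delta %in% c(-1L, 1L))  # one deletion, or one split/insertion
  }
})
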