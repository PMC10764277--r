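# Phenotype prediction: pathway rules, random forest, MinHash neighbour
# groups, consensus reconciliation, pathway-intactness gene filter.

refFixture <- function() {
  # phenotype AND = role1 & role2; all four role combinations represented
  roles <- matrix(c(1, 1, 1, 0, 0, 1, 0, 0,
                    1, 1, 0, 1, 1, 0, 0, 0), ncol = 2,
                  dimnames = list(sprintf("R%d", 1:8), c("role1", "role2")))
  bpm <- matrix(as.integer(roles[, 1] & roles[, 2]), ncol = 1,
                dimnames = list(rownames(roles), "AND"))
  list(roles = roles, bpm = bpm,
       defs = list(AND = list(c("role1", "role2"))))
}

test_that("pathway rules learn an AND over the full truth table", {
  fx <- refFixture()
  rules <- trainPathwayRules(fx$roles, fx$bpm, fx$defs)
  expect_equal(rules$AND$type, "tree")
  expect_equal(rules$AND$training_accuracy, 1)
  grid <- as.matrix(expand.grid(role1 = 0:1, role2 = 0:1))
  rownames(grid) <- sprintf("g%d", 1:4)
  pred <- predictRules(grid, rules)
  expect_equal(unname(pred[, "AND"]), as.integer(grid[, 1] & grid[, 2]))

  # dropout of a required role is a designed false negative
  mag <- matrix(c(1, 0), 1, dimnames = list("m", c("role1", "role2")))
  expect_equal(unname(predictRules(mag, rules)[, "AND"]), 0L)

  # missing roles are treated as absent genes
  empty <- matrix(0L, 1, 1, dimnames = list("m", "unrelated"))
  expect_equal(unname(predictRules(empty, rules)[, "AND"]), 0L)

  # constant phenotype flagged
  cb <- matrix(1L, 8, 1, dimnames = list(rownames(fx$roles), "CONST"))
  rc <- trainPathwayRules(fx$roles, cb)
  expect_equal(rc$CONST$type, "constant")
  expect_equal(unname(predictRules(empty, rc)[, "CONST"]), 1L)
})

test_that("random-forest predictions are accurate, reproducible and reported", {
  cfg <- smallConfig(seed = 14, background_role_rate = 0)  # noiseless, separable
  pg <- generateReferenceCollection(cfg)
  roles <- rolePresenceMatrix(refGenomes(pg))
  bpm <- truthBpm(pg)
  ml1 <- predictMl(roles, bpm, roles, seed = 3, loo = TRUE)
  ml2 <- predictMl(roles, bpm, roles, seed = 3, loo = FALSE)
  expect_identical(ml1$predictions, ml2$predictions)
  # noiseless separable references: leave-one-out accuracy 100%
  expect_true(all(ml1$report$loo_accuracy == 1))
  # resubstitution recovers truth
  expect_equal(unname(ml1$predictions), unname(bpm))
  # chosen hyperparameters recorded
  expect_true(all(c("mtry", "nodesize", "oob_error") %in% names(ml1$report)))
})

test_that("mash distance follows the MinHash formula and its caps", {
  s1 <- minhashSketch("MKVLITGGAGFIGSNLVRALLAQGH", "a", k = 5, sketch_size = 10)
  expect_equal(mashDistance(s1, s1), 0)

  mk <- function(h, id) methods::new("MinHashSketch", genomeId = id,
                                     k = 21L, sketchSize = 1000L,
                                     hashes = as.numeric(sort(h)))
  # shared 900 of bottom-1000 in the union -> j = 0.9
  a <- mk(1:1000, "a"); b <- mk(101:1100, "b")
  expect_equal(mashDistance(a, b), -(1 / 21) * log(1.8 / 1.9), tolerance = 1e-12)
  expect_equal(mashDistance(a, b), mashDistance(b, a))
  # disjoint sketches capped at 1
  expect_equal(mashDistance(mk(1:100, "a"), mk(1001:1100, "b")), 1)
  bad <- methods::new("MinHashSketch", genomeId = "c", k = 15L,
                      sketchSize = 1000L, hashes = as.numeric(1:10))
  expect_error(mashDistance(a, bad), "invalid comparison")
})

test_that("neighbour grouping enforces the distance cap and minimum size", {
  mk <- function(h, id) methods::new("MinHashSketch", genomeId = id,
                                     k = 21L, sketchSize = 100L,
                                     hashes = as.numeric(sort(h)))
  base <- 1:100
  near <- lapply(1:5, function(i) mk(c(base[1:95], 200 + i * 5 + 1:5), paste0("r", i)))
  far <- mk(5001:5100, "lone")
  sk <- c(setNames(near, paste0("r", 1:5)), list(lone = far))
  gr <- assignNeighborGroups(sk, max_distance = 0.1, min_size = 4)
  expect_equal(length(gr$groups), 1)
  expect_setequal(gr$groups[[1]], paste0("r", 1:5))
  # a group of 3 dissolves
  gr3 <- assignNeighborGroups(sk[c(1, 2, 3, 6)], max_distance = 0.1, min_size = 4)
  expect_equal(length(gr3$groups), 0)
})

test_that("neighbour vote adopts the closest pattern on required roles only", {
  roles <- rbind(ra = c(1, 1, 0, 0, 0),   # exact match on required p1, p2
                 rb = c(0, 0, 1, 1, 1),   # exact match on irrelevant x1-x3
                 rc = c(0, 1, 0, 1, 0))
  colnames(roles) <- c("p1", "p2", "x1", "x2", "x3")
  bpm <- matrix(c(1, 0, 0), 3, 1, dimnames = list(rownames(roles), "PH"))
  defs <- list(PH = list(c("p1", "p2")))
  # full-profile Hamming would pick rb (distance 2 vs 3); the required-role
  # restriction picks ra (distance 0 vs 2)
  mag <- c(p1 = 1, p2 = 1, x1 = 1, x2 = 1, x3 = 1)
  v <- predictNeighbor(mag, c("ra", "rb", "rc"), roles, bpm, defs)
  expect_equal(unname(v["PH"]), 1L)
  # equidistant references with conflicting phenotypes abstain
  roles2 <- matrix(c(1, 0, 0, 1), 2, 2,
                   dimnames = list(c("ra", "rb"), c("p1", "p2")))
  bpm2 <- matrix(c(1, 0), 2, 1, dimnames = list(c("ra", "rb"), "PH"))
  v2 <- predictNeighbor(c(p1 = 1, p2 = 1), c("ra", "rb"), roles2, bpm2, defs)
  expect_true(is.na(v2["PH"]))
  # no reference genomes in the group -> abstain
  v3 <- predictNeighbor(mag, "nobody", roles, bpm, defs)
  expect_true(is.na(v3["PH"]))
})

test_that("consensus reconciliation follows the declared scheme", {
  expect_equal(consensusCall(1, 1, 1), list(consensus = 1L, confidence = "high"))
  expect_equal(consensusCall(0, 0, 0), list(consensus = 0L, confidence = "high"))
  expect_equal(consensusCall(0, 1, 0), list(consensus = 0L, confidence = "medium"))
  expect_equal(consensusCall(1, 0, 1), list(consensus = 1L, confidence = "medium"))
  # false-negative rescue: positive neighbour match overrides dropout zeros
  expect_equal(consensusCall(0, 0, 1), list(consensus = 1L, confidence = "medium"))
  # the rescue is one-directional: a negative neighbour vote cannot veto
  expect_equal(consensusCall(1, 1, 0), list(consensus = 1L, confidence = "medium"))
  expect_equal(consensusCall(1, 1, NA), list(consensus = 1L, confidence = "medium"))
  # irreconcilable: defaults to the machine-learning vote at low confidence
  expect_equal(consensusCall(0, 1, NA), list(consensus = 1L, confidence = "low"))
  expect_equal(consensusCall(1, 0, NA), list(consensus = 0L, confidence = "low"))
  expect_error(consensusCall(NA, NA, NA), "undefined call")
})

test_that("complete MAGs are perfectly recovered by all strategies", {
  cfg <- smallConfig(seed = 77, mag_completeness = 1, mag_contamination = 0,
                     fragmentation_rate = 0)
  pg <- generateReferenceCollection(cfg)
  mags <- deriveMags(pg, cfg)
  roles <- rolePresenceMatrix(refGenomes(pg))
  mag_roles <- rolePresenceMatrix(mags, roles = colnames(roles))
  ph <- predictPhenotypes(roles, truthBpm(pg), mag_roles,
                          pathwayDefinitions(pg), groups = NULL, seed = 2)
  truth <- truthBpm(pg)[vapply(mags, `[[`, "", "source_genome"), ]
  rownames(truth) <- names(mags)
  expect_identical(unname(ph$rule_bpm), unname(truth))
  expect_identical(unname(ph$ml_bpm), unname(truth))
  expect_identical(unname(ph$bpm), unname(truth))
  expect_true(all(ph$calls$confidence %in% c("high", "medium", "low")))
})

test_that("consensus rescues dropout false negatives at 90% completeness", {
  accs <- t(vapply(1:5, function(s) {
    cfg <- smallConfig(seed = 100 + s)
    pg <- generateReferenceCollection(cfg)
    mags <- deriveMags(pg, cfg)
    roles <- rolePresenceMatrix(refGenomes(pg))
    mag_roles <- rolePresenceMatrix(mags, roles = colnames(roles))
    sk <- c(lapply(refGenomes(pg), function(g) minhashSketch(g$genes$seq, g$genome_id)),
            lapply(mags, function(m) minhashSketch(m$genes$seq, m$mag_id)))
    gr <- assignNeighborGroups(sk)
    ph <- predictPhenotypes(roles, truthBpm(pg), mag_roles,
                            pathwayDefinitions(pg), gr, seed = s)
    truth <- truthBpm(pg)[vapply(mags, `[[`, "", "source_genome"), ]
    c(consensus = mean(ph$bpm == truth), rule = mean(ph$rule_bpm == truth))
  }, c(consensus = 0, rule = 0)))
  expect_gt(mean(accs[, "consensus"]), mean(accs[, "rule"]))
  expect_gte(mean(accs[, "consensus"]), 0.9)
})

test_that("gene filtering keeps only roles of intact pathways", {
  ann <- data.frame(genome = c("g1", "g1", "g1", "g2"),
                    gene_id = c("a", "b", "c", "d"),
                    role = c("r1", "r2", NA, "r1"),
                    stringsAsFactors = FALSE)
  bpm <- matrix(c(1, 0, 0, 1), 2, 2,
                dimnames = list(c("g1", "g2"), c("P1", "P2")))
  defs <- list(P1 = list("r1"), P2 = list("r2"))
  out <- filterGenesToIntactPathways(ann, bpm, defs)
  # g1: P1 intact -> r1 kept, P2 absent -> r2 dropped; unannotated dropped
  # g2: P2 intact but r1 only in P1 (absent) -> dropped
  expect_identical(out$gene_id, "a")
})
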