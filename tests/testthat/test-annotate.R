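# Annotation workflow: top-hit selection, domain splitting, KDE identity
# threshold, majority rule with outgroup veto, end-to-end recovery.

mkHits <- function(n, bitscore, sseqid = sprintf("s%03d", seq_len(n)),
                   pident = 90, qstart = 1L, qend = 100L) {
  data.frame(qseqid = "q1", sseqid = sseqid, pident = pident,
             length = qend - qstart + 1L, mismatch = 0L, gapopen = 0L,
             qstart = qstart, qend = qend, sstart = 1L, send = 100L,
             evalue = 1e-20, bitscore = bitscore, stringsAsFactors = FALSE)
}

test_that("top-hit selection is bitscore-ranked and tie-deterministic", {
  h <- mkHits(60, bitscore = 60:1)
  top <- selectTopHits(h, 50)
  expect_equal(nrow(top), 50)
  expect_equal(top$bitscore, sort(h$bitscore, decreasing = TRUE)[1:50])

  h10 <- mkHits(10, bitscore = 1:10)
  expect_equal(nrow(selectTopHits(h10, 50)), 10)

  # two equal bitscores straddling the boundary: lexicographic subject wins
  h <- mkHits(51, bitscore = c(51:2, 2), sseqid = c(sprintf("s%03d", 1:50), "aaa"))
  top <- selectTopHits(h, 50)
  expect_true("aaa" %in% top$sseqid)
  expect_false("s050" %in% top$sseqid)
})

test_that("domain splitting recovers planted boundaries and drops short domains", {
  set.seed(1)
  # 10 hits spanning 1-100, 10 spanning 150-250
  h <- rbind(
    mkHits(10, bitscore = 50, qstart = pmax(1L, 1L + sample(-2:2, 10, TRUE)),
           qend = 100L + sample(-2:2, 10, TRUE)),
    mkHits(10, bitscore = 50, qstart = 150L + sample(-2:2, 10, TRUE),
           qend = 250L + sample(-2:2, 10, TRUE)))
  sp <- splitQueryIntoDomains(h)
  expect_equal(nrow(sp$domains), 2)
  expect_lte(abs(sp$domains$start[1] - 1), 5)
  expect_lte(abs(sp$domains$end[1] - 100), 5)
  expect_lte(abs(sp$domains$start[2] - 150), 5)
  expect_lte(abs(sp$domains$end[2] - 250), 5)
  # attribution covers every attributed hit midpoint
  mid <- (h$qstart + h$qend) / 2
  d <- sp$hits$domain
  expect_true(all(mid >= sp$domains$start[d] - 5 & mid <= sp$domains$end[d] + 5))

  # all hits over one region -> single consensus domain
  one <- splitQueryIntoDomains(mkHits(8, bitscore = 40))
  expect_equal(nrow(one$domains), 1)

  # candidate domain of length 30 is discarded
  short <- splitQueryIntoDomains(mkHits(6, bitscore = 10, qstart = 1L, qend = 30L))
  expect_equal(nrow(short$domains), 0)
})

test_that("KDE identity threshold separates planted bimodal mixtures", {
  expect_error(identityThreshold(numeric(0)), "invalid input")
  expect_equal(identityThreshold(rep(90, 50)), 0)

  for (s in 1:5) {
    set.seed(s)
    lo <- pmin(100, pmax(0, rnorm(50, 55, 3)))
    hi <- pmin(100, pmax(0, rnorm(50, 95, 2)))
    thr <- identityThreshold(c(lo, hi))
    expect_gt(thr, 65)
    expect_lt(thr, 90)
    expect_gte(mean(lo < thr), 0.95)
  }
})

test_that("domain annotation applies plurality, tie and outgroup-veto rules", {
  dh <- data.frame(pident = c(95, 94, 93), bitscore = c(100, 90, 80),
                   role = c("A", "A", "B"), is_outgroup = FALSE)
  expect_equal(annotateDomain(dh, 0)$role, "A")

  # outgroup plurality vetoes annotation
  og <- data.frame(pident = 95, bitscore = c(100, 90, 80),
                   role = c(NA, NA, "B"), is_outgroup = c(TRUE, TRUE, FALSE))
  expect_true(is.na(annotateDomain(og, 0)$role))

  # tied votes resolved by summed bitscore
  tie <- data.frame(pident = 95, bitscore = c(120, 80, 100, 50),
                    role = c("A", "A", "B", "B"), is_outgroup = FALSE)
  expect_equal(annotateDomain(tie, 0)$role, "A")

  # exact tie on votes and bitscore abstains
  tie2 <- data.frame(pident = 95, bitscore = c(100, 100),
                     role = c("A", "B"), is_outgroup = FALSE)
  expect_true(is.na(annotateDomain(tie2, 0)$role))

  # threshold removing all hits abstains
  expect_true(is.na(annotateDomain(dh, 99)$role))
})

test_that("genome annotation recovers planted roles and is order-invariant", {
  fx <- simulateAnnotationFixture(n_proteins = 30, n_outgroup_queries = 4,
                                  seed = 8)
  ann <- annotateGenome(fx$queries, fx$hits, fx$refmap)
  truth <- fx$truth

  # outgroup-only queries annotated as none
  og_q <- truth$query_id[is.na(truth$role)]
  expect_true(all(is.na(ann$role[ann$query_id %in% og_q])))

  # planted-role recovery on two-domain proteins
  tt <- truth[!is.na(truth$role), ]
  got <- mapply(function(q, s, e, r) {
    rows <- ann[ann$query_id == q & !is.na(ann$domain_start), ]
    ov <- pmin(rows$domain_end, e) - pmax(rows$domain_start, s)
    any(ov > 0 & !is.na(rows$role) & rows$role == r)
  }, tt$query_id, tt$start, tt$end, tt$role)
  expect_gte(mean(got), 0.95)

  # permutation invariance wrt hit order
  perm <- fx$hits[sample(nrow(fx$hits)), ]
  ann2 <- annotateGenome(fx$queries, perm, fx$refmap)
  expect_identical(ann, ann2)

  # empty hits table: all roles none, no crash
  e <- annotateGenome(c("qa", "qb"), fx$hits[0, ], fx$refmap)
  expect_equal(nrow(e), 2)
  expect_true(all(is.na(e$role)))
})

test_that("thresholding never removes the plurality role on noiseless fixtures", {
  for (s in 1:5) {
    fx <- simulateAnnotationFixture(n_proteins = 10, n_outgroup_queries = 0,
                                    identity_separation = 30, seed = s)
    ann <- annotateGenome(fx$queries, fx$hits, fx$refmap)
    tt <- fx$truth
    got <- mapply(function(q, s1, e1, r) {
      rows <- ann[ann$query_id == q & !is.na(ann$domain_start), ]
      ov <- pmin(rows$domain_end, e1) - pmax(rows$domain_start, s1)
      any(ov > 0 & !is.na(rows$role) & rows$role == r)
    }, tt$query_id, tt$start, tt$end, tt$role)
    expect_equal(mean(got), 1)
  }
})
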