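# Pre-ranked GSEA: running-sum oracle equivalence, permutation p-values
# against exhaustive enumeration, skipping rules, leading-edge extraction.

rankedFixture <- function(n, seed) {
  set.seed(seed)
  rankFeatures(sprintf("f%03d", 1:n), rnorm(n))
}

test_that("enrichment score matches a brute-force running-sum oracle exactly", {
  for (s in 1:20) {
    n <- sample(20:100, 1)
    ranked <- rankedFixture(n, s)
    members <- sample(names(ranked), sample(3:10, 1))
    es <- enrichmentScore(ranked, members)
    oracle <- naiveEnrichmentScore(ranked, members)
    expect_equal(es$ES, oracle$ES, tolerance = 1e-12)
    expect_equal(es$peak, oracle$peak)
  }
})

test_that("enrichment score agrees with an independent GSEA implementation", {
  ranked <- rankedFixture(80, 99)
  members <- sample(names(ranked), 8)
  es <- enrichmentScore(ranked, members)
  ref <- fgsea::calcGseaStat(unname(ranked),
                             which(names(ranked) %in% members),
                             gseaParam = 1)
  expect_equal(es$ES, ref, tolerance = 1e-12)
})

test_that("a set packed at the top of the list attains the analytic maximum", {
  ranked <- rankFeatures(sprintf("f%02d", 1:50), seq(50, 1))
  members <- names(ranked)[1:5]
  es <- enrichmentScore(ranked, members)
  expect_gt(es$ES, 0)
  expect_equal(es$ES, 1, tolerance = 1e-12)  # all hits before any decrement
  expect_equal(es$peak, 5)
})

test_that("degenerate and undersized sets are skipped, not errored", {
  ranked <- rankedFixture(30, 3)
  expect_null(enrichmentScore(ranked, names(ranked)))        # whole universe
  expect_null(enrichmentScore(ranked, c("nope1", "nope2")))  # no intersection
  res <- gseaPreranked(ranked, list(tiny = names(ranked)[1:9],
                                    ok = names(ranked)[1:12]),
                       n_perm = 200, seed = 1, min_size = 10)
  expect_true(res$skipped[res$set == "tiny"])
  expect_match(res$reason[res$set == "tiny"], "below minimum")
  expect_false(res$skipped[res$set == "ok"])
})

test_that("permutation p-values match exhaustive enumeration on a toy universe", {
  ranked <- rankFeatures(letters[1:8], c(3, 2.5, 2, 1, -0.5, -1, -2, -3))
  members <- c("a", "b", "d")
  es <- enrichmentScore(ranked, members)
  # exact exceedance probability over all C(8,3) member sets
  combos <- combn(8, 3)
  null_es <- apply(combos, 2, function(ix)
    naiveEnrichmentScore(ranked, names(ranked)[ix])$ES)
  p_enum <- mean(sign(null_es) == sign(es$ES) &
                   abs(null_es) >= abs(es$ES) - 1e-12)
  n_perm <- 4000
  res <- gseaPreranked(ranked, list(S = members), n_perm = n_perm, seed = 5,
                       min_size = 3)
  # expected permutation estimate, with binomial 99% Monte Carlo band
  p_expect <- (1 + n_perm * p_enum) / (1 + n_perm)
  se <- sqrt(p_enum * (1 - p_enum) / n_perm)
  expect_lt(abs(res$p - p_expect), 2.58 * se + 1e-12)
  expect_equal(sign(res$NES), sign(res$ES))
})

test_that("fixed seeds reproduce and positive scaling preserves ranks and edges", {
  ranked <- rankedFixture(60, 12)
  sets <- list(A = names(ranked)[c(1:6, 30:33)], B = names(ranked)[20:31])
  r1 <- gseaPreranked(ranked, sets, n_perm = 300, seed = 9, min_size = 5)
  r2 <- gseaPreranked(ranked, sets, n_perm = 300, seed = 9, min_size = 5)
  expect_identical(r1, r2)
  scaled <- ranked * 7.5
  r3 <- gseaPreranked(scaled, sets, n_perm = 300, seed = 9, min_size = 5)
  expect_identical(r1$leading_edge, r3$leading_edge)
  expect_identical(rank(r1$ES), rank(r3$ES))
})

test_that("leading edge contains exactly the members driving the extremum", {
  ranked <- rankFeatures(sprintf("f%02d", 1:20), seq(10, -9))
  members <- c("f01", "f02", "f03", "f15")
  es <- enrichmentScore(ranked, members)
  le <- leadingEdge(ranked, members, es$ES, es$peak)
  expect_true(all(le %in% members))
  expect_true(all(match(le, names(ranked)) <= es$peak))
  # fully top-ranked set: leading edge is the whole set
  m2 <- c("f01", "f02", "f03")
  es2 <- enrichmentScore(ranked, m2)
  expect_setequal(leadingEdge(ranked, m2, es2$ES, es2$peak), m2)
  # negative enrichment: members at or after the minimum
  m3 <- c("f18", "f19", "f20")
  es3 <- enrichmentScore(ranked, m3)
  expect_lt(es3$ES, 0)
  le3 <- leadingEdge(ranked, m3, es3$ES, es3$peak)
  expect_true(all(match(le3, names(ranked)) >= es3$peak))
})

test_that("null rankings produce calibrated permutation p-values", {
  set.seed(31)
  ranked <- rankFeatures(sprintf("f%03d", 1:80), rnorm(80))
  sets <- lapply(1:100, function(i) sample(names(ranked), 12))
  names(sets) <- sprintf("S%03d", 1:100)
  res <- gseaPreranked(ranked, sets, n_perm = 400, seed = 17, min_size = 10)
  frac <- mean(res$p < 0.05)
  expect_lt(abs(frac - 0.05), 0.07)  # generous Monte Carlo band at n = 100
})

test_that("GMT round-trip preserves sets", {
  sets <- list(A = c("x", "y", "z"), B = c("p", "q"))
  path <- tempfile(fileext = ".gmt")
  writeGmt(sets, path)
  expect_identical(readGmt(path), sets)
})
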