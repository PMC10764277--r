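# Association modelling: filters, variance stabilization, mixed models,
# transcript preprocessing, NB differential expression, ranking metric, BH.

test_that("TPM filter applies strict abundance and prevalence thresholds", {
  m <- rbind(a = c(6, 6, 0), b = c(6, 0, 0), c = c(5, 5, 5), d = c(5.1, 5.1, 0))
  colnames(m) <- paste0("s", 1:3)
  expect_setequal(filterMagsTpm(m), c("a", "d"))
  expect_identical(filterMagsTpm(m[0, , drop = FALSE]), character(0))
})

test_that("variance stabilization is finite, monotone and flattening", {
  set.seed(4)
  counts <- matrix(rnbinom(200 * 8, mu = rep(exp(rnorm(200, 4, 1.5)), 8),
                           size = 2), 200, 8,
                   dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:8)))
  v <- varianceStabilize(counts)
  expect_true(all(is.finite(v)))
  # within-sample monotonicity
  for (j in 1:8) {
    o <- order(counts[, j])
    expect_true(all(diff(v[o, j]) >= -1e-12))
  }
  # flattens the group-SD vs group-mean slope relative to log2(x + 1)
  slope <- function(x) {
    mu <- rowMeans(x); s <- apply(x, 1, sd)
    bins <- cut(rank(mu), 10)
    coef(lm(tapply(s, bins, mean) ~ tapply(mu, bins, mean)))[2]
  }
  expect_lt(abs(slope(v)), abs(slope(log2(counts + 1))) + 1e-9)
  # all-zero sample errors with the sample name
  bad <- counts; bad[, 3] <- 0
  expect_error(varianceStabilize(bad), "s3")
})

test_that("the mixed model collapses to OLS without between-participant variance", {
  set.seed(11)
  n <- 120
  pid <- rep(sprintf("p%02d", 1:24), each = 5)
  x <- rnorm(n); wk <- rep(0:4, 24)
  e <- rnorm(n, 0, 0.3)
  e <- e - ave(e, pid)  # exactly zero between-participant variance
  y <- 0.3 + 0.5 * x + 0.02 * wk + e
  fit <- fitLmm(y, data.frame(mag = x, week = wk), pid)
  ols <- olsFit(y, data.frame(mag = x, week = wk))
  expect_lt(max(abs(fit$estimate - ols)), 1e-6)
  expect_error(fitLmm(rep(1, n), data.frame(x = x), pid), "constant")
  expect_error(fitLmm(y, data.frame(a = x, b = 2 * x), pid), "rank")
})

test_that("planted fixed effects are recovered without bias", {
  ests <- vapply(1:30, function(s) {
    set.seed(s)
    pid <- rep(sprintf("p%02d", 1:40), each = 5)
    wk <- rep(c(0, 2, 4, 8, 12), 40)
    x <- rnorm(200)
    y <- -2.5 + rnorm(40, 0, 0.3)[match(pid, unique(pid))] +
      0.5 * x + 0.015 * wk + rnorm(200, 0, 0.25)
    fit <- fitLmm(y, data.frame(mag = x, week = wk), pid)
    fit$estimate[fit$term == "mag"]
  }, 0)
  expect_lt(abs(mean(ests) - 0.5), 0.05)
})

test_that("group-time interaction model exposes a sign-symmetric rate contrast", {
  set.seed(7)
  pid <- rep(sprintf("p%02d", 1:30), each = 4)
  meta <- data.frame(PID = pid, study_week = rep(c(0, 4, 8, 12), 30),
                     arm = rep(c("A", "B"), each = 60))
  y <- 0.1 * meta$study_week * (meta$arm == "B") + rnorm(120, 0, 0.5) +
    rnorm(30, 0, 0.3)[match(pid, unique(pid))]
  f1 <- fitGroupTimeModel(y, meta)
  b3 <- f1$estimate[which(f1$coef == "beta3")]
  expect_gt(b3, 0.05)
  # swapping group labels negates the interaction estimate
  meta2 <- meta; meta2$arm <- ifelse(meta$arm == "A", "B", "A")
  f2 <- fitGroupTimeModel(y, meta2)
  expect_equal(f2$estimate[which(f2$coef == "beta3")], -b3, tolerance = 1e-6)
  meta3 <- meta; meta3$arm <- "A"
  expect_error(fitGroupTimeModel(y, meta3), "two levels")
  # planted divergent slopes recover the right sign
  signs <- vapply(1:20, function(s) {
    set.seed(100 + s)
    yy <- 0.08 * meta$study_week * (meta$arm == "B") + rnorm(120, 0, 0.4)
    ff <- fitGroupTimeModel(yy, meta)
    sign(ff$estimate[which(ff$coef == "beta3")])
  }, 0)
  expect_gte(mean(signs > 0), 0.95)
})

test_that("DNA-conditioned transcript zeroing follows the strict floor", {
  rna <- matrix(5L, 4, 2, dimnames = list(paste0("t", 1:4), c("s1", "s2")))
  dna <- rbind(m1 = c(0.4, 0.6), m2 = c(0.5, 10))
  colnames(dna) <- c("s1", "s2")
  map <- data.frame(transcript_id = paste0("t", 1:4),
                    mag = c("m1", "m1", "m2", "m2"))
  z <- zeroLowDnaTranscripts(rna, dna, map, floor = 0.5)
  expect_equal(unname(z[, "s1"]), c(0L, 0L, 5L, 5L))  # m1 < 0.5; m2 == 0.5 kept
  expect_equal(unname(z[, "s2"]), rep(5L, 4))
  expect_identical(zeroLowDnaTranscripts(rna, dna, map, floor = 0), rna)
  bad <- map; bad$mag[1] <- NA
  expect_error(zeroLowDnaTranscripts(rna, dna, data.frame(
    transcript_id = "x", mag = "m1"), 0.5), "unknown MAG")
})

test_that("CPM filter thresholds are inclusive and match hand computation", {
  # hand-worked 10 x 6 toy table: libraries are column sums; survivor rule
  # cpm >= 5 in >= 35% of samples (>= 2.1 -> >= 3 of 6 samples)
  set.seed(2)
  m <- matrix(rpois(60, 40), 10, 6,
              dimnames = list(sprintf("t%02d", 1:10), sprintf("s%d", 1:6)))
  lib <- colSums(m)
  cpm_hand <- t(t(m) / lib) * 1e6
  expected <- rownames(m)[rowSums(cpm_hand >= 5) / 6 >= 0.35]
  expect_identical(cpmFilter(m, 5, 0.35), expected)

  # exact boundary: 5 CPM in exactly 35% of samples is kept (inclusive)
  n_s <- 20
  tx <- c(rep(5, 7), rep(0, 13))            # libraries sum to exactly 1e6
  base <- rbind(t = tx, pad = 1e6 - tx)
  colnames(base) <- paste0("s", 1:n_s)
  expect_true("t" %in% cpmFilter(base, min_cpm = 5, min_prev = 0.35))
  expect_false("t" %in% cpmFilter(base, min_cpm = 5, min_prev = 0.36))
  # 4.9 CPM everywhere is dropped
  low <- rbind(t = rep(49, 6), pad = rep(1e7 - 49, 6))
  colnames(low) <- paste0("s", 1:6)
  expect_false("t" %in% cpmFilter(low, 5, 0.35))
  z <- m; z[, 2] <- 0
  expect_error(cpmFilter(z), "s2")
})

test_that("TMM factors are calibrated and scale-equivariant", {
  m <- matrix(rep(c(100L, 200L, 50L, 400L), 3), 4, 3,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  f <- tmmFactors(m)
  expect_equal(unname(f), rep(1, 3), tolerance = 1e-9)
  # doubled library, same composition: normalized expression is equalized
  m2 <- cbind(s1 = m[, 1], s2 = 2L * m[, 1])
  f2 <- tmmFactors(m2)
  expect_equal(prod(f2), 1, tolerance = 1e-9)
  eff <- t(t(m2) / (colSums(m2) * f2)) * 1e6
  expect_equal(eff[, 1], eff[, 2], tolerance = 1e-9)
  expect_warning(tmmFactors(matrix(c(5L, 0L, 6L, 0L), 2, 2)), "degenerate")
})

test_that("NB differential expression recovers planted fold changes with valid nulls", {
  set.seed(33)
  ns <- 40
  meta <- data.frame(arm = rep(c("A", "B"), each = ns / 2),
                     study_week = rep(c(0, 12), ns / 2))
  # planted genes: 4-fold group difference
  mu0 <- exp(rnorm(200, 5, 1))
  mu <- outer(mu0, rep(1, ns))
  mu[, meta$arm == "B"] <- mu[, meta$arm == "B"] * 4
  planted <- matrix(rnbinom(200 * ns, mu = mu, size = 4), 200, ns,
                    dimnames = list(sprintf("p%03d", 1:200), sprintf("s%d", 1:ns)))
  null <- matrix(rnbinom(2000 * ns, mu = rep(exp(rnorm(2000, 5, 1)), ns),
                         size = 4), 2000, ns,
                 dimnames = list(sprintf("n%04d", 1:2000), sprintf("s%d", 1:ns)))
  de_p <- nbDifferentialExpression(rbind(planted, null)[, ], meta,
                                   coef = "group")
  lfc <- de_p$logFC[match(sprintf("p%03d", 1:200), de_p$feature)]
  expect_gt(median(abs(lfc)), 1.5)
  expect_lt(median(abs(lfc)), 2.5)
  # null p-values approximately uniform
  de_n <- nbDifferentialExpression(null, meta, coef = "group")
  ks <- suppressWarnings(ks.test(de_n$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("ranking metric and BH adjustment follow their formulas", {
  expect_equal(rankingMetric(2, 0.001), 3)
  expect_equal(rankingMetric(-1, 0.01), -2)
  expect_equal(rankingMetric(5, 1), 0)
  expect_warning(rankingMetric(1, 0), "clipped")
  expect_error(rankingMetric(1, 2), "<= 1")

  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bhAdjust(0.2), 0.2)
  p <- c(0.04, 0.001, 0.9, 0.3)
  expect_equal(bhAdjust(p)[order(p)], bhAdjust(sort(p)))
  expect_true(all(bhAdjust(p) >= p))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")

  r <- rankFeatures(c("b", "a", "c"), c(1, 1, 5))
  expect_identical(names(r), c("c", "a", "b"))  # tie broken by id
})
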