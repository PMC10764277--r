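# Independent oracles used across tests. Deliberately naive implementations
# that share no code with the package internals they check.

# Brute-force GSEA running sum: walk the list position by position.
naiveEnrichmentScore <- function(ranked, members, weight = 1) {
  hit <- names(ranked) %in% members
  m <- sum(hit)
  N <- length(ranked)
  denom <- sum(abs(ranked[hit])^weight)
  run <- 0
  best <- 0
  peak <- 0L
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) abs(unname(ranked[i]))^weight / denom
           else -1 / (N - m)
    if (abs(run) > abs(best)) {
      best <- run
      peak <- i
    }
  }
  list(ES = best, peak = peak)
}

# Closed-form OLS slope/intercept fit for comparison with a boundary LMM fit.
olsFit <- function(y, X) {
  as.numeric(stats::coef(stats::lm(y ~ ., data = as.data.frame(X))))
}

# Recompute a binary phenotype matrix from gene content and pathway variants.
naiveBpm <- function(genomes, defs) {
  out <- sapply(names(defs), function(p) {
    sapply(genomes, function(g) {
      roles <- g$genes$role
      as.integer(any(sapply(defs[[p]], function(v) all(v %in% roles))))
    })
  })
  rownames(out) <- names(genomes)
  out
}

# Small toy ORF table builder for PUL tests.
toyOrfs <- function(classes, genome = "T", contig = "c1",
                    seqs = NULL, strand = "+") {
  n <- length(classes)
  if (is.null(seqs))
    seqs <- vapply(seq_len(n), function(i)
      paste(rep(LETTERS[(i %% 20) + 1], 60), collapse = ""), "")
  data.frame(orf_id = sprintf("%s_o%02d", genome, seq_len(n)),
             contig = contig, pos = seq_len(n),
             strand = rep(strand, length.out = n),
             role_class = classes, family = NA_character_,
             seq = seqs, stringsAsFactors = FALSE)
}

smallConfig <- function(seed = 1, ...) {
  simulationConfig(n_ref_genomes = 20L, n_phenotypes = 8L, n_mags = 10L,
                   n_participants = 16L, timepoints = c(0, 4, 8, 12),
                   effect_sizes = list(beta1 = c(0.5, -0.5),
                                       beta3 = c(0.08, -0.08)),
                   seed = seed, ...)
}
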