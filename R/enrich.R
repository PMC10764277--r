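# Enrichment module: pre-ranked GSEA with a weighted Kolmogorov-Smirnov
# running sum, gene-label permutation null, sign-stratified normalized
# enrichment scores, BH FDR and leading-edge extraction.

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list; at set members the running sum rises by
#' `|metric|^weight` (normalized over the member weights), at non-members it
#' falls by `1/(N - m)`. The enrichment score is the extremum of the running
#' sum; the peak index is recorded for leading-edge extraction.
#'
#' @param ranked named numeric vector sorted in decreasing metric order
#'   (see [rankFeatures()]).
#' @param members character vector of set member ids.
#' @param weight exponent on the metric (1 = classic weighted statistic).
#' @return list: `ES`, `peak` (index of the extremum), `running` (the full
#'   running sum), `size` (members in the universe). `NULL` (degenerate skip)
#'   when the intersection is empty or the set spans the whole universe.
#' @export
enrichmentScore <- function(ranked, members, weight = 1) {
  N <- length(ranked)
  hit <- names(ranked) %in% members
  m <- sum(hit)
  if (m == 0L || m == N) return(NULL)
  w <- abs(ranked)^weight
  denom <- sum(w[hit])
  inc <- rep(-1 / (N - m), N)
  inc[hit] <- if (denom > 0) w[hit] / denom else 1 / m
  running <- cumsum(inc)
  peak <- which.max(abs(running))
  list(ES = running[peak], peak = peak, running = running, size = m)
}

# Fast ES for a set given by positions in the ranked list (no running vector).
# Candidate extrema occur at each hit and immediately before each hit.
esFromPositions <- function(pos, w, N, denom_all = NULL) {
  pos <- sort(pos)
  m <- length(pos)
  wh <- w[pos]
  denom <- sum(wh)
  hitcum <- if (denom > 0) cumsum(wh) / denom else seq_len(m) / m
  missrate <- 1 / (N - m)
  at_hit <- hitcum - (pos - seq_len(m)) * missrate
  before_hit <- c(0, hitcum[-m]) - (pos - seq_len(m)) * missrate
  cand <- c(at_hit, before_hit, -(N - pos[m]) * missrate + 1 * 0 + at_hit[m])
  cand[which.max(abs(cand))]
}

#' Pre-ranked gene set enrichment analysis
#'
#' Computes the enrichment score of each set against the ranked list, builds
#' a null from random same-size member sets, and reports sign-stratified
#' permutation p-values `(1 + #{same-sign |ES_null| >= |ES|}) / (1 + n_perm)`,
#' normalized enrichment scores `NES = ES / mean(|same-sign null ES|)`, BH
#' q-values across the scored sets, and leading-edge members. Sets smaller
#' than `min_size` after intersection with the universe (or spanning it
#' entirely) are skipped with a reason.
#'
#' @param ranked named numeric vector sorted decreasing ([rankFeatures()]).
#' @param sets named list of member-id character vectors.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed (fixed seed gives identical results).
#' @param min_size minimum usable set size after intersection.
#' @param weight metric exponent.
#' @return data.frame: `set`, `size`, `ES`, `NES`, `p`, `q`,
#'   `leading_edge` (comma-separated ids), `skipped`, `reason`.
#' @export
gseaPreranked <- function(ranked, sets, n_perm = 10000L, seed = 1L,
                          min_size = 10L, weight = 1) {
  stopifnot(n_perm >= 100L)
  N <- length(ranked)
  w <- abs(ranked)^weight
  scored <- list()
  rows <- list()
  for (s in names(sets)) {
    inter <- intersect(sets[[s]], names(ranked))
    if (length(inter) < min_size || length(inter) >= N) {
      reason <- if (length(inter) >= N) "set spans the whole universe"
                else sprintf("set size %d below minimum %d", length(inter), min_size)
      rows[[s]] <- data.frame(set = s, size = length(inter), ES = NA_real_,
                              NES = NA_real_, p = NA_real_, q = NA_real_,
                              leading_edge = "", skipped = TRUE,
                              reason = reason, stringsAsFactors = FALSE)
      next
    }
    es <- enrichmentScore(ranked, inter, weight)
    scored[[s]] <- list(inter = inter, es = es)
  }
  if (!length(scored)) {
    out <- bindRows(rows)
    if (is.null(out)) out <- data.frame()
    warning("all gene sets were skipped")
    return(out)
  }

  sizes <- sort(unique(vapply(scored, function(x) length(x$inter), 0L)))
  nulls <- withSubstream(seed, "gsea-null", {
    out <- list()
    for (sz in sizes) {
      out[[as.character(sz)]] <- vapply(seq_len(n_perm), function(i)
        esFromPositions(sample.int(N, sz), w, N), 0)
    }
    out
  })

  for (s in names(scored)) {
    es <- scored[[s]]$es
    null_es <- nulls[[as.character(length(scored[[s]]$inter))]]
    same <- null_es[sign(null_es) == sign(es$ES)]
    # ties with the observed score count as exceedances (within float noise)
    p <- (1 + sum(abs(same) >= abs(es$ES) - 1e-12)) / (1 + n_perm)
    nes <- if (length(same)) es$ES / mean(abs(same)) else NA_real_
    le <- leadingEdge(ranked, scored[[s]]$inter, es$ES, es$peak)
    rows[[s]] <- data.frame(set = s, size = es$size, ES = es$ES, NES = nes,
                            p = p, q = NA_real_,
                            leading_edge = paste(le, collapse = ","),
                            skipped = FALSE, reason = "",
                            stringsAsFactors = FALSE)
  }
  out <- bindRows(rows[names(sets)[names(sets) %in% names(rows)]])
  out$q[!out$skipped] <- bhAdjust(out$p[!out$skipped])
  out
}

#' Leading-edge members of an enrichment result
#'
#' For a positively enriched set, the members ranked at or before the peak of
#' the running sum; for a negatively enriched set, the members at or after
#' the minimum. These are the features responsible for the enrichment.
#'
#' @param ranked named numeric vector sorted decreasing.
#' @param members set member ids.
#' @param ES enrichment score.
#' @param peak index of the running-sum extremum.
#' @return character vector of leading-edge ids (subset of `members`).
#' @export
leadingEdge <- function(ranked, members, ES, peak) {
  idx <- which(names(ranked) %in% members)
  if (ES >= 0) names(ranked)[idx[idx <= peak]]
  else names(ranked)[idx[idx >= peak]]
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (set name, description, then member ids, tab-separated).
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (l in lines[nzchar(lines)]) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    out[[f[1]]] <- f[-(1:2)]
  }
  out
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(sets), function(s)
    paste(c(s, "na", sets[[s]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
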