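# Annotation module: assign functional roles to query proteins from tabular
# alignment hits. Multidomain proteins are handled by clustering alignment
# start/end coordinates into candidate domain boundaries; per-domain hit sets
# are then filtered by a kernel-density identity threshold and annotated by
# majority rule, with high-identity outgroup hits vetoing annotation.

#' Select the top alignment hits of one query
#'
#' Keeps at most `k` hits ranked by descending bitscore, with ties broken by
#' lexicographic subject identifier so the selection is deterministic.
#'
#' @param hits data.frame of alignment hits for a single query (outfmt-6
#'   dialect columns; requires `bitscore` and `sseqid`).
#' @param k maximum number of hits retained.
#' @return the selected rows, sorted by descending bitscore.
#' @export
selectTopHits <- function(hits, k = 50L) {
  if (is.null(hits) || nrow(hits) == 0) return(hits)
  ord <- order(-hits$bitscore, hits$sseqid)
  hits[ord[seq_len(min(k, nrow(hits)))], , drop = FALSE]
}

# Density-based 1-D clustering: sorted values are chained while consecutive
# gaps are <= eps; clusters below min_n are noise. Returns rounded means.
cluster1d <- function(x, eps, min_n) {
  if (!length(x)) return(numeric(0))
  xs <- sort(x)
  grp <- cumsum(c(1, diff(xs) > eps))
  centers <- vapply(split(xs, grp), function(v)
    if (length(v) >= min_n) round(mean(v)) else NA_real_, 0)
  sort(unname(centers[!is.na(centers)]))
}

#' Split a query protein into candidate domains from its hit coordinates
#'
#' Alignment start and end coordinates are clustered independently
#' (density-based 1-D clustering, gap threshold `cluster_eps`, minimum cluster
#' size `min_cluster`); rounded cluster means become candidate boundaries.
#' Each start is paired with the last end before the next start. Hits are
#' attributed to the domain they overlap most, and domains shorter than
#' `min_domain_len` residues are discarded.
#'
#' @param hits data.frame of hits for one query (`qstart`, `qend`, 1-based
#'   inclusive).
#' @param cluster_eps maximum within-cluster coordinate gap (residues).
#' @param min_cluster minimum hits per boundary cluster.
#' @param min_domain_len minimum retained domain length (residues).
#' @return list with `domains` (data.frame `start`, `end`, `length`) and
#'   `hits` (the input with a `domain` index column; `NA` for hits whose
#'   domain was discarded).
#' @export
splitQueryIntoDomains <- function(hits, cluster_eps = 10, min_cluster = 2L,
                                  min_domain_len = 35L) {
  stopifnot(nrow(hits) >= 1)
  S <- cluster1d(hits$qstart, cluster_eps, min_cluster)
  E <- cluster1d(hits$qend, cluster_eps, min_cluster)
  if (!length(S)) S <- min(hits$qstart)
  if (!length(E)) E <- max(hits$qend)
  doms <- data.frame(start = numeric(0), end = numeric(0))
  for (i in seq_along(S)) {
    nxt <- if (i < length(S)) S[i + 1] else Inf
    cand <- E[E >= S[i] & E < nxt]
    e <- if (length(cand)) max(cand)
         else if (any(E >= S[i])) min(E[E >= S[i]])
         else max(hits$qend)
    doms <- rbind(doms, data.frame(start = S[i], end = e))
  }
  doms <- unique(doms[doms$end >= doms$start, , drop = FALSE])

  # attribute each hit to the domain it overlaps most (ties: first domain)
  ov <- sapply(seq_len(nrow(doms)), function(d)
    pmax(0, pmin(hits$qend, doms$end[d]) - pmax(hits$qstart, doms$start[d]) + 1))
  ov <- matrix(ov, nrow = nrow(hits))
  assign <- apply(ov, 1, function(r) if (max(r) > 0) which.max(r) else NA_integer_)

  doms$length <- doms$end - doms$start + 1
  keep <- which(doms$length >= min_domain_len &
                  seq_len(nrow(doms)) %in% assign)
  remap <- match(assign, keep)
  hits$domain <- remap
  doms <- doms[keep, , drop = FALSE]
  rownames(doms) <- NULL
  list(domains = doms, hits = hits)
}

#' Identity threshold from the kernel density of hit identities
#'
#' Fits a Gaussian kernel density (Silverman's rule-of-thumb bandwidth, 512
#' grid points over \[0, 100\]) to the percent-identity distribution and
#' returns the highest-identity interior local minimum, used to discard
#' low-confidence hits. Unimodal or degenerate inputs return 0 (keep all).
#'
#' @param identities numeric vector of percent identities in \[0, 100\].
#' @return threshold in \[0, 100\].
#' @export
identityThreshold <- function(identities) {
  if (is.null(identities) || length(identities) == 0)
    stop("invalid input: no identity values supplied")
  if (any(identities < 0 | identities > 100))
    stop("invalid input: identities must lie in [0, 100]")
  if (length(identities) < 3 || stats::sd(identities) == 0) return(0)
  d <- stats::density(identities, bw = "nrd0", n = 512, from = 0, to = 100)
  y <- d$y
  n <- length(y)
  locmin <- which(y[2:(n - 1)] < y[1:(n - 2)] & y[2:(n - 1)] <= y[3:n]) + 1
  # a genuine between-mode minimum lies inside the data range at
  # non-negligible density; numerical wiggles in the underflowed tails do not
  locmin <- locmin[y[locmin] > 1e-6 * max(y) &
                     d$x[locmin] > min(identities) &
                     d$x[locmin] < max(identities)]
  # and it must be a prominent valley: sampling wiggles on a unimodal
  # density have minima nearly as high as their flanking peaks, while a true
  # between-mode valley sits well below the smaller peak even at small n
  prominent <- vapply(locmin, function(i) {
    y[i] <= 0.7 * min(max(y[1:i]), max(y[i:n]))
  }, TRUE)
  locmin <- locmin[prominent]
  if (!length(locmin)) return(0)
  max(d$x[locmin])
}

#' Annotate one domain by majority rule with outgroup veto
#'
#' Hits below the identity threshold are removed; the surviving hits vote by
#' reference role (outgroup hits vote as a bloc against annotation). The
#' plurality role wins; a tied vote is resolved by the larger summed bitscore
#' and abstains (`NA` role) if still tied; an outgroup plurality vetoes the
#' annotation.
#'
#' @param domain_hits hits attributed to one domain, joined with the reference
#'   map (columns `pident`, `bitscore`, `role`, `is_outgroup`).
#' @param threshold identity threshold from [identityThreshold()].
#' @return one-row data.frame: `role`, `votes`, `n_hits`, `sum_bitscore`.
#' @export
annotateDomain <- function(domain_hits, threshold = 0) {
  surv <- domain_hits[domain_hits$pident >= threshold, , drop = FALSE]
  abstain <- data.frame(role = NA_character_, votes = 0L,
                        n_hits = nrow(surv), sum_bitscore = 0,
                        stringsAsFactors = FALSE)
  if (!nrow(surv)) return(abstain)
  ballot <- ifelse(surv$is_outgroup, ".outgroup", surv$role)
  ballot[is.na(ballot)] <- ".outgroup"
  votes <- table(ballot)
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1) {
    bs <- vapply(top, function(r) sum(surv$bitscore[ballot == r]), 0)
    top <- top[bs == max(bs)]
    if (length(top) > 1) return(abstain)
  }
  if (top == ".outgroup") {
    abstain$votes <- as.integer(votes[[top]])
    return(abstain)
  }
  data.frame(role = top, votes = as.integer(votes[[top]]),
             n_hits = nrow(surv),
             sum_bitscore = sum(surv$bitscore[ballot == top]),
             stringsAsFactors = FALSE)
}

#' Annotate all proteins of a genome from an alignment-hit table
#'
#' Per query: top-`k` hits by bitscore, domain splitting from coordinate
#' clusters, a per-domain kernel-density identity threshold, then
#' majority-rule role assignment with outgroup veto. Whole genes and gene
#' fragments are treated alike (one record per query and domain). Queries
#' without hits are emitted with an `NA` role. The procedure is invariant to
#' the input order of hits.
#'
#' @param queries character vector of query identifiers, or a data.frame with
#'   a `query_id` column (ensures hit-less queries are reported).
#' @param hits outfmt-6 style data.frame for all queries.
#' @param refmap data.frame `subject_id`, `role`, `is_outgroup`.
#' @param k top hits retained per query.
#' @param cluster_eps,min_cluster,min_domain_len see [splitQueryIntoDomains()].
#' @return data.frame: `query_id`, `domain_start`, `domain_end`, `role`,
#'   `votes`, `n_hits`.
#' @export
annotateGenome <- function(queries, hits, refmap, k = 50L,
                           cluster_eps = 10, min_cluster = 2L,
                           min_domain_len = 35L) {
  qids <- if (is.data.frame(queries)) queries$query_id else queries
  if (nrow(hits)) {
    missing_subj <- setdiff(hits$sseqid, refmap$subject_id)
    if (length(missing_subj))
      stop("hits reference subjects absent from the reference map: ",
           paste(utils::head(missing_subj, 3), collapse = ", "))
    hits$role <- refmap$role[match(hits$sseqid, refmap$subject_id)]
    hits$is_outgroup <- refmap$is_outgroup[match(hits$sseqid, refmap$subject_id)]
  }
  out <- list()
  for (q in sort(unique(qids))) {
    h <- hits[hits$qseqid == q, , drop = FALSE]
    if (!nrow(h)) {
      out[[length(out) + 1L]] <- data.frame(
        query_id = q, domain_start = NA_real_, domain_end = NA_real_,
        role = NA_character_, votes = 0L, n_hits = 0L,
        stringsAsFactors = FALSE)
      next
    }
    h <- selectTopHits(h, k)
    sp <- splitQueryIntoDomains(h, cluster_eps, min_cluster, min_domain_len)
    if (!nrow(sp$domains)) {
      out[[length(out) + 1L]] <- data.frame(
        query_id = q, domain_start = NA_real_, domain_end = NA_real_,
        role = NA_character_, votes = 0L, n_hits = nrow(h),
        stringsAsFactors = FALSE)
      next
    }
    for (d in seq_len(nrow(sp$domains))) {
      dh <- sp$hits[!is.na(sp$hits$domain) & sp$hits$domain == d, , drop = FALSE]
      thr <- identityThreshold(dh$pident)
      ann <- annotateDomain(dh, thr)
      out[[length(out) + 1L]] <- data.frame(
        query_id = q,
        domain_start = sp$domains$start[d], domain_end = sp$domains$end[d],
        role = ann$role, votes = ann$votes, n_hits = ann$n_hits,
        stringsAsFactors = FALSE)
    }
  }
  bindRows(out)
}

#' Read a BLAST/DIAMOND tabular hits file (outfmt 6)
#'
#' @param path TSV with the 12 standard columns (qseqid sseqid pident length
#'   mismatch gapopen qstart qend sstart send evalue bitscore), no header.
#' @return data.frame with typed columns.
#' @export
readAlignmentHits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  h <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = cols,
                         colClasses = c("character", "character", "numeric",
                                        "integer", "integer", "integer",
                                        "integer", "integer", "integer",
                                        "integer", "numeric", "numeric"))
  h
}

#' Read a subject-to-role sidecar map
#'
#' @param path TSV with header `subject_id`, `role`, `is_outgroup` (role empty
#'   or `NA` for outgroup proteins).
#' @return data.frame.
#' @export
readRoleMap <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, na.strings = c("", "NA"))
  m$is_outgroup <- as.logical(m$is_outgroup)
  m
}

#' Write an annotation table
#'
#' @param annotations result of [annotateGenome()].
#' @param path output TSV path.
#' @export
writeAnnotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
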