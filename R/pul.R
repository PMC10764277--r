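# PUL module: detect polysaccharide utilization loci from role-annotated ORF
# tables, classify PUL conservation between genomes from pairwise protein
# identities and synteny, encode conservation profiles {1, 0.5, 0}, and relate
# profile distance to growth-association coefficients.

pulComponentClasses <- c("SusC", "SusD", "CAZyme", "regulator")

#' Percent identity of two proteins by global alignment
#'
#' Needleman-Wunsch global alignment with unit match score, zero mismatch
#' score and small gap penalties; identity = matched columns / full
#' end-to-end alignment length (terminal and internal gaps both count in the
#' denominator, so a fragment can never reach high identity against a
#' full-length protein).
#'
#' @param a,b amino-acid sequences (character).
#' @return identity in \[0, 1\].
#' @export
proteinIdentity <- function(a, b) {
  if (!nchar(a) || !nchar(b)) return(0)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = identitySubMatrix(),
    gapOpening = 2, gapExtension = 1, type = "global")
  Biostrings::nmatch(aln) /
    max(Biostrings::nchar(aln), nchar(a), nchar(b))
}

identitySubMatrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      alph <- c(Biostrings::AA_STANDARD, "X", "*")
      m <- matrix(0, length(alph), length(alph), dimnames = list(alph, alph))
      diag(m) <- 1
      cache <<- m
    }
    cache
  }
})

#' Detect PULs in a role-annotated ORF table
#'
#' Seeds at each adjacent SusC/SusD pair and extends in both directions over
#' CAZyme and regulator ORFs, tolerating at most `max_gap` intervening
#' unrelated (`other`) ORFs; overlapping seeds on one contig are merged.
#'
#' @param orfs data.frame of ORFs (`orf_id`, `contig`, `pos`, `strand`,
#'   `role_class`, `family`, `seq`).
#' @param max_gap maximum run of `other` ORFs bridged during extension.
#' @param genome genome label for the emitted PULs.
#' @return list of [Pul-class] objects (empty when no SusC/SusD pair exists).
#' @export
detectPuls <- function(orfs, max_gap = 2L, genome = "genome") {
  out <- list()
  for (ctg in unique(orfs$contig)) {
    tab <- orfs[orfs$contig == ctg, , drop = FALSE]
    tab <- tab[order(tab$pos), , drop = FALSE]
    rc <- tab$role_class
    n <- nrow(tab)
    pair_at <- which((rc[-n] == "SusC" & rc[-1] == "SusD") |
                       (rc[-n] == "SusD" & rc[-1] == "SusC"))
    if (!length(pair_at)) next
    spans <- lapply(pair_at, function(i) {
      lo <- i; hi <- i + 1L
      # extend right
      j <- hi + 1L; gap <- 0L
      while (j <= n && gap <= max_gap) {
        if (rc[j] %in% pulComponentClasses) {
          hi <- j; gap <- 0L
        } else gap <- gap + 1L
        j <- j + 1L
      }
      # extend left
      j <- lo - 1L; gap <- 0L
      while (j >= 1L && gap <= max_gap) {
        if (rc[j] %in% pulComponentClasses) {
          lo <- j; gap <- 0L
        } else gap <- gap + 1L
        j <- j - 1L
      }
      c(lo, hi)
    })
    # merge overlapping spans
    spans <- spans[order(vapply(spans, `[`, 0, 1))]
    merged <- list(spans[[1]])
    for (sp in spans[-1]) {
      last <- merged[[length(merged)]]
      if (sp[1] <= last[2]) merged[[length(merged)]] <- c(last[1], max(last[2], sp[2]))
      else merged[[length(merged) + 1L]] <- sp
    }
    for (sp in merged) {
      sub <- tab[sp[1]:sp[2], , drop = FALSE]
      out[[length(out) + 1L]] <- methods::new(
        "Pul", id = sprintf("%s_%s_PUL%02d", genome, ctg, length(out) + 1L),
        genome = genome, orfs = sub)
    }
  }
  out
}

#' Classify the conservation of a reference PUL in a query genome
#'
#' Anchored homologue search: each component ORF of the reference PUL (SusC,
#' SusD, CAZymes, regulators) is matched to its best-identity query ORF. The
#' locus is `conserved` when every component has a >90%-identity match and the
#' matches are organized identically (consecutive, order preserved; a
#' strand-flipped, order-reversed block counts as identical organization);
#' `structurally_distinct` when a homologous block exists (>= 2 anchored
#' components) but components are missing or fragmented or extra component
#' ORFs are inserted; `absent` otherwise.
#'
#' @param ref_pul a [Pul-class].
#' @param query_orfs ORF data.frame of the query genome (may be empty).
#' @param min_identity identity required for an ORF match (default 0.9,
#'   exclusive).
#' @param fragment_coverage combined length fraction of a reference ORF that
#'   two or more partial matches must reach to call it fragmented rather than
#'   missing.
#' @return list (`ConservationCall`): `pul`, `genome`, `category`, `evidence`
#'   (per-ORF identities and defect notes).
#' @export
classifyConservation <- function(ref_pul, query_orfs, min_identity = 0.9,
                                 fragment_coverage = 0.8) {
  ref <- pulOrfs(ref_pul)
  comp <- ref[ref$role_class %in% pulComponentClasses, , drop = FALSE]
  genome <- if (!is.null(query_orfs) && nrow(query_orfs))
    query_orfs$genome %||% "query" else "query"
  call <- function(category, evidence)
    list(pul = ref_pul@id, genome = if (length(genome) > 1) genome[1] else genome,
         category = category, evidence = evidence)
  if (is.null(query_orfs) || nrow(query_orfs) == 0)
    return(call("absent", list(note = "empty query genome")))

  # candidate query ORFs per reference component: best global identity
  best_id <- numeric(nrow(comp))
  best_at <- rep(NA_integer_, nrow(comp))
  qlen <- nchar(query_orfs$seq)
  for (i in seq_len(nrow(comp))) {
    rlen <- nchar(comp$seq[i])
    cand <- which(qlen >= 0.3 * rlen & qlen <= 3 * rlen)
    if (!length(cand)) next
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(query_orfs$seq[cand]),
      Biostrings::AAString(comp$seq[i]),
      substitutionMatrix = identitySubMatrix(),
      gapOpening = 2, gapExtension = 1, type = "global")
    ids <- Biostrings::nmatch(aln) /
      pmax(Biostrings::nchar(aln), qlen[cand], rlen)
    best_id[i] <- max(ids)
    if (max(ids) > min_identity) best_at[i] <- cand[which.max(ids)]
  }
  matched <- !is.na(best_at)
  evidence <- list(identities = stats::setNames(round(best_id, 3), comp$orf_id))

  if (sum(matched) < 2L)
    return(call("absent", c(evidence, list(note = "no homologous block"))))

  pos <- query_orfs$pos[best_at[matched]]
  dpos <- diff(pos)
  ordered <- all(dpos > 0) || all(dpos < 0)
  span <- query_orfs[query_orfs$pos >= min(pos) & query_orfs$pos <= max(pos), ,
                     drop = FALSE]
  extra <- span[span$role_class %in% pulComponentClasses &
                  !span$pos %in% pos, , drop = FALSE]
  consecutive <- length(pos) == nrow(span[span$role_class %in%
                                            pulComponentClasses, , drop = FALSE])

  if (all(matched) && ordered && nrow(extra) == 0 && consecutive)
    return(call("conserved", evidence))

  defects <- character(0)
  for (i in which(!matched)) {
    # fragmented: >= 2 query ORFs jointly covering most of the reference ORF
    rseq <- comp$seq[i]; rlen <- nchar(rseq)
    frag_cand <- which(qlen >= 0.2 * rlen & qlen < 0.95 * rlen)
    frag_len <- 0
    nfrag <- 0L
    for (j in frag_cand) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(query_orfs$seq[j]), Biostrings::AAString(rseq),
        substitutionMatrix = identitySubMatrix(),
        gapOpening = 2, gapExtension = 1, type = "local")
      if (Biostrings::nmatch(aln) > min_identity * qlen[j]) {
        frag_len <- frag_len + qlen[j]
        nfrag <- nfrag + 1L
      }
    }
    defects <- c(defects, sprintf(
      "%s (%s) %s", comp$orf_id[i], comp$role_class[i],
      if (nfrag >= 2L && frag_len >= fragment_coverage * rlen) "fragmented"
      else "missing"))
  }
  if (nrow(extra))
    defects <- c(defects, sprintf("extra ORF %s inserted", extra$orf_id))
  if (!ordered) defects <- c(defects, "component order rearranged")
  call("structurally_distinct", c(evidence, list(defects = defects)))
}

#' Encode conservation calls as a numeric profile
#'
#' `conserved` -> 1, `structurally_distinct` -> 0.5, `absent`/not conserved
#' -> 0, ordered by the reference PUL order.
#'
#' @param calls list of conservation calls ([classifyConservation()] results)
#'   covering each reference PUL exactly once.
#' @param pul_order character vector of reference PUL ids (defaults to the
#'   order encountered).
#' @return named numeric vector with values in \{1, 0.5, 0\}.
#' @export
encodeProfile <- function(calls, pul_order = NULL) {
  ids <- vapply(calls, `[[`, "", "pul")
  if (is.null(pul_order)) pul_order <- ids
  if (anyDuplicated(ids))
    stop("multiple calls for reference PUL ", ids[duplicated(ids)][1])
  missing <- setdiff(pul_order, ids)
  if (length(missing))
    stop("missing conservation call for reference PUL ", missing[1])
  codes <- c(conserved = 1, structurally_distinct = 0.5, absent = 0)
  cats <- vapply(calls, `[[`, "", "category")
  stats::setNames(codes[cats], ids)[pul_order]
}

#' Conservation profile matrix for a panel of genomes
#'
#' Classifies every reference PUL in every query genome and encodes the
#' calls; the reference genome itself is included as an all-conserved row.
#'
#' @param ref_puls list of reference [Pul-class] objects.
#' @param query_orfs named list of per-genome ORF tables.
#' @param reference label for the reference genome row.
#' @param ... forwarded to [classifyConservation()].
#' @return numeric matrix (genomes x PULs) with values in \{1, 0.5, 0\}.
#' @export
conservationMatrix <- function(ref_puls, query_orfs, reference = "REF", ...) {
  pul_ids <- vapply(ref_puls, function(p) p@id, "")
  prof <- matrix(NA_real_, length(query_orfs) + 1L, length(pul_ids),
                 dimnames = list(c(reference, names(query_orfs)), pul_ids))
  prof[reference, ] <- 1
  for (g in names(query_orfs)) {
    calls <- lapply(ref_puls, classifyConservation,
                    query_orfs = query_orfs[[g]], ...)
    prof[g, ] <- encodeProfile(calls, pul_ids)
  }
  prof
}

#' Relate PUL conservation distance to growth association
#'
#' Computes the Euclidean distance between each genome's conservation
#' profile and the reference genome's profile, then the Pearson correlation
#' (with two-sided t-test) between those distances and the genomes'
#' growth-association coefficients, paired by genome id.
#'
#' @param profiles genomes x PULs numeric matrix (rows include `reference`).
#' @param beta1 named numeric vector of association coefficients per genome.
#' @param reference row of `profiles` to measure distances from.
#' @return list: `r`, `p`, `n`, `distances` (named vector).
#' @export
correlateProfilesWithAssociation <- function(profiles, beta1,
                                             reference = "REF") {
  if (!reference %in% rownames(profiles))
    stop("reference genome '", reference, "' absent from profiles")
  genomes <- intersect(rownames(profiles), names(beta1))
  genomes <- setdiff(genomes, reference)
  if (length(genomes) < 3L)
    stop("insufficient data: need >= 3 genomes with both a profile and a coefficient")
  refp <- profiles[reference, ]
  d <- vapply(genomes, function(g) sqrt(sum((profiles[g, ] - refp)^2)), 0)
  if (stats::sd(d) == 0 || stats::sd(beta1[genomes]) == 0)
    stop("undefined correlation: zero variance in distances or coefficients")
  ct <- stats::cor.test(d, beta1[genomes], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(genomes),
       distances = d)
}
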