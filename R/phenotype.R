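# Phenotype module: predict the binary phenotype matrix (BPM) of MAGs by
# three strategies — pathway-rule decision trees, random forests, and
# neighbour-group Hamming matching over MinHash genome distances — reconciled
# into consensus calls with confidence grades.

#' Role presence/absence matrix
#'
#' @param x either a named list of genome/MAG records (each with a `genes`
#'   data.frame carrying a `role` column) or a long data.frame with columns
#'   `genome` and `role`.
#' @param roles role universe for the columns (default: union of observed
#'   non-`NA` roles).
#' @return binary matrix, genomes x roles.
#' @export
rolePresenceMatrix <- function(x, roles = NULL) {
  if (is.data.frame(x)) {
    long <- x[!is.na(x$role), c("genome", "role")]
    ids <- unique(x$genome)
  } else {
    long <- bindRows(lapply(names(x), function(g) {
      r <- x[[g]]$genes$role
      r <- r[!is.na(r)]
      if (!length(r)) return(NULL)
      data.frame(genome = g, role = r, stringsAsFactors = FALSE)
    }))
    ids <- names(x)
  }
  if (is.null(roles))
    roles <- sort(unique(long$role))
  m <- matrix(0L, length(ids), length(roles), dimnames = list(ids, roles))
  if (!is.null(long) && nrow(long)) {
    long <- long[long$role %in% roles, , drop = FALSE]
    m[cbind(long$genome, long$role)] <- 1L
  }
  m
}

# Align a role matrix to a reference role universe (absent roles count as 0:
# the gene was not found).
alignRoles <- function(m, roles) {
  out <- matrix(0L, nrow(m), length(roles),
                dimnames = list(rownames(m), roles))
  common <- intersect(colnames(m), roles)
  out[, common] <- m[, common, drop = FALSE]
  out
}

#' Train per-phenotype pathway-rule decision trees
#'
#' One binary classification tree per phenotype (Gini impurity, no pruning,
#' depth capped at the number of roles in the pathway) over role-presence
#' predictors, mirroring curated pathway rules. Phenotypes constant across
#' the reference set yield a flagged constant rule.
#'
#' @param ref_roles reference role-presence matrix (genomes x roles).
#' @param ref_bpm reference binary phenotype matrix (genomes x phenotypes).
#' @param pathway_definitions optional list (per phenotype, variants of
#'   required roles) used only to cap tree depth.
#' @return named list of rules; each is a list with `type`
#'   (`"tree"`/`"constant"`), `fit` or `value`, and `training_accuracy`.
#' @export
trainPathwayRules <- function(ref_roles, ref_bpm, pathway_definitions = NULL) {
  stopifnot(identical(rownames(ref_roles), rownames(ref_bpm)))
  rules <- list()
  df <- as.data.frame(ref_roles)
  for (p in colnames(ref_bpm)) {
    y <- ref_bpm[, p]
    if (length(unique(y)) == 1L) {
      rules[[p]] <- list(type = "constant", value = unname(y[1]),
                         training_accuracy = 1)
      next
    }
    depth <- if (!is.null(pathway_definitions) && !is.null(pathway_definitions[[p]]))
      length(unique(unlist(pathway_definitions[[p]]))) else 30L
    dat <- cbind(df, .y = factor(y, levels = c(0, 1)))
    fit <- rpart::rpart(.y ~ ., data = dat, method = "class",
                        control = rpart::rpart.control(
                          minsplit = 2, minbucket = 1, cp = -1,
                          maxdepth = min(30L, max(1L, depth)),
                          xval = 0, maxsurrogate = 0, maxcompete = 0))
    acc <- mean(stats::predict(fit, dat, type = "class") == dat$.y)
    rules[[p]] <- list(type = "tree", fit = fit, training_accuracy = acc)
  }
  rules
}

#' Apply pathway rules to MAG role patterns
#'
#' Deterministic tree evaluation; roles absent from the MAG matrix are
#' treated as 0 (gene not found).
#'
#' @param mag_roles MAG role-presence matrix.
#' @param rules result of [trainPathwayRules()].
#' @return binary matrix, MAGs x phenotypes.
#' @export
predictRules <- function(mag_roles, rules) {
  roles <- unique(unlist(lapply(rules, function(r)
    if (r$type == "tree") attr(stats::terms(r$fit), "term.labels") else character(0))))
  m <- alignRoles(mag_roles, union(colnames(mag_roles), roles))
  df <- as.data.frame(m)
  out <- matrix(0L, nrow(m), length(rules),
                dimnames = list(rownames(m), names(rules)))
  for (p in names(rules)) {
    r <- rules[[p]]
    out[, p] <- if (r$type == "constant") r$value
    else as.integer(as.character(stats::predict(r$fit, df, type = "class")))
  }
  out
}

#' Random-forest phenotype prediction with grid search
#'
#' Per phenotype, a random forest over role-presence predictors is tuned by a
#' small grid (`mtry` in \{sqrt(p), p/3\}, minimum node size in \{1, 3\})
#' using out-of-bag error, then applied to the MAGs. Optionally reports
#' leave-one-out accuracy across the reference genomes at the selected
#' hyperparameters. Fixed seed makes predictions reproducible.
#'
#' @inheritParams trainPathwayRules
#' @param mag_roles MAG role-presence matrix.
#' @param n_trees trees per forest.
#' @param grid data.frame of `mtry_frac` (`"sqrt"` or `"third"`) and
#'   `nodesize` combinations searched.
#' @param seed integer seed.
#' @param loo compute the leave-one-out report (slower).
#' @return list: `predictions` (MAGs x phenotypes), `report` (per phenotype:
#'   chosen hyperparameters, OOB error, LOO accuracy when requested, constant
#'   flag).
#' @export
predictMl <- function(ref_roles, ref_bpm, mag_roles, n_trees = 200L,
                      grid = expand.grid(mtry_frac = c("sqrt", "third"),
                                         nodesize = c(1L, 3L),
                                         stringsAsFactors = FALSE),
                      seed = 1L, loo = FALSE) {
  stopifnot(nrow(ref_roles) >= 4L)
  p <- ncol(ref_roles)
  mtry_of <- function(frac) max(1L, if (frac == "sqrt") floor(sqrt(p))
                                else floor(p / 3))
  m <- alignRoles(mag_roles, colnames(ref_roles))
  preds <- matrix(0L, nrow(m), ncol(ref_bpm),
                  dimnames = list(rownames(m), colnames(ref_bpm)))
  report <- list()
  for (phen in colnames(ref_bpm)) {
    y <- factor(ref_bpm[, phen], levels = c(0, 1))
    if (length(unique(ref_bpm[, phen])) == 1L) {
      preds[, phen] <- unique(ref_bpm[, phen])
      report[[phen]] <- data.frame(phenotype = phen, constant = TRUE,
                                   mtry = NA, nodesize = NA, oob_error = 0,
                                   loo_accuracy = if (loo) 1 else NA,
                                   stringsAsFactors = FALSE)
      next
    }
    fits <- vector("list", nrow(grid))
    oob <- numeric(nrow(grid))
    for (i in seq_len(nrow(grid))) {
      fits[[i]] <- withSubstream(seed, paste0("rf:", phen, ":", i),
        randomForest::randomForest(
          x = ref_roles, y = y, ntree = n_trees,
          mtry = mtry_of(grid$mtry_frac[i]), nodesize = grid$nodesize[i]))
      oob[i] <- fits[[i]]$err.rate[n_trees, "OOB"]
    }
    best <- which.min(oob)
    fit <- fits[[best]]
    preds[, phen] <- as.integer(as.character(
      stats::predict(fit, m, type = "response")))
    loo_acc <- NA_real_
    if (loo) {
      hit <- vapply(seq_len(nrow(ref_roles)), function(j) {
        f <- withSubstream(seed, paste0("rf-loo:", phen, ":", j),
          randomForest::randomForest(
            x = ref_roles[-j, , drop = FALSE], y = y[-j], ntree = n_trees,
            mtry = mtry_of(grid$mtry_frac[best]),
            nodesize = grid$nodesize[best]))
        as.character(stats::predict(f, ref_roles[j, , drop = FALSE])) ==
          as.character(y[j])
      }, TRUE)
      loo_acc <- mean(hit)
    }
    report[[phen]] <- data.frame(phenotype = phen, constant = FALSE,
                                 mtry = mtry_of(grid$mtry_frac[best]),
                                 nodesize = grid$nodesize[best],
                                 oob_error = oob[best],
                                 loo_accuracy = loo_acc,
                                 stringsAsFactors = FALSE)
  }
  list(predictions = preds, report = bindRows(report))
}

#' Bottom-sketch MinHash signature
#'
#' Hashes every k-mer of the supplied protein (or nucleotide) sequences and
#' keeps the `sketch_size` smallest distinct hash values.
#'
#' @param seqs character vector of sequences (e.g. all proteins of a genome).
#' @param genome_id identifier stored in the sketch.
#' @param k k-mer size (residues).
#' @param sketch_size sketch capacity.
#' @return a [MinHashSketch-class].
#' @export
minhashSketch <- function(seqs, genome_id = "genome", k = 21L,
                          sketch_size = 1000L) {
  h <- sort(unique(unlist(lapply(seqs, hashKmers, k = k))))
  methods::new("MinHashSketch", genomeId = genome_id, k = as.integer(k),
               sketchSize = as.integer(sketch_size),
               hashes = utils::head(h, sketch_size))
}

#' Mash distance between two MinHash sketches
#'
#' The Jaccard index `j` is estimated from the merged bottom sketch and
#' converted to a distance `d = -(1/k) log(2j / (1 + j))`; disjoint sketches
#' (`j = 0`) are reported at the cap of 1.
#'
#' @param s1,s2 [MinHashSketch-class] objects with equal `k` and sketch size.
#' @return distance >= 0 (capped at 1).
#' @export
mashDistance <- function(s1, s2) {
  if (s1@k != s2@k || s1@sketchSize != s2@sketchSize)
    stop("invalid comparison: sketches differ in k or sketch size")
  merged <- utils::head(sort(unique(c(s1@hashes, s2@hashes))), s1@sketchSize)
  if (!length(merged)) return(1)
  shared <- sum(merged %in% s1@hashes & merged %in% s2@hashes)
  j <- shared / length(merged)
  if (j <= 0) return(1)
  d <- -(1 / s1@k) * log(2 * j / (1 + j))
  min(max(d, 0), 1)
}

#' Group MAGs with closely related reference genomes
#'
#' Single-linkage grouping of all sketches under the distance cap (connected
#' components of the graph whose edges are pairs at Mash distance <=
#' `max_distance`). Groups smaller than `min_size` are dissolved; a MAG in no
#' group abstains from neighbour-group prediction.
#'
#' @param sketches named list of [MinHashSketch-class] (MAGs and references).
#' @param max_distance distance cap defining neighbours.
#' @param min_size minimum surviving group size.
#' @return list: `groups` (list of member-id character vectors) and `dist`
#'   (full symmetric distance matrix).
#' @export
assignNeighborGroups <- function(sketches, max_distance = 0.1, min_size = 4L) {
  ids <- names(sketches)
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- mashDistance(sketches[[i]], sketches[[j]])
      D[i, j] <- d; D[j, i] <- d
    }
  }
  # connected components under the cap (single linkage)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(D[i, ] <= max_distance)
      target <- min(comp[nb])
      if (any(comp[nb] != target)) {
        comp[nb] <- target
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  groups <- split(ids, comp)
  groups <- unname(groups[vapply(groups, length, 0L) >= min_size])
  list(groups = groups, dist = D)
}

#' Neighbour-group phenotype vote for one MAG
#'
#' For each phenotype, the comparison is limited to the roles required by
#' that pathway; the MAG adopts the phenotype of the neighbour-group
#' reference genome with the smallest Hamming distance on that restriction,
#' even if some of the genes are absent from the MAG. Equidistant references
#' with conflicting phenotypes, or a group without references, abstain.
#'
#' @param mag_roles named 0/1 vector (or 1-row matrix) of the MAG's roles.
#' @param group character vector of group member ids.
#' @param ref_roles,ref_bpm reference matrices (rows = reference genome ids).
#' @param pathway_definitions list per phenotype of variants of required roles.
#' @return named integer vector over phenotypes with values 0/1/`NA` (abstain).
#' @export
predictNeighbor <- function(mag_roles, group, ref_roles, ref_bpm,
                            pathway_definitions) {
  if (is.matrix(mag_roles)) mag_roles <- mag_roles[1, ]
  phen <- colnames(ref_bpm)
  out <- stats::setNames(rep(NA_integer_, length(phen)), phen)
  refs <- intersect(group, rownames(ref_roles))
  if (!length(refs)) return(out)
  for (p in phen) {
    req <- unique(unlist(pathway_definitions[[p]]))
    if (!length(req)) next
    magv <- stats::setNames(rep(0L, length(req)), req)
    common <- intersect(req, names(mag_roles))
    magv[common] <- mag_roles[common]
    refm <- alignRoles(ref_roles[refs, , drop = FALSE], req)
    ham <- rowSums(sweep(refm, 2, magv, "!="))
    nearest <- refs[ham == min(ham)]
    vals <- unique(ref_bpm[nearest, p])
    out[p] <- if (length(vals) == 1L) as.integer(vals) else NA_integer_
  }
  out
}

#' Reconcile the three phenotype votes into a consensus call
#'
#' Unanimity gives the common value at high confidence. When the
#' neighbour-group vote participates, a 2-vs-1 split resolves by majority at
#' medium confidence, with one deliberate exception: a positive neighbour
#' vote overrides negative rule and ML votes (medium confidence), because
#' the neighbour-group strategy exists precisely to rescue false negatives
#' that gene dropout induces in the other two methods — both of which see
#' the same incomplete gene set and therefore fail together. If the
#' neighbour vote abstains, agreement between rules and ML is medium, and an
#' irreconcilable rules/ML disagreement defaults to the machine-learning
#' value at low confidence.
#'
#' @param rule_vote,ml_vote,ng_vote votes in \{0, 1\} (`ng_vote` may be `NA`
#'   for abstention).
#' @return list with `consensus` (0/1) and `confidence`
#'   (`"high"`/`"medium"`/`"low"`).
#' @export
consensusCall <- function(rule_vote, ml_vote, ng_vote) {
  votes <- c(rule_vote, ml_vote, ng_vote)
  if (all(is.na(votes)))
    stop("undefined call: all three prediction methods abstained")
  if (is.na(ng_vote)) {
    if (is.na(rule_vote) || is.na(ml_vote)) {
      val <- stats::na.omit(c(ml_vote, rule_vote))[1]
      return(list(consensus = as.integer(val), confidence = "low"))
    }
    if (rule_vote == ml_vote)
      return(list(consensus = as.integer(rule_vote), confidence = "medium"))
    return(list(consensus = as.integer(ml_vote), confidence = "low"))
  }
  if (rule_vote == ml_vote && ml_vote == ng_vote)
    return(list(consensus = as.integer(rule_vote), confidence = "high"))
  # false-negative rescue: a positive neighbour-group match outweighs
  # dropout-prone negatives from the gene-content methods
  if (!is.na(ng_vote) && ng_vote == 1 && rule_vote == 0 && ml_vote == 0)
    return(list(consensus = 1L, confidence = "medium"))
  maj <- as.integer(sum(votes) >= 2)
  list(consensus = maj, confidence = "medium")
}

#' Consensus phenotype prediction for a set of MAGs
#'
#' Runs the three strategies (pathway rules, random forest, neighbour-group
#' matching) and reconciles them per (MAG, phenotype) via [consensusCall()].
#'
#' @inheritParams predictMl
#' @param pathway_definitions list per phenotype of role-requirement variants.
#' @param groups optional result of [assignNeighborGroups()] (its `groups`
#'   element, or the full list); when `NULL` every neighbour vote abstains.
#' @param loo forward to [predictMl()].
#' @return list: `calls` (long data.frame of votes/consensus/confidence),
#'   `bpm` (consensus matrix), `rule_bpm`, `ml_bpm`, `ml_report`.
#' @export
predictPhenotypes <- function(ref_roles, ref_bpm, mag_roles,
                              pathway_definitions, groups = NULL,
                              n_trees = 200L, seed = 1L, loo = FALSE) {
  rules <- trainPathwayRules(ref_roles, ref_bpm, pathway_definitions)
  rule_bpm <- predictRules(mag_roles, rules)
  ml <- predictMl(ref_roles, ref_bpm, mag_roles, n_trees = n_trees,
                  seed = seed, loo = loo)
  ml_bpm <- ml$predictions
  grp_list <- if (is.list(groups) && !is.null(groups$groups)) groups$groups
              else groups
  mags <- rownames(mag_roles)
  phen <- colnames(ref_bpm)
  bpm <- matrix(0L, length(mags), length(phen), dimnames = list(mags, phen))
  calls <- vector("list", length(mags) * length(phen))
  idx <- 0L
  for (m in mags) {
    grp <- NULL
    if (!is.null(grp_list)) {
      hit <- which(vapply(grp_list, function(g) m %in% g, TRUE))
      if (length(hit)) grp <- setdiff(grp_list[[hit[1]]], m)
    }
    ng <- if (is.null(grp))
      stats::setNames(rep(NA_integer_, length(phen)), phen)
    else predictNeighbor(mag_roles[m, ], grp, ref_roles, ref_bpm,
                         pathway_definitions)
    for (p in phen) {
      cc <- consensusCall(rule_bpm[m, p], ml_bpm[m, p], ng[[p]])
      bpm[m, p] <- cc$consensus
      idx <- idx + 1L
      calls[[idx]] <- data.frame(
        genome = m, phenotype = p,
        rule_vote = rule_bpm[m, p], ml_vote = ml_bpm[m, p],
        ng_vote = ng[[p]], consensus = cc$consensus,
        confidence = cc$confidence, stringsAsFactors = FALSE)
    }
  }
  list(calls = bindRows(calls), bpm = bpm, rule_bpm = rule_bpm,
       ml_bpm = ml_bpm, ml_report = ml$report)
}

#' Filter gene annotations to intact functional pathways
#'
#' A gene survives iff its functional role belongs to at least one pathway
#' whose consensus binary phenotype is 1 in that genome; unannotated genes
#' are dropped.
#'
#' @param annotations data.frame with columns `genome`, `gene_id`, `role`.
#' @param consensus_bpm genomes x phenotypes binary matrix.
#' @param pathway_definitions list per phenotype of role-requirement variants.
#' @return the surviving annotation rows.
#' @export
filterGenesToIntactPathways <- function(annotations, consensus_bpm,
                                        pathway_definitions) {
  role_to_phen <- list()
  for (p in names(pathway_definitions)) {
    for (r in unique(unlist(pathway_definitions[[p]])))
      role_to_phen[[r]] <- c(role_to_phen[[r]], p)
  }
  keep <- vapply(seq_len(nrow(annotations)), function(i) {
    r <- annotations$role[i]
    g <- annotations$genome[i]
    if (is.na(r) || is.null(role_to_phen[[r]])) return(FALSE)
    if (!g %in% rownames(consensus_bpm)) return(FALSE)
    any(consensus_bpm[g, role_to_phen[[r]]] == 1)
  }, TRUE)
  annotations[keep, , drop = FALSE]
}
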