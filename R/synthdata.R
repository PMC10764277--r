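# Synthetic-data module: generates every input the pipeline consumes with
# known ground truth (reference pangenomes with planted pathway content, MAG
# degradation, longitudinal cohorts with planted growth/treatment effects,
# alignment-hit tables, PUL variants).

#' Simulation configuration
#'
#' Validated bundle of all generator parameters. Defaults are the study
#' conditions the package simulates throughout: a scaled-down reference
#' collection (60 genomes, 20 metabolic phenotypes with 2-4 required roles
#' each), MAG recovery at 90% completeness / 2% contamination / 5% gene
#' fragmentation, and a two-arm longitudinal cohort (40 participants sampled
#' at study weeks 0, 2, 4, 8 and 12) with negative-binomial counts.
#'
#' @param n_ref_genomes number of reference genomes (>= 4, the minimum
#'   neighbour-group size).
#' @param n_phenotypes number of binary metabolic phenotypes.
#' @param roles_per_pathway length-2 integer range of required roles per
#'   pathway variant.
#' @param n_variants pathway variants per phenotype.
#' @param background_role_rate probability that a non-carrier genome holds any
#'   given role of a pathway (always kept short of a complete variant).
#' @param n_outgroup_families,outgroup_genes_per_genome protein families
#'   outside all subsystems and the number of their members per genome.
#' @param n_clades number of phylogenetic clades the reference genomes fall
#'   into; sequence divergence separates clades beyond the neighbour-group
#'   distance cap, while genomes within a clade remain close.
#' @param clade_divergence per-site substitution rate between a family's
#'   clade variants (sets between-clade sequence distance).
#' @param clade_flip_rate probability that a genome's carrier status differs
#'   from its clade's state (pathways are largely conserved within clades).
#' @param prevalence_range allowed range of phenotype prevalence across
#'   reference genomes.
#' @param protein_length length-2 range of protein lengths (residues).
#' @param family_identity target within-family pairwise amino-acid identity.
#' @param n_mags number of MAGs derived from the reference genomes for the
#'   cohort (defaults to `min(30, n_ref_genomes)`).
#' @param n_participants,timepoints,arms cohort design.
#' @param nb_dispersion negative-binomial dispersion of counts.
#' @param effect_sizes list with `beta1` (planted WLZ effect per MAG, on the
#'   standardized variance-stabilized abundance scale) and `beta3`
#'   (planted treatment-group x study-week effect on log MAG abundance,
#'   per week). Unnamed vectors are assigned to the leading MAGs.
#' @param transcript_effects list with `pathways` (phenotype ids whose member
#'   transcripts in positively planted MAGs are differentially expressed) and
#'   `beta3` (log-scale group x week effect per week).
#' @param mag_completeness,mag_contamination,fragmentation_rate MAG
#'   degradation parameters, all fractions in \[0, 1\].
#' @param wlz_baseline,wlz_participant_sd,wlz_week_slope,wlz_noise_sd
#'   anthropometry model: baseline Z score, random-intercept SD, secular
#'   per-week slope, residual SD.
#' @param seed top-level integer seed; all generator randomness flows from it
#'   through named substreams.
#' @return object of class `SimulationConfig` (validated list).
#' @export
simulationConfig <- function(n_ref_genomes = 60L,
                             n_phenotypes = 20L,
                             roles_per_pathway = c(2L, 4L),
                             n_variants = 1L,
                             background_role_rate = 0.08,
                             n_outgroup_families = 30L,
                             outgroup_genes_per_genome = 8L,
                             n_clades = 10L,
                             clade_divergence = 0.1,
                             clade_flip_rate = 0.1,
                             prevalence_range = c(0.3, 0.7),
                             protein_length = c(120L, 320L),
                             family_identity = 0.95,
                             n_mags = NULL,
                             n_participants = 40L,
                             timepoints = c(0, 2, 4, 8, 12),
                             arms = c("MDCF-2", "RUSF"),
                             nb_dispersion = 0.5,
                             effect_sizes = list(beta1 = rep(c(0.5, -0.5), each = 4),
                                                 beta3 = rep(c(0.08, -0.08), each = 4)),
                             transcript_effects = list(pathways = c("P01", "P02"),
                                                       beta3 = 0.12),
                             mag_completeness = 0.9,
                             mag_contamination = 0.02,
                             fragmentation_rate = 0.05,
                             wlz_baseline = -2.5,
                             wlz_participant_sd = 0.3,
                             wlz_week_slope = 0.015,
                             wlz_noise_sd = 0.25,
                             seed = 1L) {
  cfg <- list(
    n_ref_genomes = as.integer(n_ref_genomes),
    n_phenotypes = as.integer(n_phenotypes),
    roles_per_pathway = as.integer(roles_per_pathway),
    n_variants = as.integer(n_variants),
    background_role_rate = background_role_rate,
    n_outgroup_families = as.integer(n_outgroup_families),
    outgroup_genes_per_genome = as.integer(outgroup_genes_per_genome),
    n_clades = as.integer(n_clades),
    clade_divergence = clade_divergence,
    clade_flip_rate = clade_flip_rate,
    prevalence_range = prevalence_range,
    protein_length = as.integer(protein_length),
    family_identity = family_identity,
    n_mags = if (is.null(n_mags)) min(30L, as.integer(n_ref_genomes))
             else as.integer(n_mags),
    n_participants = as.integer(n_participants),
    timepoints = as.numeric(timepoints),
    arms = arms,
    nb_dispersion = nb_dispersion,
    effect_sizes = effect_sizes,
    transcript_effects = transcript_effects,
    mag_completeness = mag_completeness,
    mag_contamination = mag_contamination,
    fragmentation_rate = fragmentation_rate,
    wlz_baseline = wlz_baseline,
    wlz_participant_sd = wlz_participant_sd,
    wlz_week_slope = wlz_week_slope,
    wlz_noise_sd = wlz_noise_sd,
    seed = as.integer(seed)
  )
  validateSimulationConfig(cfg)
  class(cfg) <- "SimulationConfig"
  cfg
}

validateSimulationConfig <- function(cfg) {
  if (cfg$n_ref_genomes < 4L)
    stop("invalid config: n_ref_genomes must be >= 4 (minimum neighbour-group size)")
  if (cfg$n_phenotypes < 1L)
    stop("invalid config: n_phenotypes must be >= 1")
  fracs <- c(cfg$background_role_rate, cfg$mag_completeness,
             cfg$mag_contamination, cfg$fragmentation_rate,
             cfg$prevalence_range, cfg$family_identity)
  if (any(fracs < 0 | fracs > 1))
    stop("invalid config: all fractions must lie in [0, 1]")
  if (length(cfg$timepoints) >= 2 && any(diff(cfg$timepoints) <= 0))
    stop("invalid config: timepoints must be strictly increasing")
  if (length(cfg$roles_per_pathway) != 2L ||
      cfg$roles_per_pathway[1] > cfg$roles_per_pathway[2] ||
      cfg$roles_per_pathway[1] < 1L)
    stop("invalid config: roles_per_pathway must be an increasing positive range")
  if (cfg$n_participants < 0L)
    stop("invalid config: n_participants must be non-negative")
  invisible(TRUE)
}

phenotypeIds <- function(n) sprintf("P%02d", seq_len(n))
genomeIds <- function(n) sprintf("G%03d", seq_len(n))

# Phenotype = 1 iff the genome carries every role of at least one variant.
recomputeBpmFromGenes <- function(genomes, defs) {
  phen <- names(defs)
  bpm <- matrix(0L, length(genomes), length(phen),
                dimnames = list(names(genomes), phen))
  for (g in names(genomes)) {
    roles <- genomes[[g]]$genes$role
    for (p in phen) {
      complete <- any(vapply(defs[[p]], function(v) all(v %in% roles), TRUE))
      bpm[g, p] <- as.integer(complete)
    }
  }
  bpm
}

#' Generate a reference genome collection with planted pathway content
#'
#' Builds a scaled-down reference pangenome with phylogenetic structure: the
#' genomes fall into clades whose sequence divergence places different clades
#' beyond the neighbour-group distance cap while keeping within-clade genomes
#' close. Per phenotype, one or more pathway variants are defined as sets of
#' required functional roles; carrier status is assigned per clade (pathways
#' are largely conserved within clades, with a small per-genome flip rate),
#' carrier genomes hold a complete variant and non-carriers hold at most a
#' sparse, incomplete subset of its roles. Protein sequences are random
#' amino-acid strings per role family, mutated once per clade and again per
#' genome, so within-family identity is high and between-family identity is
#' at chance. The truth binary phenotype matrix (BPM) is consistent with gene
#' content by construction, and phenotype prevalences are clamped into the
#' configured band.
#'
#' @param config a [simulationConfig()].
#' @return a [ReferencePangenome-class] object.
#' @export
generateReferenceCollection <- function(config) {
  validateSimulationConfig(config)
  withSubstream(config$seed, "pangenome", {
    np <- config$n_phenotypes
    ng <- config$n_ref_genomes
    phen <- phenotypeIds(np)
    gids <- genomeIds(ng)
    mut <- (1 - config$family_identity) / 2  # per-copy rate; pairwise ~ target

    # pathway definitions and role family base sequences
    defs <- vector("list", np)
    names(defs) <- phen
    base_seq <- list()
    for (p in phen) {
      defs[[p]] <- list()
      for (v in seq_len(config$n_variants)) {
        nr <- sample(config$roles_per_pathway[1]:config$roles_per_pathway[2], 1L)
        tag <- if (config$n_variants > 1L) paste0(p, "_V", v) else p
        roles <- paste0(tag, "_R", seq_len(nr))
        defs[[p]][[v]] <- roles
        for (r in roles)
          base_seq[[r]] <- randomProtein(
            sample(config$protein_length[1]:config$protein_length[2], 1L))
      }
    }
    og <- sprintf("OG%02d", seq_len(config$n_outgroup_families))
    for (r in og)
      base_seq[[r]] <- randomProtein(
        sample(config$protein_length[1]:config$protein_length[2], 1L))

    # clade membership and per-clade sequence variants of every family
    ncl <- max(1L, min(config$n_clades, ng %/% 2L))
    clade <- rep(seq_len(ncl), length.out = ng)  # interleaved assignment
    clade_seq <- lapply(seq_len(ncl), function(cl)
      lapply(base_seq, mutateProtein, rate = config$clade_divergence))

    # carrier assignment: per-clade states with a small per-genome flip rate,
    # then clamped into the configured prevalence band
    lo_n <- max(2L, ceiling(ng * config$prevalence_range[1]))
    hi_n <- min(ng - 2L, floor(ng * config$prevalence_range[2]))
    carrier <- matrix(FALSE, ng, np, dimnames = list(gids, phen))
    variant_of <- matrix(NA_integer_, ng, np, dimnames = list(gids, phen))
    for (j in seq_len(np)) {
      prev <- runif(1, config$prevalence_range[1], config$prevalence_range[2])
      k_cl <- max(1L, min(ncl - 1L, round(ncl * prev)))
      carrier_clades <- sample(ncl, k_cl)
      state <- clade %in% carrier_clades
      flip <- runif(ng) < config$clade_flip_rate
      cc <- state != flip
      # clamp the realized prevalence into the band
      if (sum(cc) < lo_n) {
        add <- sample(which(!cc), lo_n - sum(cc))
        cc[add] <- TRUE
      } else if (sum(cc) > hi_n) {
        drop <- sample(which(cc), sum(cc) - hi_n)
        cc[drop] <- FALSE
      }
      carrier[cc, j] <- TRUE
      # genomes of one clade share a pathway variant; flipped-in genomes draw
      clade_variant <- sample(config$n_variants, ncl, replace = TRUE)
      variant_of[cc, j] <- clade_variant[clade[cc]]
    }

    genomes <- vector("list", ng)
    names(genomes) <- gids
    for (i in seq_len(ng)) {
      g <- gids[i]
      fam <- character(0)
      role <- character(0)
      for (j in seq_len(np)) {
        p <- phen[j]
        if (carrier[i, j]) {
          roles <- defs[[p]][[variant_of[i, j]]]
          fam <- c(fam, roles)
          role <- c(role, roles)
        } else {
          all_roles <- unlist(defs[[p]])
          keep <- all_roles[runif(length(all_roles)) < config$background_role_rate]
          # a non-carrier must never hold a complete variant
          for (v in defs[[p]]) {
            if (all(v %in% keep)) keep <- setdiff(keep, sample(v, 1L))
          }
          fam <- c(fam, keep)
          role <- c(role, keep)
        }
      }
      ogf <- sample(og, min(config$outgroup_genes_per_genome, length(og)))
      fam <- c(fam, ogf)
      role <- c(role, rep(NA_character_, length(ogf)))
      cseq <- clade_seq[[clade[i]]]
      seqs <- vapply(fam, function(f) mutateProtein(cseq[[f]], mut), "")
      genomes[[g]] <- list(
        genome_id = g,
        genes = data.frame(
          gene_id = paste0(g, "_", fam),
          role = role,
          family = fam,
          seq = unname(seqs),
          stringsAsFactors = FALSE
        )
      )
    }

    subsystems <- lapply(defs, function(vl) unique(unlist(vl)))
    bpm <- recomputeBpmFromGenes(genomes, defs)
    stopifnot(identical(unname(bpm), unname(1L * carrier)))
    methods::new("ReferencePangenome",
                 genomes = genomes,
                 subsystems = subsystems,
                 pathwayDefinitions = defs,
                 truthBpm = bpm,
                 outgroupFamilies = og)
  })
}

#' Degrade a reference genome into a MAG
#'
#' Emulates metagenomic genome recovery: each gene is retained independently
#' with probability `completeness`; retained genes are split into two
#' fragments with probability `fragmentation_rate`; contaminant genes are
#' drawn from donor genomes at the contamination rate. The provenance of every
#' surviving gene (`retained`, `fragment`, `contaminant`) is recorded.
#'
#' @param genome a genome record (see [ReferencePangenome-class]).
#' @param completeness,contamination,fragmentation_rate fractions in \[0, 1\].
#' @param seed integer seed.
#' @param donors optional list of genome records supplying contaminant genes.
#' @return a MAG record: list with `mag_id`, `source_genome` and a `genes`
#'   data.frame carrying provenance columns.
#' @export
degradeGenomeToMag <- function(genome, completeness = 0.9,
                               contamination = 0.02,
                               fragmentation_rate = 0.05,
                               seed = 1L, donors = NULL) {
  if (!is.list(genome) || is.null(genome$genes) || nrow(genome$genes) == 0)
    stop("genome must be a non-empty genome record")
  for (v in c(completeness, contamination, fragmentation_rate))
    if (!is.finite(v) || v < 0 || v > 1)
      stop("invalid parameter: completeness, contamination and fragmentation_rate must lie in [0, 1]")
  withSubstream(seed, paste0("mag:", genome$genome_id), {
    genes <- genome$genes
    keep <- runif(nrow(genes)) < completeness
    kept <- genes[keep, , drop = FALSE]
    out <- list()
    if (nrow(kept)) {
      frag <- runif(nrow(kept)) < fragmentation_rate
      whole <- kept[!frag, , drop = FALSE]
      if (nrow(whole)) {
        whole$origin <- "retained"
        whole$source_genome <- genome$genome_id
        whole$source_gene <- whole$gene_id
        out[[length(out) + 1L]] <- whole
      }
      for (i in which(frag)) {
        g <- kept[i, ]
        len <- nchar(g$seq)
        cut <- sample(max(2L, floor(len / 3)):min(len - 1L, ceiling(2 * len / 3)), 1L)
        for (piece in 1:2) {
          fg <- g
          fg$gene_id <- paste0(g$gene_id, "_f", piece)
          fg$seq <- if (piece == 1) substr(g$seq, 1, cut)
                    else substr(g$seq, cut + 1, len)
          fg$origin <- "fragment"
          fg$source_genome <- genome$genome_id
          fg$source_gene <- g$gene_id
          out[[length(out) + 1L]] <- fg
        }
      }
    }
    if (contamination > 0 && !is.null(donors) && length(donors)) {
      donors <- Filter(function(d) d$genome_id != genome$genome_id, donors)
      ncont <- rbinom(1L, nrow(genes), contamination)
      if (ncont > 0 && length(donors)) {
        pool <- bindRows(lapply(donors, function(d)
          cbind(d$genes, donor = d$genome_id)))
        pick <- pool[sample(nrow(pool), min(ncont, nrow(pool))), , drop = FALSE]
        cont <- data.frame(
          gene_id = paste0(pick$gene_id, "_cont"),
          role = pick$role,
          family = pick$family,
          seq = pick$seq,
          origin = "contaminant",
          source_genome = pick$donor,
          source_gene = pick$gene_id,
          stringsAsFactors = FALSE
        )
        out[[length(out) + 1L]] <- cont
      }
    }
    genes_out <- bindRows(out)
    if (is.null(genes_out))
      genes_out <- data.frame(gene_id = character(0), role = character(0),
                              family = character(0), seq = character(0),
                              origin = character(0),
                              source_genome = character(0),
                              source_gene = character(0),
                              stringsAsFactors = FALSE)
    list(mag_id = paste0("MAG_", genome$genome_id),
         source_genome = genome$genome_id,
         genes = genes_out)
  })
}

#' Derive the cohort MAG set from a pangenome
#'
#' Degrades the first `config$n_mags` reference genomes into MAGs under the
#' configured completeness/contamination/fragmentation, with contaminants
#' drawn from the remaining genomes.
#'
#' @inheritParams generateReferenceCollection
#' @param pangenome a [ReferencePangenome-class].
#' @return named list of MAG records.
#' @export
deriveMags <- function(pangenome, config) {
  gids <- names(refGenomes(pangenome))[seq_len(config$n_mags)]
  mags <- lapply(gids, function(g)
    degradeGenomeToMag(refGenomes(pangenome)[[g]],
                       completeness = config$mag_completeness,
                       contamination = config$mag_contamination,
                       fragmentation_rate = config$fragmentation_rate,
                       seed = substreamSeed(config$seed, paste0("mags:", g)),
                       donors = refGenomes(pangenome)))
  names(mags) <- vapply(mags, `[[`, "", "mag_id")
  mags
}

resolveEffects <- function(eff, mag_ids) {
  out <- numeric(0)
  if (is.null(eff) || !length(eff)) return(out)
  if (!is.null(names(eff)) && all(nzchar(names(eff)))) {
    out <- eff[names(eff) %in% mag_ids]
  } else {
    n <- min(length(eff), length(mag_ids))
    out <- stats::setNames(eff[seq_len(n)], mag_ids[seq_len(n)])
  }
  out
}

#' Simulate a longitudinal two-arm cohort with planted effects
#'
#' Generates MAG DNA abundances (TPM and negative-binomial counts), transcript
#' counts and per-sample clinical metadata. WLZ trajectories are built as
#' participant random intercept + secular week slope + planted `beta1` effects
#' on the standardized variance-stabilized MAG abundance scale + Gaussian
#' noise. Planted `beta3` effects make MAG abundances (and, for the configured
#' pathways, member transcripts of positively planted MAGs) diverge between
#' arms over time.
#'
#' @param pangenome a [ReferencePangenome-class].
#' @param config a [simulationConfig()].
#' @param mags optional list of MAG records (defaults to [deriveMags()]).
#' @return a [SyntheticCohort-class].
#' @export
simulateCohort <- function(pangenome, config, mags = NULL) {
  validateSimulationConfig(config)
  if (config$n_participants < 1L)
    stop("invalid config: zero participants")
  if (is.null(mags)) mags <- deriveMags(pangenome, config)
  mag_ids <- names(mags)
  nm <- length(mag_ids)

  withSubstream(config$seed, "cohort", {
    # ---- design ----
    pids <- sprintf("PID%03d", seq_len(config$n_participants))
    arm <- rep(config$arms, length.out = config$n_participants)[
      sample(config$n_participants)]
    names(arm) <- pids
    weeks <- config$timepoints
    meta <- data.frame(
      sample_id = as.vector(t(outer(pids, weeks, function(p, w)
        sprintf("%s_w%02g", p, w)))),
      PID = rep(pids, each = length(weeks)),
      study_week = rep(weeks, times = length(pids)),
      arm = rep(arm, each = length(weeks)),
      stringsAsFactors = FALSE
    )
    ns <- nrow(meta)
    is_mdcf <- as.numeric(meta$arm == config$arms[1])

    # ---- MAG DNA abundance ----
    beta3_dna <- resolveEffects(config$effect_sizes$beta3, mag_ids)
    meanlog <- rnorm(nm, log(100), 1.0)
    n_rare <- min(3L, max(0L, nm - length(resolveEffects(
      config$effect_sizes$beta1, mag_ids)) - 1L))
    if (n_rare > 0) meanlog[(nm - n_rare + 1L):nm] <- meanlog[(nm - n_rare + 1L):nm] - 9
    names(meanlog) <- mag_ids
    la <- matrix(rnorm(nm * ns, rep(meanlog, ns), 0.8), nm, ns,
                 dimnames = list(mag_ids, meta$sample_id))
    # participant-level abundance offsets (repeated measures structure)
    pid_off <- matrix(rnorm(nm * length(pids), 0, 0.5), nm, length(pids),
                      dimnames = list(mag_ids, pids))
    la <- la + pid_off[, meta$PID]
    for (m in names(beta3_dna))
      la[m, ] <- la[m, ] + beta3_dna[m] * meta$study_week * is_mdcf
    abund <- exp(la)
    tpm <- sweep(abund, 2, colSums(abund), "/") * 1e6
    lib <- exp(rnorm(ns, log(3e5), 0.2))
    mu <- sweep(tpm / 1e6, 2, lib, "*")
    counts <- matrix(rnbinom(nm * ns, mu = mu, size = 1 / config$nb_dispersion),
                     nm, ns, dimnames = dimnames(tpm))

    # ---- WLZ ----
    beta1 <- resolveEffects(config$effect_sizes$beta1, mag_ids)
    vst <- varianceStabilize(counts)
    wlz <- config$wlz_baseline +
      rnorm(length(pids), 0, config$wlz_participant_sd)[
        match(meta$PID, pids)] +
      config$wlz_week_slope * meta$study_week +
      rnorm(ns, 0, config$wlz_noise_sd)
    for (m in names(beta1)) {
      z <- as.numeric(scale(vst[m, ]))
      wlz <- wlz + beta1[m] * z
    }
    meta$WLZ <- wlz

    # WLZ-response quartiles within the first (microbiome-directed) arm
    slope <- vapply(pids, function(p) {
      rows <- meta$PID == p
      unname(stats::coef(stats::lm(meta$WLZ[rows] ~ meta$study_week[rows]))[2])
    }, 0)
    meta$quartile <- "other"
    mdcf_p <- pids[arm == config$arms[1]]
    if (length(mdcf_p) >= 4) {
      qs <- stats::quantile(slope[mdcf_p], c(0.25, 0.75))
      meta$quartile[meta$PID %in% mdcf_p[slope[mdcf_p] >= qs[2]]] <- "upper"
      meta$quartile[meta$PID %in% mdcf_p[slope[mdcf_p] <= qs[1]]] <- "lower"
    }

    # ---- transcripts ----
    tx <- bindRows(lapply(mags, function(m) {
      g <- m$genes
      if (!nrow(g)) return(NULL)
      data.frame(transcript_id = g$gene_id, mag = m$mag_id, role = g$role,
                 origin = g$origin, stringsAsFactors = FALSE)
    }))
    de_roles <- unique(unlist(lapply(
      config$transcript_effects$pathways,
      function(p) unlist(pathwayDefinitions(pangenome)[[p]])
    )))
    pos_mags <- names(beta1)[beta1 > 0]
    de_tx <- tx$transcript_id[tx$mag %in% pos_mags & tx$role %in% de_roles]
    nt <- nrow(tx)
    rel <- exp(rnorm(nt, log(1e-3), 0.7))
    depth <- exp(rnorm(ns, 0, 0.2))
    lmu <- log(tpm[tx$mag, , drop = FALSE] + 1) + log(rel)  # nt x ns
    lmu <- sweep(lmu, 2, log(depth), "+")
    b3t <- config$transcript_effects$beta3
    if (length(de_tx) && !is.null(b3t) && b3t != 0) {
      shift <- outer(rep(b3t, length(de_tx)), meta$study_week * is_mdcf)
      lmu[match(de_tx, tx$transcript_id), ] <-
        lmu[match(de_tx, tx$transcript_id), ] + shift
    }
    rna <- matrix(rnbinom(nt * ns, mu = exp(lmu), size = 1 / config$nb_dispersion),
                  nt, ns, dimnames = list(tx$transcript_id, meta$sample_id))

    rownames(meta) <- meta$sample_id
    dna_se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(tpm = tpm, counts = counts),
      colData = S4Vectors::DataFrame(meta))
    rna_se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = rna),
      rowData = S4Vectors::DataFrame(tx),
      colData = S4Vectors::DataFrame(meta))
    methods::new("SyntheticCohort", dna = dna_se, rna = rna_se,
                 truth = list(beta1 = beta1, beta3_dna = beta3_dna,
                              de_transcripts = de_tx,
                              de_pathways = config$transcript_effects$pathways,
                              participant_slopes = slope))
  })
}

#' Simulate tabular alignment hits for MAG proteins
#'
#' Emulates the protein-vs-reference-database search the annotation workflow
#' consumes: every query protein receives high-identity hits to the reference
#' members of its own family and low-identity decoy hits to other families,
#' with jittered alignment coordinates and bitscores increasing with identity
#' and alignment length.
#'
#' @param mag MAG record (or any list with a `genes` data.frame carrying
#'   `gene_id`, `family`, `seq`).
#' @param pangenome a [ReferencePangenome-class] supplying reference proteins.
#' @param seed integer seed.
#' @param identity_high,identity_sd mean/SD percent identity for same-family hits.
#' @param identity_low,decoys_per_query mean identity and count of decoy hits.
#' @return list with `hits` (DIAMOND/BLAST outfmt-6 style data.frame) and
#'   `refmap` (subject_id -> role / outgroup flag).
#' @export
simulateAlignmentHits <- function(mag, pangenome, seed = 1L,
                                  identity_high = 92, identity_sd = 2,
                                  identity_low = 55, decoys_per_query = 8L) {
  refmap <- referenceProteinMap(pangenome)
  ref_genes <- bindRows(lapply(refGenomes(pangenome), `[[`, "genes"))
  fam_index <- split(seq_len(nrow(ref_genes)), ref_genes$family)
  withSubstream(seed, paste0("hits:", mag$mag_id %||% "query"), {
    rows <- lapply(seq_len(nrow(mag$genes)), function(i) {
      q <- mag$genes[i, ]
      qlen <- nchar(q$seq)
      subj_true <- ref_genes$gene_id[fam_index[[q$family]] %||% integer(0)]
      other_fams <- setdiff(names(fam_index), q$family)
      subj_decoy <- ref_genes$gene_id[vapply(
        sample(other_fams, min(decoys_per_query, length(other_fams))),
        function(f) fam_index[[f]][1L], 0L)]
      n1 <- length(subj_true); n2 <- length(subj_decoy)
      if (n1 + n2 == 0) return(NULL)
      pid <- c(pmin(100, rnorm(n1, identity_high, identity_sd)),
               pmin(100, rnorm(n2, identity_low, 4)))
      qs <- pmax(1L, 1L + round(rnorm(n1 + n2, 0, 1)))
      qe <- pmin(qlen, qlen + round(rnorm(n1 + n2, 0, 1)))
      qe <- pmax(qe, qs)
      alen <- qe - qs + 1L
      data.frame(
        qseqid = q$gene_id, sseqid = c(subj_true, subj_decoy),
        pident = round(pid, 1), length = alen,
        mismatch = round(alen * (1 - pid / 100)), gapopen = 0L,
        qstart = qs, qend = qe, sstart = 1L, send = alen,
        evalue = 10^(-pmin(200, alen * pid / 200)),
        bitscore = round(alen * pid / 50 + rnorm(n1 + n2, 0, 2), 1),
        stringsAsFactors = FALSE
      )
    })
    list(hits = bindRows(rows) %||% emptyHits(), refmap = refmap)
  })
}

emptyHits <- function() {
  data.frame(qseqid = character(0), sseqid = character(0), pident = numeric(0),
             length = integer(0), mismatch = integer(0), gapopen = integer(0),
             qstart = integer(0), qend = integer(0), sstart = integer(0),
             send = integer(0), evalue = numeric(0), bitscore = numeric(0),
             stringsAsFactors = FALSE)
}

#' Reference protein map of a pangenome
#'
#' @param pangenome a [ReferencePangenome-class].
#' @return data.frame (`subject_id`, `role`, `is_outgroup`): the sidecar role
#'   map the annotation workflow joins against alignment hits.
#' @export
referenceProteinMap <- function(pangenome) {
  genes <- bindRows(lapply(refGenomes(pangenome), `[[`, "genes"))
  data.frame(subject_id = genes$gene_id,
             role = genes$role,
             is_outgroup = genes$family %in% pangenome@outgroupFamilies,
             stringsAsFactors = FALSE)
}

#' Planted multi-domain annotation fixture
#'
#' Builds alignment-hit tables for proteins with two planted domains (plus
#' optional outgroup-only queries): each domain draws high-identity hits from
#' its true role family and low-identity decoy hits from other families, with
#' Gaussian jitter on the alignment coordinates. Ground-truth boundaries and
#' roles are returned for recovery scoring.
#'
#' @param n_proteins number of two-domain query proteins.
#' @param n_roles number of in-scope role families.
#' @param n_outgroup_queries queries whose only hits are outgroup proteins.
#' @param identity_high,identity_separation mean identity of true hits and the
#'   gap (in identity points) down to the decoy mode.
#' @param hits_per_domain,decoys_per_domain hit counts per planted domain.
#' @param boundary_sd SD (residues) of coordinate jitter.
#' @param seed integer seed.
#' @return list with `hits`, `refmap`, `queries` (query_id, length) and
#'   `truth` (query_id, domain, start, end, role).
#' @export
simulateAnnotationFixture <- function(n_proteins = 100L, n_roles = 12L,
                                      n_outgroup_queries = 5L,
                                      identity_high = 90,
                                      identity_separation = 35,
                                      hits_per_domain = 20L,
                                      decoys_per_domain = 20L,
                                      boundary_sd = 2, seed = 1L) {
  withSubstream(seed, "annotation-fixture", {
    roles <- sprintf("ROLE%02d", seq_len(n_roles))
    og <- sprintf("OGF%02d", 1:4)
    refmap <- data.frame(
      subject_id = c(as.vector(outer(roles, seq_len(max(hits_per_domain, 1L)),
                                     function(r, k) sprintf("%s_ref%02d", r, k))),
                     as.vector(outer(og, 1:hits_per_domain,
                                     function(r, k) sprintf("%s_ref%02d", r, k)))),
      stringsAsFactors = FALSE
    )
    refmap$role <- sub("_ref[0-9]+$", "", refmap$subject_id)
    refmap$is_outgroup <- refmap$role %in% og
    refmap$role[refmap$is_outgroup] <- NA_character_

    id_low <- identity_high - identity_separation
    mk_hits <- function(qid, s, e, role, outgroup = FALSE) {
      subs_true <- sprintf("%s_ref%02d", role, seq_len(hits_per_domain))
      decoy_roles <- sample(setdiff(roles, role), decoys_per_domain, replace = TRUE)
      subs_decoy <- sprintf("%s_ref%02d", decoy_roles,
                            sample(hits_per_domain, decoys_per_domain, replace = TRUE))
      n1 <- hits_per_domain; n2 <- if (outgroup) 0L else decoys_per_domain
      subs <- c(subs_true, subs_decoy[seq_len(n2)])
      pid <- c(rnorm(n1, identity_high, 2), rnorm(n2, id_low, 3))
      qs <- pmax(1L, round(s + rnorm(n1 + n2, 0, boundary_sd)))
      qe <- round(e + rnorm(n1 + n2, 0, boundary_sd))
      qe <- pmax(qe, qs + 10L)
      alen <- qe - qs + 1L
      data.frame(qseqid = qid, sseqid = subs, pident = round(pmin(100, pid), 1),
                 length = alen, mismatch = round(alen * (1 - pid / 100)),
                 gapopen = 0L, qstart = qs, qend = qe, sstart = 1L, send = alen,
                 evalue = 1e-30,
                 bitscore = round(alen * pid / 50 + rnorm(n1 + n2, 0, 1), 1),
                 stringsAsFactors = FALSE)
    }

    hits <- list(); truth <- list(); queries <- list()
    for (i in seq_len(n_proteins)) {
      qid <- sprintf("Q%04d", i)
      l1 <- sample(60:120, 1L); gap <- sample(40:60, 1L); l2 <- sample(60:120, 1L)
      d1 <- c(1L, l1); d2 <- c(l1 + gap + 1L, l1 + gap + l2)
      rr <- sample(roles, 2L)
      hits[[length(hits) + 1L]] <- mk_hits(qid, d1[1], d1[2], rr[1])
      hits[[length(hits) + 1L]] <- mk_hits(qid, d2[1], d2[2], rr[2])
      truth[[length(truth) + 1L]] <- data.frame(
        query_id = qid, domain = 1:2,
        start = c(d1[1], d2[1]), end = c(d1[2], d2[2]), role = rr,
        stringsAsFactors = FALSE)
      queries[[length(queries) + 1L]] <-
        data.frame(query_id = qid, length = d2[2] + 20L, stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_outgroup_queries)) {
      qid <- sprintf("QOG%03d", i)
      len <- sample(120:250, 1L)
      hits[[length(hits) + 1L]] <- mk_hits(qid, 1L, len, sample(og, 1L),
                                           outgroup = TRUE)
      truth[[length(truth) + 1L]] <- data.frame(
        query_id = qid, domain = 1L, start = 1L, end = len,
        role = NA_character_, stringsAsFactors = FALSE)
      queries[[length(queries) + 1L]] <-
        data.frame(query_id = qid, length = len, stringsAsFactors = FALSE)
    }
    list(hits = bindRows(hits), refmap = refmap,
         queries = bindRows(queries), truth = bindRows(truth))
  })
}

# ---------------------------------------------------------------------------
# PUL generation

#' Build a reference polysaccharide utilization locus
#'
#' @param id,genome identifiers.
#' @param n_cazymes number of CAZyme ORFs downstream of the SusC/SusD pair.
#' @param with_regulator include an upstream regulator ORF.
#' @param seed integer seed.
#' @return a [Pul-class] object (ORFs on contig `c1`, positions 1..n).
#' @export
makeReferencePul <- function(id = "PUL1", genome = "REF", n_cazymes = 3L,
                             with_regulator = TRUE, seed = 1L) {
  withSubstream(seed, paste0("refpul:", id), {
    classes <- c(if (with_regulator) "regulator", "SusC", "SusD",
                 rep("CAZyme", n_cazymes))
    fams <- ifelse(classes == "CAZyme",
                   sprintf("GH%d", sample(c(5, 10, 26, 43, 51, 130),
                                          length(classes), replace = TRUE)),
                   classes)
    n <- length(classes)
    orfs <- data.frame(
      orf_id = sprintf("%s_%s_orf%02d", genome, id, seq_len(n)),
      contig = "c1", pos = seq_len(n), strand = "+",
      role_class = classes, family = fams,
      seq = vapply(classes, function(cl)
        randomProtein(sample(150:350, 1L)), ""),
      stringsAsFactors = FALSE
    )
    methods::new("Pul", id = id, genome = genome, orfs = orfs)
  })
}

#' Plant a conservation variant of a reference PUL
#'
#' `conserved`: every ORF point-mutated to well above 90% identity, order
#' preserved. `structurally_distinct`: a conserved copy with exactly one
#' structural defect (a CAZyme or one SusC/SusD deleted or fragmented, or an
#' extra ORF inserted), recorded in the result. `absent`: no PUL.
#'
#' @param reference_pul a [Pul-class] with >= 1 SusC/SusD pair and >= 1 CAZyme.
#' @param mode one of `"conserved"`, `"structurally_distinct"`, `"absent"`.
#' @param seed integer seed.
#' @param genome identifier for the emitted variant's genome.
#' @param mutation_rate per-site substitution rate for conserved ORFs.
#' @return `NULL` for `absent`; otherwise a list with `orfs` (data.frame),
#'   `mode` and `defect` (provenance string, `NA` when conserved).
#' @export
plantPulVariants <- function(reference_pul, mode, seed = 1L, genome = "QRY",
                             mutation_rate = 0.03) {
  mode <- as.character(mode)
  if (!mode %in% c("conserved", "structurally_distinct", "absent"))
    stop("invalid parameter: unknown mode '", mode, "'")
  ref <- pulOrfs(reference_pul)
  if (!any(ref$role_class == "CAZyme"))
    stop("reference PUL must contain >= 1 CAZyme ORF")
  if (mode == "absent") return(NULL)
  withSubstream(seed, paste0("pulvar:", reference_pul@id, ":", mode), {
    orfs <- ref
    orfs$orf_id <- paste0(genome, "_", sub("^[^_]+_", "", ref$orf_id))
    orfs$seq <- vapply(ref$seq, mutateProtein, "", rate = mutation_rate)
    defect <- NA_character_
    if (mode == "structurally_distinct") {
      choices <- c("delete_cazyme", "delete_transporter", "fragment_cazyme",
                   "insert_orf")
      pick <- sample(choices, 1L)
      caz <- which(orfs$role_class == "CAZyme")
      if (pick == "delete_cazyme") {
        i <- sample(caz, 1L)
        defect <- paste0("deleted CAZyme ", ref$orf_id[i])
        orfs <- orfs[-i, , drop = FALSE]
      } else if (pick == "delete_transporter") {
        i <- sample(which(orfs$role_class %in% c("SusC", "SusD")), 1L)
        defect <- paste0("deleted transporter ", ref$orf_id[i])
        orfs <- orfs[-i, , drop = FALSE]
      } else if (pick == "fragment_cazyme") {
        i <- sample(caz, 1L)
        g <- orfs[i, ]
        len <- nchar(g$seq)
        cut <- sample(floor(len * 0.4):ceiling(len * 0.6), 1L)
        f1 <- g; f2 <- g
        f1$orf_id <- paste0(g$orf_id, "_f1"); f1$seq <- substr(g$seq, 1, cut)
        f2$orf_id <- paste0(g$orf_id, "_f2"); f2$seq <- substr(g$seq, cut + 1, len)
        defect <- paste0("fragmented CAZyme ", ref$orf_id[i])
        orfs <- bindRows(list(orfs[seq_len(i - 1L), , drop = FALSE], f1, f2,
                              orfs[-seq_len(i), , drop = FALSE]))
      } else {
        i <- sample(seq_len(nrow(orfs) - 1L), 1L)
        extra <- data.frame(orf_id = paste0(genome, "_", reference_pul@id,
                                            "_extra"),
                            contig = "c1", pos = 0, strand = "+",
                            role_class = "CAZyme", family = "GH2",
                            seq = randomProtein(sample(150:300, 1L)),
                            stringsAsFactors = FALSE)
        defect <- "inserted extra CAZyme ORF"
        orfs <- bindRows(list(orfs[seq_len(i), , drop = FALSE], extra,
                              orfs[-seq_len(i), , drop = FALSE]))
      }
    }
    orfs$pos <- seq_len(nrow(orfs))
    list(orfs = orfs, mode = mode, defect = defect)
  })
}

#' Embed PUL ORFs into a genome-scale ORF table
#'
#' Surrounds the locus with unrelated background ORFs so that detection and
#' conservation classification operate on a realistic gene neighbourhood.
#'
#' @param orfs PUL ORF data.frame (or `NULL` for a genome with no PUL).
#' @param genome genome identifier.
#' @param n_background background ORFs split across the flanks.
#' @param seed integer seed.
#' @param flip reverse the ORF order and strand of the embedded block
#'   (strand-flipped synteny).
#' @return data.frame of genome ORFs ordered by position.
#' @export
embedPulInGenome <- function(orfs, genome, n_background = 20L, seed = 1L,
                             flip = FALSE) {
  withSubstream(seed, paste0("embed:", genome), {
    bg <- function(n, offset) {
      if (n <= 0) return(NULL)
      data.frame(orf_id = sprintf("%s_bg%03d", genome, offset + seq_len(n)),
                 contig = "c1", pos = 0, strand = sample(c("+", "-"), n, TRUE),
                 role_class = "other", family = NA_character_,
                 seq = vapply(seq_len(n), function(i)
                   randomProtein(sample(120:300, 1L)), ""),
                 stringsAsFactors = FALSE)
    }
    nl <- n_background %/% 2L
    nr <- n_background - nl
    mid <- NULL
    if (!is.null(orfs) && nrow(orfs)) {
      mid <- orfs
      if (flip) {
        mid <- mid[rev(seq_len(nrow(mid))), , drop = FALSE]
        mid$strand <- ifelse(mid$strand == "+", "-", "+")
      }
    }
    out <- bindRows(list(bg(nl, 0L), mid, bg(nr, nl)))
    out$contig <- "c1"
    out$pos <- seq_len(nrow(out))
    out
  })
}

#' Simulate a PUL conservation study with a planted association decay
#'
#' Builds a reference genome carrying `n_puls` PULs and a panel of query
#' genomes whose PUL conservation decays monotonically with their planted
#' growth-association coefficient: the genome with the largest `beta1` keeps
#' almost all PULs conserved, the smallest keeps almost none.
#'
#' @param n_puls reference PULs.
#' @param n_genomes query genomes (the reference itself is not included).
#' @param beta_range range of planted association coefficients (descending
#'   across genomes).
#' @param seed integer seed.
#' @param embed also embed variants in background ORF tables (needed for
#'   sequence-level classification; profile-level analyses can skip it).
#' @return list: `ref_puls` (list of [Pul-class]), `ref_orfs`, `queries`
#'   (per-genome ORF tables, if `embed`), `categories` (genomes x PULs planted
#'   category matrix), `beta1` (named vector).
#' @export
simulatePulStudy <- function(n_puls = 8L, n_genomes = 10L,
                             beta_range = c(0.6, -0.6), seed = 1L,
                             embed = TRUE) {
  withSubstream(seed, "pulstudy", {
    ref_puls <- lapply(seq_len(n_puls), function(i)
      makeReferencePul(sprintf("PUL%d", i), "REF",
                       n_cazymes = sample(2:4, 1L),
                       seed = substreamSeed(seed, paste0("pul", i))))
    names(ref_puls) <- vapply(ref_puls, function(p) p@id, "")
    ref_orfs <- bindRows(lapply(ref_puls, pulOrfs))
    ref_orfs$pos <- seq_len(nrow(ref_orfs))

    gids <- sprintf("Q%02d", seq_len(n_genomes))
    beta1 <- stats::setNames(seq(beta_range[1], beta_range[2],
                                 length.out = n_genomes), gids)
    # conservation propensity decreases with association rank
    p_cons <- seq(0.95, 0.05, length.out = n_genomes)
    modes <- c("conserved", "structurally_distinct", "absent")
    categories <- matrix(NA_character_, n_genomes, n_puls,
                         dimnames = list(gids, names(ref_puls)))
    queries <- vector("list", n_genomes)
    names(queries) <- gids
    for (i in seq_len(n_genomes)) {
      pc <- p_cons[i]
      prob <- c(pc, (1 - pc) * 0.5, (1 - pc) * 0.5)
      cat_i <- sample(modes, n_puls, replace = TRUE, prob = prob)
      categories[i, ] <- cat_i
      if (embed) {
        blocks <- lapply(seq_len(n_puls), function(j) {
          v <- plantPulVariants(ref_puls[[j]], cat_i[j],
                                seed = substreamSeed(seed, paste0(gids[i], ":", j)),
                                genome = gids[i])
          if (is.null(v)) NULL else v$orfs
        })
        tab <- bindRows(c(list(NULL), blocks))
        queries[[i]] <- embedPulInGenome(
          tab, gids[i], n_background = 12L,
          seed = substreamSeed(seed, paste0("embed:", gids[i])))
      }
    }
    list(ref_puls = ref_puls, ref_orfs = ref_orfs, queries = queries,
         categories = categories, beta1 = beta1)
  })
}
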