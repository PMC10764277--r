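#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Reference pangenome with curated pathway content and truth phenotypes
#'
#' Container for a collection of reference genomes whose proteins carry
#' functional-role labels, the subsystem/pathway definitions built over those
#' roles, and the ground-truth binary phenotype matrix (BPM) implied by gene
#' content. Produced by [generateReferenceCollection()].
#'
#' @slot genomes named list; each element is a genome record, a list with
#'   `genome_id` and a `genes` data.frame (`gene_id`, `role` (`NA` for
#'   proteins outside any subsystem), `family`, `seq`).
#' @slot subsystems named list mapping subsystem name to the character vector
#'   of functional roles it contains.
#' @slot pathwayDefinitions named list; per phenotype, a list of pathway
#'   variants, each a character vector of required functional roles.
#' @slot truthBpm genomes x phenotypes binary matrix.
#' @slot outgroupFamilies character; protein families outside all subsystems
#'   (their members carry no in-scope role label).
#' @exportClass ReferencePangenome
setClass("ReferencePangenome",
  representation(
    genomes = "list",
    subsystems = "list",
    pathwayDefinitions = "list",
    truthBpm = "matrix",
    outgroupFamilies = "character"
  )
)

setValidity("ReferencePangenome", function(object) {
  msgs <- character(0)
  if (!all(object@truthBpm %in% c(0, 1)))
    msgs <- c(msgs, "truthBpm entries must be 0/1")
  if (!identical(rownames(object@truthBpm), names(object@genomes)))
    msgs <- c(msgs, "truthBpm rows must match genome names")
  roles_present <- unique(unlist(lapply(object@genomes,
                                        function(g) g$genes$role)))
  needed <- unique(unlist(object@pathwayDefinitions))
  if (!all(needed %in% roles_present))
    msgs <- c(msgs, "every role referenced by a pathway must exist in >=1 genome")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ReferencePangenome-class number of genomes and phenotypes
#' @param object a `ReferencePangenome`
#' @export
setMethod("show", "ReferencePangenome", function(object) {
  cat("ReferencePangenome with", length(object@genomes), "genomes,",
      ncol(object@truthBpm), "phenotypes,",
      length(unique(unlist(object@subsystems))), "functional roles\n")
})

#' @rdname ReferencePangenome-class
#' @param x a `ReferencePangenome`
#' @export
truthBpm <- function(x) x@truthBpm

#' @rdname ReferencePangenome-class
#' @export
pathwayDefinitions <- function(x) x@pathwayDefinitions

#' @rdname ReferencePangenome-class
#' @export
refGenomes <- function(x) x@genomes

#' Synthetic longitudinal cohort
#'
#' Holds paired MAG DNA abundance and transcript count data for a simulated
#' feeding-trial cohort, with per-sample clinical covariates and the planted
#' ground-truth effects. Both assays are stored as
#' [SummarizedExperiment::SummarizedExperiment] objects (features x samples)
#' sharing the same samples/colData.
#'
#' @slot dna `SummarizedExperiment` with assays `tpm` and `counts`
#'   (MAGs x samples).
#' @slot rna `SummarizedExperiment` with assay `counts`
#'   (transcripts x samples); rowData carries the transcript -> MAG map and
#'   the functional role of each gene.
#' @slot truth list of planted effects (`beta1`, `beta3_dna`,
#'   `beta3_transcripts`, ...).
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
  representation(
    dna = "SummarizedExperiment",
    rna = "SummarizedExperiment",
    truth = "list"
  )
)

setValidity("SyntheticCohort", function(object) {
  msgs <- character(0)
  if (!identical(colnames(object@dna), colnames(object@rna)))
    msgs <- c(msgs, "dna and rna assays must share sample columns")
  cnt <- SummarizedExperiment::assay(object@rna, "counts")
  if (any(cnt < 0) || any(cnt != round(cnt)))
    msgs <- c(msgs, "transcript counts must be non-negative integers")
  if (any(SummarizedExperiment::assay(object@dna, "tpm") < 0))
    msgs <- c(msgs, "TPM values must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SyntheticCohort-class brief summary
#' @param object a `SyntheticCohort`
#' @export
setMethod("show", "SyntheticCohort", function(object) {
  meta <- sampleMeta(object)
  cat("SyntheticCohort:", nrow(object@dna), "MAGs,", nrow(object@rna),
      "transcripts,", ncol(object@dna), "samples from",
      length(unique(meta$PID)), "participants\n")
})

#' @rdname SyntheticCohort-class
#' @param x a `SyntheticCohort`
#' @export
dnaTpm <- function(x) SummarizedExperiment::assay(x@dna, "tpm")

#' @rdname SyntheticCohort-class
#' @export
dnaCounts <- function(x) SummarizedExperiment::assay(x@dna, "counts")

#' @rdname SyntheticCohort-class
#' @export
rnaCounts <- function(x) SummarizedExperiment::assay(x@rna, "counts")

#' @rdname SyntheticCohort-class
#' @export
sampleMeta <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x@dna))
}

#' @rdname SyntheticCohort-class
#' @export
transcriptMap <- function(x) {
  as.data.frame(SummarizedExperiment::rowData(x@rna))
}

#' @rdname SyntheticCohort-class
#' @export
cohortTruth <- function(x) x@truth

#' Bottom-sketch MinHash signature of a genome
#'
#' @slot genomeId character genome identifier.
#' @slot k k-mer size (residues).
#' @slot sketchSize maximum number of retained minimal hashes.
#' @slot hashes sorted ascending minimal hash values.
#' @exportClass MinHashSketch
setClass("MinHashSketch",
  representation(
    genomeId = "character",
    k = "integer",
    sketchSize = "integer",
    hashes = "numeric"
  )
)

setValidity("MinHashSketch", function(object) {
  msgs <- character(0)
  if (length(object@hashes) > object@sketchSize)
    msgs <- c(msgs, "more hashes than sketchSize")
  if (is.unsorted(object@hashes))
    msgs <- c(msgs, "hashes must be sorted ascending")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn MinHashSketch-class brief summary
#' @param object a `MinHashSketch`
#' @export
setMethod("show", "MinHashSketch", function(object) {
  cat("MinHashSketch", object@genomeId, "k =", object@k,
      "|hashes| =", length(object@hashes), "\n")
})

#' Polysaccharide utilization locus
#'
#' An ordered, role-labelled ORF cluster detected on a single contig.
#' Validity requires at least one adjacent SusC/SusD transporter pair.
#'
#' @slot id PUL identifier.
#' @slot genome source genome identifier.
#' @slot orfs data.frame of member ORFs, ordered by contig position, with
#'   columns `orf_id`, `contig`, `pos`, `strand`, `role_class`
#'   (`SusC`, `SusD`, `CAZyme`, `regulator`, `other`), `family`, `seq`.
#' @slot substrate optional predicted substrate label.
#' @exportClass Pul
setClass("Pul",
  representation(
    id = "character",
    genome = "character",
    orfs = "data.frame",
    substrate = "character"
  ),
  prototype(substrate = NA_character_)
)

setValidity("Pul", function(object) {
  orfs <- object@orfs
  msgs <- character(0)
  if (length(unique(orfs$contig)) != 1L)
    msgs <- c(msgs, "all ORFs of a PUL must lie on one contig")
  if (anyDuplicated(orfs$pos))
    msgs <- c(msgs, "ordinal ORF positions must be unique")
  rc <- orfs$role_class[order(orfs$pos)]
  pair <- any(rc[-length(rc)] == "SusC" & rc[-1] == "SusD") ||
    any(rc[-length(rc)] == "SusD" & rc[-1] == "SusC")
  if (!pair) msgs <- c(msgs, "a PUL must contain an adjacent SusC/SusD pair")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn Pul-class brief summary
#' @param object a `Pul`
#' @export
setMethod("show", "Pul", function(object) {
  tab <- table(object@orfs$role_class)
  cat("Pul", object@id, "(", object@genome, "):", nrow(object@orfs),
      "ORFs [", paste(names(tab), tab, sep = ":", collapse = " "), "]\n")
})

#' @rdname Pul-class
#' @param x a `Pul`
#' @export
pulOrfs <- function(x) x@orfs
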