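# Readers and writers for the standard interchange formats: protein FASTA,
# GFF3 gene calls, TSV count matrices and metadata, JSON truth files.

#' Write protein sequences to FASTA
#'
#' @param seqs named character vector of amino-acid sequences, or a genome /
#'   MAG record (its `genes` data.frame supplies `gene_id` and `seq`).
#' @param path output path.
#' @export
writeProteinFasta <- function(seqs, path) {
  if (is.list(seqs) && !is.null(seqs$genes))
    seqs <- stats::setNames(seqs$genes$seq, seqs$genes$gene_id)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA path.
#' @return named character vector.
#' @export
readProteinFasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write gene calls as GFF3
#'
#' Genes are laid out sequentially on a single contig with 1-based inclusive
#' nucleotide coordinates (3 nt per residue plus stop), which is sufficient
#' for tools that only need gene identity, order and frame.
#'
#' @param record genome/MAG record with a `genes` data.frame.
#' @param path output path.
#' @export
writeGff3 <- function(record, path) {
  genes <- record$genes
  widths <- nchar(genes$seq) * 3L + 3L
  starts <- cumsum(c(1L, utils::head(widths + 100L, -1L)))
  gr <- GenomicRanges::GRanges(
    seqnames = "contig_1",
    ranges = IRanges::IRanges(start = starts, width = widths),
    strand = "+")
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$source <- "magpheno"
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a features x samples matrix as TSV
#'
#' Header row holds the sample ids; the first column (`feature`) holds the
#' feature ids.
#'
#' @param mat numeric matrix with dimnames.
#' @param path output path.
#' @export
writeCountTable <- function(mat, path) {
  df <- data.frame(feature = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a features x samples TSV matrix
#'
#' @param path TSV written by [writeCountTable()].
#' @return numeric matrix.
#' @export
readCountTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write sample metadata as TSV
#'
#' @param meta data.frame with columns `sample_id`, `PID`, `study_week`,
#'   `arm`, `WLZ`, `quartile`.
#' @param path output path.
#' @export
writeSampleMeta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readSampleMeta <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Export a synthetic cohort to a directory of plain-text files
#'
#' Writes `dna_tpm.tsv`, `dna_counts.tsv`, `rna_counts.tsv`, `meta.tsv`,
#' `transcript_map.tsv` and `truth.json`.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
exportCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    writeCountTable(dnaTpm(cohort), file.path(dir, "dna_tpm.tsv")),
    writeCountTable(dnaCounts(cohort), file.path(dir, "dna_counts.tsv")),
    writeCountTable(rnaCounts(cohort), file.path(dir, "rna_counts.tsv")),
    writeSampleMeta(sampleMeta(cohort), file.path(dir, "meta.tsv")),
    {
      p <- file.path(dir, "transcript_map.tsv")
      utils::write.table(transcriptMap(cohort), p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      p
    },
    {
      p <- file.path(dir, "truth.json")
      truth <- lapply(cohortTruth(cohort), function(x)
        if (!is.null(names(x))) as.list(x) else x)  # keep names in JSON
      jsonlite::write_json(truth, p, auto_unbox = TRUE, digits = NA)
      p
    })
  invisible(paths)
}
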