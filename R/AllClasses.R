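#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData rowRanges
NULL

#' GeneModel: the coordinate machine for one protein-coding gene
#'
#' A \code{GeneModel} records the chromosome, strand and ordered CDS segments
#' of one gene, and is the object back-translation uses to map protein
#' positions to genomic coordinates. Segments are stored as 1-based inclusive
#' genomic intervals in \emph{transcription} order: ascending genomic
#' coordinates on the plus strand, descending on the minus strand.
#'
#' @slot geneId single gene identifier.
#' @slot chrom chromosome / sequence name.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot segments integer matrix with columns \code{start}, \code{end}; one
#'   row per CDS segment, rows in transcription order.
#' @slot phase phase of the first segment (0, 1 or 2); the number of bases to
#'   skip before the first complete codon. Generated models always have 0.
#'
#' @examples
#' gm <- GeneModel("g1", "chr1", "+", cbind(start = 101L, end = 160L))
#' cdsLength(gm)
#' @export
setClass("GeneModel",
  representation(
    geneId = "character",
    chrom = "character",
    strand = "character",
    segments = "matrix",
    phase = "integer"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character()
  seg <- object@segments
  if (!is.numeric(seg) || ncol(seg) != 2L)
    return("'segments' must be a numeric matrix with columns start, end")
  if (length(object@strand) != 1L || !object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  if (any(seg[, 2L] < seg[, 1L]))
    msg <- c(msg, "segment end < start")
  if (nrow(seg) > 1L) {
    o <- order(seg[, 1L])
    s <- seg[o, , drop = FALSE]
    if (any(s[-1L, 1L] <= s[-nrow(s), 2L]))
      msg <- c(msg, "CDS segments overlap")
  }
  if (!object@phase %in% 0:2)
    msg <- c(msg, "phase must be 0, 1 or 2")
  len <- sum(seg[, 2L] - seg[, 1L] + 1L) - object@phase
  if (len %% 3L != 0L)
    msg <- c(msg, "total CDS length (after phase) not divisible by 3")
  if (length(msg)) msg else TRUE
})

#' @param geneId,chrom,strand,segments,phase see slots.
#' @rdname GeneModel-class
#' @export
GeneModel <- function(geneId, chrom, strand, segments, phase = 0L) {
  storage.mode(segments) <- "integer"
  colnames(segments) <- c("start", "end")
  new("GeneModel", geneId = geneId, chrom = chrom, strand = strand,
      segments = segments, phase = as.integer(phase))
}

#' KmerHistogram: a k-mer occurrence spectrum
#'
#' Maps occurrence (multiplicity of a k-mer in the reads) to the number of
#' distinct k-mers observed at that multiplicity — the standard two-column
#' "histo" output of k-mer counters.
#'
#' @slot occurrence positive integer occurrences (unique).
#' @slot count number of distinct k-mers at each occurrence (non-negative;
#'   numeric so that summary-level spectra with fractional counts can be
#'   represented).
#' @slot k the k-mer length.
#'
#' @examples
#' h <- KmerHistogram(c(1L, 2L, 50L), c(1e5, 2e4, 4e4), k = 25L)
#' totalObservations(h)
#' @export
setClass("KmerHistogram",
  representation(occurrence = "integer", count = "numeric", k = "integer")
)

setValidity("KmerHistogram", function(object) {
  msg <- character()
  if (length(object@occurrence) != length(object@count))
    return("occurrence and count lengths differ")
  if (any(object@occurrence < 1L)) msg <- c(msg, "occurrences must be >= 1")
  if (anyDuplicated(object@occurrence)) msg <- c(msg, "duplicated occurrences")
  if (any(object@count < 0)) msg <- c(msg, "negative counts")
  if (length(object@k) != 1L || object@k < 1L) msg <- c(msg, "invalid k")
  if (length(msg)) msg else TRUE
})

#' @param occurrence,count,k see slots.
#' @rdname KmerHistogram-class
#' @export
KmerHistogram <- function(occurrence, count, k = 25L) {
  o <- order(occurrence)
  new("KmerHistogram", occurrence = as.integer(occurrence[o]),
      count = as.numeric(count[o]), k = as.integer(k))
}

#' SpectrumEstimate: genome size estimated from a k-mer spectrum
#'
#' Result container for [estimateGenomeSize()]: the detected (or supplied)
#' heterozygous and homozygous peak coverages, the artifact cutoff, total and
#' artifact k-mer observations (sums of occurrence times count), and the
#' genome size in bp, defined as
#' (total observations − artifact observations) / homozygous peak coverage.
#'
#' @slot hetPeak heterozygous peak occurrence, or NA when absent.
#' @slot homPeak homozygous peak occurrence.
#' @slot cutoff artifact cutoff: occurrences below it are discarded.
#' @slot totalObservations sum of occurrence * count over the whole spectrum.
#' @slot artifactObservations same sum restricted to occurrence < cutoff.
#' @slot genomeSize estimated genome size in bp.
#' @export
setClass("SpectrumEstimate",
  representation(
    hetPeak = "numeric", homPeak = "numeric", cutoff = "numeric",
    totalObservations = "numeric", artifactObservations = "numeric",
    genomeSize = "numeric"
  )
)

setValidity("SpectrumEstimate", function(object) {
  msg <- character()
  if (object@homPeak <= 0) msg <- c(msg, "homPeak must be positive")
  if (!is.na(object@hetPeak) && object@homPeak <= object@hetPeak)
    msg <- c(msg, "homPeak must exceed hetPeak when both are present")
  expected <- (object@totalObservations - object@artifactObservations) /
    object@homPeak
  if (abs(object@genomeSize - expected) > 1e-6 * max(1, expected))
    msg <- c(msg, "genomeSize inconsistent with observations and homPeak")
  if (length(msg)) msg else TRUE
})

#' SharingMatrix: species-level allele-sharing proportions
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"sharing"}
#' holds, for each amino acid variant (row) and species (column), the
#' proportion (in [0, 1]) of that species' accessions that are homozygous for
#' the wild allele at every SNV making up the variant. \code{rowData} carries
#' the gene id and variant label; \code{colData} carries the species group
#' and the accession count used as the denominator.
#'
#' @export
setClass("SharingMatrix", contains = "SummarizedExperiment")

setValidity("SharingMatrix", function(object) {
  msg <- character()
  if (!"sharing" %in% SummarizedExperiment::assayNames(object))
    return("assay 'sharing' missing")
  x <- SummarizedExperiment::assay(object, "sharing")
  if (any(is.na(x)) || any(x < 0) || any(x > 1))
    msg <- c(msg, "sharing proportions must lie in [0, 1]")
  cd <- SummarizedExperiment::colData(object)
  if (!"n_accessions" %in% colnames(cd))
    msg <- c(msg, "colData must record n_accessions")
  else if (any(cd$n_accessions < 1))
    msg <- c(msg, "n_accessions must be >= 1")
  if (length(msg)) msg else TRUE
})

#' SpeciesClustering: hierarchical clustering of species columns
#'
#' Wraps the \code{\link[stats]{hclust}} tree built on the species columns of
#' a [SharingMatrix], together with the canonical leaf order (left-to-right
#' traversal, smaller subtree first) and the cophenetic distances.
#'
#' @slot hclust the \code{hclust} object.
#' @slot leafOrder species names in canonical dendrogram order.
#' @slot cophenetic cophenetic distance matrix (class \code{dist}).
#' @slot linkage,metric the parameters used.
#' @export
setClass("SpeciesClustering",
  representation(
    hclust = "ANY", leafOrder = "character", cophenetic = "ANY",
    linkage = "character", metric = "character"
  )
)

setValidity("SpeciesClustering", function(object) {
  msg <- character()
  if (!inherits(object@hclust, "hclust") && !is.null(object@hclust))
    msg <- c(msg, "hclust slot must hold an hclust object (or NULL for 1 leaf)")
  labs <- if (is.null(object@hclust)) object@leafOrder else object@hclust$labels
  if (!setequal(labs, object@leafOrder) ||
      anyDuplicated(object@leafOrder))
    msg <- c(msg, "leafOrder must be a permutation of the species labels")
  if (length(msg)) msg else TRUE
})
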