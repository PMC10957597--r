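#' @rdname GeneModel-class
setMethod("geneId", "GeneModel", function(x) x@geneId)

#' @rdname GeneModel-class
setMethod("cdsSegments", "GeneModel", function(x) x@segments)

#' @rdname GeneModel-class
setMethod("cdsLength", "GeneModel", function(x)
  sum(x@segments[, 2L] - x@segments[, 1L] + 1L) - x@phase)

#' @rdname GeneModel-class
setMethod("proteinLength", "GeneModel", function(x) cdsLength(x) %/% 3L - 1L)

#' Genomic positions of the spliced CDS, 5' to 3'
#'
#' Returns the genomic coordinate of every spliced-CDS base in transcript
#' order; positions descend within minus-strand segments. Bases skipped by a
#' non-zero phase are excluded.
#' @rdname GeneModel-class
setMethod("genomicPositions", "GeneModel", function(x) {
  seg <- x@segments
  pos <- unlist(lapply(seq_len(nrow(seg)), function(i) {
    if (x@strand == "+") seq.int(seg[i, 1L], seg[i, 2L])
    else seq.int(seg[i, 2L], seg[i, 1L])
  }), use.names = FALSE)
  if (x@phase > 0L) pos <- pos[-seq_len(x@phase)]
  pos
})

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel", object@geneId, "\n",
      " ", object@chrom, " strand ", object@strand, ", ",
      nrow(object@segments), " CDS segment(s), ",
      cdsLength(object), " nt (", proteinLength(object), " aa + stop)\n",
      sep = "")
})

#' @rdname KmerHistogram-class
setMethod("totalObservations", "KmerHistogram", function(x)
  sum(x@occurrence * x@count))

setMethod("show", "KmerHistogram", function(object) {
  cat("KmerHistogram (k = ", object@k, "): ",
      length(object@occurrence), " occurrence bins, ",
      format(sum(object@count), big.mark = ","), " distinct k-mers, ",
      format(totalObservations(object), big.mark = ","), " observations\n",
      sep = "")
})

#' @rdname SpectrumEstimate-class
setMethod("genomeSize", "SpectrumEstimate", function(x) x@genomeSize)

#' @rdname SpectrumEstimate-class
setMethod("homPeak", "SpectrumEstimate", function(x) x@homPeak)

#' @rdname SpectrumEstimate-class
setMethod("hetPeak", "SpectrumEstimate", function(x) x@hetPeak)

setMethod("show", "SpectrumEstimate", function(object) {
  cat("SpectrumEstimate\n",
      "  het peak:  ", ifelse(is.na(object@hetPeak), "none",
                              object@hetPeak), "\n",
      "  hom peak:  ", object@homPeak, "\n",
      "  cutoff:    ", object@cutoff, "\n",
      "  total obs: ", format(object@totalObservations, big.mark = ","), "\n",
      "  artifact:  ", format(object@artifactObservations, big.mark = ","),
      "\n",
      "  genome size: ", sprintf("%.1f Mbp", object@genomeSize / 1e6), "\n",
      sep = "")
})

#' @rdname SharingMatrix-class
setMethod("sharingValues", "SharingMatrix", function(x)
  SummarizedExperiment::assay(x, "sharing"))

#' @rdname SharingMatrix-class
setMethod("speciesCounts", "SharingMatrix", function(x) {
  cd <- SummarizedExperiment::colData(x)
  stats::setNames(cd$n_accessions, rownames(cd))
})

#' @rdname SharingMatrix-class
setMethod("variantLabels", "SharingMatrix", function(x)
  SummarizedExperiment::rowData(x)$label)

setMethod("show", "SharingMatrix", function(object) {
  cat("SharingMatrix: ", nrow(object), " variant(s) x ", ncol(object),
      " species (", sum(speciesCounts(object)), " accessions)\n", sep = "")
  callNextMethod()
})

#' @rdname SpeciesClustering-class
setMethod("leafOrder", "SpeciesClustering", function(x) x@leafOrder)

setMethod("show", "SpeciesClustering", function(object) {
  cat("SpeciesClustering (", object@linkage, " linkage, ", object@metric,
      " distance)\n  leaf order: ",
      paste(object@leafOrder, collapse = ", "), "\n", sep = "")
})
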