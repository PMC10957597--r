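#' @rdname GeneModel-class
#' @param object,x a \code{GeneModel}.
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @rdname GeneModel-class
#' @export
setGeneric("cdsSegments", function(x) standardGeneric("cdsSegments"))

#' @rdname GeneModel-class
#' @export
setGeneric("cdsLength", function(x) standardGeneric("cdsLength"))

#' @rdname GeneModel-class
#' @export
setGeneric("proteinLength", function(x) standardGeneric("proteinLength"))

#' @rdname GeneModel-class
#' @export
setGeneric("genomicPositions", function(x) standardGeneric("genomicPositions"))

#' @rdname KmerHistogram-class
#' @param x a \code{KmerHistogram}.
#' @export
setGeneric("totalObservations", function(x) standardGeneric("totalObservations"))

#' @rdname SpectrumEstimate-class
#' @param x a \code{SpectrumEstimate}.
#' @export
setGeneric("genomeSize", function(x) standardGeneric("genomeSize"))

#' @rdname SpectrumEstimate-class
#' @export
setGeneric("homPeak", function(x) standardGeneric("homPeak"))

#' @rdname SpectrumEstimate-class
#' @export
setGeneric("hetPeak", function(x) standardGeneric("hetPeak"))

#' @rdname SharingMatrix-class
#' @param x a \code{SharingMatrix}.
#' @export
setGeneric("sharingValues", function(x) standardGeneric("sharingValues"))

#' @rdname SharingMatrix-class
#' @export
setGeneric("speciesCounts", function(x) standardGeneric("speciesCounts"))

#' @rdname SharingMatrix-class
#' @export
setGeneric("variantLabels", function(x) standardGeneric("variantLabels"))

#' @rdname SpeciesClustering-class
#' @param x a \code{SpeciesClustering}.
#' @export
setGeneric("leafOrder", function(x) standardGeneric("leafOrder"))
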