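#' @rdname GeneSet-class
#' @param object,x A package object.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneSet-class
#' @export
setGeneric("upstreamSeqs", function(x) standardGeneric("upstreamSeqs"))

#' @rdname GeneSet-class
#' @export
setGeneric("regionLength", function(x) standardGeneric("regionLength"))

#' @rdname MotifReport-class
#' @export
setGeneric("motifConsensus", function(x) standardGeneric("motifConsensus"))

#' @rdname MotifReport-class
#' @export
setGeneric("motifOccurrences", function(x) standardGeneric("motifOccurrences"))

#' @rdname ProfileMatrix-class
#' @export
setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))

#' @rdname LandscapeResult-class
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname LandscapeResult-class
#' @export
setGeneric("landscapePeaks", function(x) standardGeneric("landscapePeaks"))

#' @rdname LandscapeResult-class
#' @export
setGeneric("geneCoords", function(x) standardGeneric("geneCoords"))
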