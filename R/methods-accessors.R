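#' @rdname GeneSet-class
#' @aliases geneIds,GeneSet-method
setMethod("geneIds", "GeneSet", function(x) names(x@upstream))

#' @rdname GeneSet-class
#' @aliases upstreamSeqs,GeneSet-method
setMethod("upstreamSeqs", "GeneSet", function(x) x@upstream)

#' @rdname GeneSet-class
#' @aliases regionLength,GeneSet-method
setMethod("regionLength", "GeneSet", function(x) x@regionLength)

#' @rdname GeneSet-class
setMethod("length", "GeneSet", function(x) length(x@upstream))

#' @rdname GeneSet-class
#' @param i Gene ids or indices.
setMethod("[", "GeneSet", function(x, i) {
  new("GeneSet", upstream = x@upstream[i], regionLength = x@regionLength)
})

setMethod("show", "GeneSet", function(object) {
  cat("GeneSet with", length(object), "genes, upstream window L =",
      object@regionLength, "bp\n")
  if (length(object)) {
    ids <- geneIds(object)
    cat("  genes:", paste(head(ids, 5L), collapse = ", "),
        if (length(ids) > 5L) "..." else "", "\n")
  }
})

#' @rdname MotifReport-class
#' @aliases motifConsensus,MotifReport-method
setMethod("motifConsensus", "MotifReport", function(x) x@consensus)

#' @rdname MotifReport-class
#' @aliases motifOccurrences,MotifReport-method
setMethod("motifOccurrences", "MotifReport", function(x) {
  stats::setNames(x@occurrences, x@consensus)
})

#' @rdname MotifReport-class
setMethod("length", "MotifReport", function(x) length(x@consensus))

#' @rdname MotifReport-class
#' @param x,object A MotifReport.
#' @param i Motif indices.
setMethod("[", "MotifReport", function(x, i) {
  new("MotifReport", consensus = x@consensus[i], count = x@count[i],
      sig = x@sig[i], coverage = x@coverage[i],
      occurrences = x@occurrences[i], nGenes = x@nGenes,
      regionLength = x@regionLength, nCandidates = x@nCandidates)
})

#' Summarise a MotifReport as a data.frame
#'
#' @param x A [MotifReport-class].
#' @param ... Unused.
#' @return A data.frame with columns consensus, count, sig, coverage.
#' @export
as.data.frame.MotifReport <- function(x, ...) {
  data.frame(consensus = x@consensus, count = x@count, sig = x@sig,
             coverage = x@coverage, stringsAsFactors = FALSE)
}

setMethod("show", "MotifReport", function(object) {
  cat("MotifReport:", length(object), "motifs over", object@nGenes,
      "genes (L =", object@regionLength, "bp,",
      format(object@nCandidates, big.mark = ","), "candidates scored)\n")
  if (length(object)) {
    print(head(as.data.frame(object), 10L), row.names = FALSE)
    if (length(object) > 10L) cat("  ...\n")
  }
})

#' @rdname ProfileMatrix-class
#' @aliases profileCounts,ProfileMatrix-method
setMethod("profileCounts", "ProfileMatrix", function(x) x@counts)

#' @rdname ProfileMatrix-class
#' @param x,object A ProfileMatrix.
setMethod("dim", "ProfileMatrix", function(x) dim(x@counts))

setMethod("show", "ProfileMatrix", function(object) {
  cat("ProfileMatrix:", nrow(object@counts), "genes x",
      length(object@motifs), "motifs x", object@nBins,
      "bins of", object@binWidth, "bp\n")
  nz <- sum(rowSums(object@counts) > 0)
  cat("  genes with at least one occurrence:", nz, "/",
      nrow(object@counts), "\n")
})

#' @rdname LandscapeResult-class
#' @aliases clusterLabels,LandscapeResult-method
setMethod("clusterLabels", "LandscapeResult", function(x) x@labels)

#' @rdname LandscapeResult-class
#' @aliases landscapePeaks,LandscapeResult-method
setMethod("landscapePeaks", "LandscapeResult", function(x) x@peaks)

#' @rdname LandscapeResult-class
#' @aliases geneCoords,LandscapeResult-method
setMethod("geneCoords", "LandscapeResult", function(x) x@coords)

setMethod("show", "LandscapeResult", function(object) {
  cat("LandscapeResult:", nrow(object@coords), "genes,",
      nrow(object@peaks), "peaks\n")
  tab <- table(object@labels)
  cat("  cluster sizes:",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
})

setMethod("show", "Background", function(object) {
  cat("Background model, Markov order", object@order, "\n")
  cat("  base frequencies (A,C,G,T):",
      paste(sprintf("%.3f", object@freq), collapse = ", "), "\n")
})

setMethod("show", "FixtureBundle", function(object) {
  cat("FixtureBundle (scenario:",
      object@manifest$scenario %||% "custom", ")\n")
  cat("  ", length(object@genes), "genes in",
      length(unique(object@truth)), "subsets;",
      length(object@motifDb), "database motifs\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
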