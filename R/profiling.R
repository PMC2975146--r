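## Quartile profiling: turn a motif report into the gene-motif vector
## table that is clustered downstream. The upstream window of length L
## is divided into B equal bins (default 4 bins of 200 bp); bin 1 is
## nearest the gene start.

#' Bin index of an upstream distance
#'
#' Bins are half-open on the left: bin b covers distances
#' `((b-1)*binWidth, b*binWidth]`, so bin 1 holds distances
#' `1..binWidth` (closest to the gene start) and the index is the
#' ceiling of `distance / binWidth`.
#'
#' @param distance Upstream distance(s) in bp, 1-based.
#' @param binWidth Bin width in bp.
#' @param nBins Number of bins B.
#' @return Integer bin index (vector) in `[1, nBins]`.
#' @examples
#' binOf(c(1, 200, 201, 620), binWidth = 200, nBins = 4)
#' @export
binOf <- function(distance, binWidth, nBins) {
  if (any(distance < 1L) || any(distance > binWidth * nBins)) {
    stop("distance out of range [1, ", binWidth * nBins, "]",
         call. = FALSE)
  }
  as.integer(ceiling(distance / binWidth))
}

#' Build the genes x (motif, bin) profile matrix
#'
#' One row per gene of the gene set (order preserved), one column per
#' (motif, bin) pair, holding the number of occurrences of that motif
#' whose upstream distance falls in that bin. Genes without any
#' occurrence keep an all-zero row. Column order: motifs in report
#' order, bins ascending; labels `"<consensus>@bin<i>"`.
#'
#' @param report A [MotifReport-class].
#' @param genes The [GeneSet-class] the report was computed on.
#' @param nBins Number of bins B (default 4); L must be divisible by B.
#' @return A [ProfileMatrix-class].
#' @export
buildProfileMatrix <- function(report, genes, nBins = 4L) {
  stopifnot(is(report, "MotifReport"), is(genes, "GeneSet"))
  L <- regionLength(genes)
  nBins <- as.integer(nBins)
  if (L %% nBins != 0L) {
    stop("region length ", L, " is not divisible by ", nBins, " bins",
         call. = FALSE)
  }
  binWidth <- L %/% nBins
  ids <- geneIds(genes)
  motifs <- motifConsensus(report)
  cols <- if (length(motifs)) {
    paste0(rep(motifs, each = nBins), "@bin", rep(seq_len(nBins),
                                                  length(motifs)))
  } else character(0)
  m <- matrix(0L, nrow = length(ids), ncol = length(cols),
              dimnames = list(ids, cols))
  for (j in seq_along(motifs)) {
    occ <- report@occurrences[[j]]
    if (!nrow(occ)) next
    bad <- setdiff(unique(occ$gene), ids)
    if (length(bad)) {
      stop("occurrence gene '", bad[1L], "' of motif '", motifs[j],
           "' is not in the GeneSet", call. = FALSE)
    }
    b <- binOf(occ$distance, binWidth, nBins)
    tab <- table(factor(occ$gene, levels = ids),
                 factor(b, levels = seq_len(nBins)))
    m[, (j - 1L) * nBins + seq_len(nBins)] <- as.integer(tab)
  }
  new("ProfileMatrix", counts = m, motifs = motifs, nBins = nBins,
      binWidth = as.integer(binWidth))
}

#' Distance between two gene-motif vectors
#'
#' Cosine distance is `1 - cos(u, v)`, with the convention that the
#' distance of an all-zero vector to anything (including itself) is 1;
#' Euclidean is the standard L2 norm of the difference.
#'
#' @param u,v Numeric vectors of equal length.
#' @param metric `"cosine"` (default) or `"euclidean"`.
#' @return A non-negative scalar.
#' @examples
#' profileDistance(c(1, 0, 1, 0), c(0, 1, 0, 1), "euclidean")  # 2
#' profileDistance(c(1, 0), c(0, 1), "cosine")                 # 1
#' @export
profileDistance <- function(u, v, metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  if (length(u) != length(v)) {
    stop("dimension mismatch: ", length(u), " vs ", length(v),
         call. = FALSE)
  }
  if (metric == "euclidean") return(sqrt(sum((u - v)^2)))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(1)
  1 - sum(u * v) / (nu * nv)
}

## full pairwise distance matrix over profile rows
.pairwiseDistances <- function(m, metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  if (metric == "euclidean") {
    return(as.matrix(stats::dist(m)))
  }
  norms <- sqrt(rowSums(m^2))
  d <- matrix(1, nrow(m), nrow(m), dimnames = list(rownames(m),
                                                   rownames(m)))
  nz <- norms > 0
  if (any(nz)) {
    mm <- m[nz, , drop = FALSE] / norms[nz]
    d[nz, nz] <- 1 - tcrossprod(mm)
  }
  d[d < 0] <- 0
  diag(d)[nz] <- 0
  d
}
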