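#' @import methods
#' @importFrom Biostrings DNAStringSet width reverseComplement
#'   oligonucleotideFrequency matchPattern vcountPattern readDNAStringSet
#'   DNAString letterFrequency
#' @importFrom S4Vectors isSingleNumber isSingleString
#' @importFrom IRanges start end
#' @importFrom stats pbinom phyper p.adjust rbinom rpois runif sd var
#' @importFrom utils head read.delim write.table
NULL

#' GeneSet: a gene set with fixed-length upstream sequences
#'
#' Holds the upstream (promoter-side) DNA of every gene in a co-expressed
#' gene set. Sequences are stored 5'->3' on the gene's coding strand with
#' the gene start at the right end, so the last base of each sequence is
#' the base immediately adjacent to the gene start. Upstream distances are
#' 1-based: distance 1 is the rightmost base.
#'
#' @slot upstream A [Biostrings::DNAStringSet] named by gene id; each
#'   sequence at most `regionLength` bases over the alphabet A, C, G, T, N.
#' @slot regionLength Integer, the nominal upstream window length L in bp
#'   (default 800, the community-standard window for *S. cerevisiae*).
#' @export
setClass("GeneSet",
  representation(upstream = "DNAStringSet", regionLength = "integer"))

setValidity("GeneSet", function(object) {
  ids <- names(object@upstream)
  if (length(object@upstream) > 0L &&
      (is.null(ids) || any(!nzchar(ids)) || anyNA(ids))) {
    return("every sequence must have a non-empty gene id")
  }
  if (anyDuplicated(ids)) {
    return(paste0("duplicate gene id: '", ids[duplicated(ids)][1L], "'"))
  }
  if (length(object@regionLength) != 1L || is.na(object@regionLength) ||
      object@regionLength < 1L) {
    return("regionLength must be a single positive integer")
  }
  if (length(object@upstream) > 0L) {
    w <- Biostrings::width(object@upstream)
    if (any(w > object@regionLength)) {
      return(paste0("sequence for gene '", ids[which(w > object@regionLength)[1L]],
                    "' is longer than regionLength"))
    }
  }
  TRUE
})

#' MotifReport: discovered motifs with occurrences
#'
#' One row per discovered motif: IUPAC consensus, total occurrence count,
#' Sig value (-log10 of the Bonferroni-corrected exact binomial upper
#' tail; larger = more significant), coverage (fraction of the parent
#' gene set's genes with at least one occurrence) and the full occurrence
#' list. `nCandidates` records the multiple-testing denominator used when
#' the Sig values were computed; `nGenes` the size of the parent gene set.
#'
#' @slot consensus Character vector of IUPAC consensi.
#' @slot count Integer vector, total occurrences per motif.
#' @slot sig Numeric vector of Sig values.
#' @slot coverage Numeric vector in `[0, 1]`.
#' @slot occurrences A list, one data.frame per motif with columns
#'   `gene`, `distance` (bp upstream, 1-based), `strand` (`+`/`-`).
#' @slot nGenes Integer, number of genes in the parent GeneSet.
#' @slot regionLength Integer, upstream window length L of the parent set.
#' @slot nCandidates Numeric, candidates scored (Bonferroni denominator).
#' @export
setClass("MotifReport",
  representation(consensus = "character", count = "integer",
                 sig = "numeric", coverage = "numeric",
                 occurrences = "list", nGenes = "integer",
                 regionLength = "integer", nCandidates = "numeric"))

setValidity("MotifReport", function(object) {
  n <- length(object@consensus)
  if (length(object@count) != n || length(object@sig) != n ||
      length(object@coverage) != n || length(object@occurrences) != n) {
    return("consensus, count, sig, coverage and occurrences lengths differ")
  }
  for (i in seq_len(n)) {
    occ <- object@occurrences[[i]]
    if (!is.data.frame(occ) ||
        !all(c("gene", "distance", "strand") %in% names(occ))) {
      return("each occurrences element must be a data.frame with gene, distance, strand")
    }
    if (nrow(occ) != object@count[i]) {
      return(paste0("count mismatch for motif '", object@consensus[i],
                    "': count=", object@count[i], " but ",
                    nrow(occ), " occurrences"))
    }
    if (nrow(occ) && (any(occ$distance < 1L) ||
                      any(occ$distance > object@regionLength))) {
      return(paste0("occurrence distance outside [1, L] for motif '",
                    object@consensus[i], "'"))
    }
    if (nrow(occ) && !all(occ$strand %in% c("+", "-"))) {
      return("strand must be '+' or '-'")
    }
  }
  if (any(object@coverage < 0 | object@coverage > 1)) {
    return("coverage must lie in [0, 1]")
  }
  TRUE
})

#' ProfileMatrix: genes x (motif, quartile-bin) occurrence counts
#'
#' The clustering substrate: one row per gene, one column per
#' (motif, bin) pair holding how many occurrences of that motif fall in
#' that upstream bin. Bin 1 is nearest the gene start; columns are
#' labelled `"<consensus>@bin<i>"`, motifs in report order, bins
#' ascending.
#'
#' @slot counts Integer matrix, rownames gene ids, colnames
#'   `"<consensus>@bin<i>"`.
#' @slot motifs Character vector of consensi (column blocks, in order).
#' @slot nBins Integer number of bins B (default 4).
#' @slot binWidth Integer bin width in bp (L / B).
#' @export
setClass("ProfileMatrix",
  representation(counts = "matrix", motifs = "character",
                 nBins = "integer", binWidth = "integer"))

setValidity("ProfileMatrix", function(object) {
  if (ncol(object@counts) != length(object@motifs) * object@nBins) {
    return("counts must have one column per (motif, bin) pair")
  }
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (is.null(rownames(object@counts)) && nrow(object@counts) > 0L) {
    return("counts must have gene ids as rownames")
  }
  TRUE
})

#' LandscapeResult: layout, density terrain and peak clusters
#'
#' Output of the landscape clustering: final 2-D coordinates per gene, a
#' kernel-density surface over the plane, its retained peaks, and a
#' cluster label per gene (a peak id, or `"unclustered"` for genes whose
#' ascent ends at a sub-threshold maximum or whose profile is all zero).
#'
#' @slot coords Numeric matrix n x 2, rownames gene ids.
#' @slot density Numeric matrix (gridSize x gridSize) of density values.
#' @slot gridX,gridY Numeric vectors of grid-cell centre coordinates.
#' @slot peaks A data.frame with columns `peak`, `ix`, `iy`, `x`, `y`,
#'   `height`, `prominence`, sorted by height descending.
#' @slot labels Named character vector, gene id -> peak id or
#'   `"unclustered"`.
#' @slot params List of all parameters (including the seed) of the run.
#' @export
setClass("LandscapeResult",
  representation(coords = "matrix", density = "matrix",
                 gridX = "numeric", gridY = "numeric",
                 peaks = "data.frame", labels = "character",
                 params = "list"))

setValidity("LandscapeResult", function(object) {
  if (!setequal(rownames(object@coords), names(object@labels))) {
    return("labels must cover exactly the genes in coords")
  }
  lab <- setdiff(unique(object@labels), "unclustered")
  if (length(lab) && !all(lab %in% object@peaks$peak)) {
    return("every non-'unclustered' label must name an existing peak")
  }
  if (nrow(object@peaks) > 1L &&
      is.unsorted(rev(object@peaks$height), strictly = FALSE)) {
    return("peaks must be sorted by height descending")
  }
  TRUE
})

#' Background: null sequence model for motif significance
#'
#' An order-0 (i.i.d. base frequencies) or order-1 (first-order Markov)
#' model of upstream sequence composition, used both as the significance
#' null in discovery and as the generator of synthetic background
#' promoters.
#'
#' @slot order Integer 0 or 1.
#' @slot freq Numeric length-4 base frequency vector (A, C, G, T); for
#'   order 1 this is the initial/marginal distribution.
#' @slot transition 4 x 4 row-stochastic transition matrix (order 1), or
#'   NULL for order 0.
#' @export
setClass("Background",
  representation(order = "integer", freq = "numeric", transition = "ANY"))

setValidity("Background", function(object) {
  if (!object@order %in% c(0L, 1L)) return("order must be 0 or 1")
  if (length(object@freq) != 4L || abs(sum(object@freq) - 1) > 1e-9 ||
      any(object@freq < 0)) {
    return("freq must be 4 non-negative values summing to 1")
  }
  if (object@order == 1L) {
    tr <- object@transition
    if (!is.matrix(tr) || !all(dim(tr) == c(4L, 4L)) ||
        any(abs(rowSums(tr) - 1) > 1e-9) || any(tr < 0)) {
      return("order-1 background needs a 4x4 row-stochastic transition matrix")
    }
  }
  TRUE
})

#' FixtureBundle: a fully synthetic benchmark instance
#'
#' Everything one pipeline run needs, generated from a seed: the gene set
#' with planted motifs, ground-truth subset labels, an annotation table,
#' a motif database of the planted motifs under known names, and a
#' manifest of all parameters sufficient to regenerate the bundle
#' bit-identically.
#'
#' @slot genes A [GeneSet-class].
#' @slot truth Named character vector, gene id -> subset id.
#' @slot annotation Named list, gene id -> character vector of categories.
#' @slot motifDb Named list of PWMs (4 x w probability matrices).
#' @slot manifest List of all generator parameters, including the seed.
#' @export
setClass("FixtureBundle",
  representation(genes = "GeneSet", truth = "character",
                 annotation = "list", motifDb = "list", manifest = "list"))

setValidity("FixtureBundle", function(object) {
  if (!setequal(names(object@truth), geneIds(object@genes))) {
    return("truth labels must cover exactly the genes of the GeneSet")
  }
  TRUE
})
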