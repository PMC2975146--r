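#' Construct a Background sequence model
#'
#' @param freq Length-4 base frequencies (A, C, G, T); default uniform.
#' @param order Markov order, 0 or 1.
#' @param transition 4 x 4 row-stochastic transition matrix, required for
#'   order 1.
#' @return A [Background-class].
#' @examples
#' background()                     # uniform i.i.d.
#' background(c(0.3, 0.2, 0.2, 0.3))
#' @export
background <- function(freq = rep(0.25, 4), order = 0L, transition = NULL) {
  freq <- as.numeric(freq)
  names(freq) <- c("A", "C", "G", "T")
  if (!is.null(transition)) {
    dimnames(transition) <- list(c("A", "C", "G", "T"),
                                 c("A", "C", "G", "T"))
  }
  new("Background", order = as.integer(order), freq = freq,
      transition = transition)
}

#' Estimate a Background from a GeneSet
#'
#' Order 0 tallies base frequencies over all sequences (N excluded);
#' order 1 additionally tallies dinucleotide transitions (pairs spanning
#' an N excluded). A pseudocount of 1 per cell keeps all frequencies
#' positive.
#'
#' @param genes A [GeneSet-class].
#' @param order Markov order, 0 or 1.
#' @return A [Background-class].
#' @export
estimateBackground <- function(genes, order = 0L) {
  stopifnot(is(genes, "GeneSet"))
  if (length(genes) == 0L) {
    stop("cannot estimate a background from an empty GeneSet",
         call. = FALSE)
  }
  seqs <- upstreamSeqs(genes)
  counts <- colSums(Biostrings::letterFrequency(seqs, c("A", "C", "G", "T")))
  counts <- counts + 1
  freq <- counts / sum(counts)
  if (order == 0L) return(background(freq, order = 0L))
  di <- colSums(Biostrings::dinucleotideFrequency(seqs))
  tr <- matrix(di, nrow = 4L, byrow = TRUE,
               dimnames = list(c("A", "C", "G", "T"),
                               c("A", "C", "G", "T"))) + 1
  tr <- tr / rowSums(tr)
  background(freq, order = 1L, transition = tr)
}

#' Probability that the background emits a consensus match
#'
#' The probability that a string drawn from the background at a fixed
#' position matches the IUPAC consensus: for order 0 the product over
#' positions of the summed frequencies of the admitted bases (N
#' contributes a factor of 1); for order 1 the corresponding
#' forward-chain sum over all concrete strings in the consensus set.
#'
#' @param consensus IUPAC consensus string.
#' @param bg A [Background-class].
#' @return A probability in (0, 1].
#' @examples
#' wordProbability("A", background())   # 0.25
#' wordProbability("WS", background())  # 0.25
#' wordProbability("N", background())   # 1
#' @export
wordProbability <- function(consensus, bg) {
  chars <- .checkConsensus(consensus)
  stopifnot(is(bg, "Background"))
  sets <- lapply(chars, iupacBases)
  if (bg@order == 0L) {
    return(prod(vapply(sets, function(b) sum(bg@freq[b]), 0)))
  }
  ## order 1: v[b] = P(prefix matching consensus so far, last base = b)
  v <- numeric(4L); names(v) <- c("A", "C", "G", "T")
  v[sets[[1L]]] <- bg@freq[sets[[1L]]]
  for (i in seq_along(sets)[-1L]) {
    v <- as.numeric(v %*% bg@transition)
    names(v) <- c("A", "C", "G", "T")
    keep <- names(v) %in% sets[[i]]
    v[!keep] <- 0
  }
  sum(v)
}
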