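## Motif discovery: enumerate candidate consensi of three kinds (exact
## words, degenerate IUPAC generalizations, gapped/bipartite half-site
## pairs), score each by a Bonferroni-corrected exact binomial tail
## against a background model, and keep the best scorers. When the same
## consensus arises from more than one candidate kind the maximum Sig is
## kept (ensemble max rule).

## N bases in input sequences are masked to '-' before matching, so no
## consensus symbol (not even N) ever matches a masked base.
.maskN <- function(seqs) {
  Biostrings::DNAStringSet(chartr("N", "-", as.character(seqs)))
}

#' Scan a gene set for exact IUPAC matches of a consensus
#'
#' Returns every (overlapping) match of the consensus in every gene's
#' upstream sequence. With `bothStrands`, matches of the reverse
#' complement are reported with strand `-`. Distances follow the package
#' convention: 1-based bp from the gene start (right end of the stored
#' sequence) to the match base closest to the start. A site matched on
#' both strands (palindromic consensus) is reported once, with strand
#' `+`. N bases in the sequences are never matched by any symbol.
#'
#' @param consensus IUPAC consensus string (N allowed, e.g. as the gap
#'   filler of a bipartite motif).
#' @param genes A [GeneSet-class].
#' @param bothStrands Scan the reverse strand too (default TRUE).
#' @return A data.frame with columns `gene`, `distance`, `strand`,
#'   ordered by gene (input order), then distance, then strand.
#' @examples
#' gs <- GeneSet(c(g1 = "TTACGCGTTT"), regionLength = 10)
#' scanConsensus("ACGCGT", gs)
#' @export
scanConsensus <- function(consensus, genes, bothStrands = TRUE) {
  .checkConsensus(consensus)
  stopifnot(is(genes, "GeneSet"))
  pat <- toupper(consensus)
  rcPat <- revcompConsensus(pat)
  masked <- .maskN(upstreamSeqs(genes))
  ids <- geneIds(genes)
  lens <- Biostrings::width(masked)
  fx <- c(pattern = FALSE, subject = TRUE)
  ## vmatchPattern fails on subjects shorter than the pattern; guard
  okLen <- lens >= nchar(pat)
  geneIdx <- integer(0); endPos <- integer(0); strand <- character(0)
  if (any(okLen)) {
    sub <- masked[okLen]
    mapBack <- which(okLen)
    eP <- IRanges::end(Biostrings::vmatchPattern(pat, sub, fixed = fx))
    gP <- rep(mapBack, lengths(eP))
    eP <- unlist(eP, use.names = FALSE)
    eM <- integer(0); gM <- integer(0)
    if (bothStrands) {
      eMl <- IRanges::end(Biostrings::vmatchPattern(rcPat, sub,
                                                    fixed = fx))
      gM <- rep(mapBack, lengths(eMl))
      eM <- unlist(eMl, use.names = FALSE)
      ## same width and end => same site; palindromic sites keep "+"
      dup <- paste(gM, eM) %in% paste(gP, eP)
      eM <- eM[!dup]; gM <- gM[!dup]
    }
    geneIdx <- c(gP, gM)
    endPos <- c(eP, eM)
    strand <- c(rep("+", length(eP)), rep("-", length(eM)))
  }
  d <- lens[geneIdx] - endPos + 1L
  o <- order(geneIdx, d, strand)
  data.frame(gene = ids[geneIdx][o], distance = as.integer(d[o]),
             strand = strand[o], stringsAsFactors = FALSE)
}

#' Sig value: Bonferroni-corrected binomial-tail significance
#'
#' `Sig = -log10(min(1, C * P[X >= observed]))` with
#' `X ~ Binomial(nPositions, p0)`. Sig is 0 for anything not significant
#' after correcting for the `C` candidates scored in the run, grows with
#' over-representation, and is monotone non-decreasing in the observed
#' count. Computed in log space, so very significant motifs do not
#' underflow.
#'
#' @param observed Observed occurrence count(s), non-negative.
#' @param nPositions Total scannable positions across all genes (times 2
#'   if both strands are scanned).
#' @param p0 Per-position match probability under the background.
#' @param nCandidates Bonferroni denominator C (candidates scored).
#' @return Numeric Sig value(s), `>= 0`.
#' @examples
#' sigValue(10, 10, 0.1, 1)   # -log10(0.1^10) = 10
#' sigValue(0, 100, 0.01, 5)  # 0
#' @export
sigValue <- function(observed, nPositions, p0, nCandidates) {
  if (any(observed < 0)) stop("observed count must be >= 0", call. = FALSE)
  if (any(observed > nPositions)) {
    stop("observed count exceeds the number of scannable positions",
         call. = FALSE)
  }
  if (any(p0 <= 0) || any(p0 > 1)) {
    stop("p0 must lie in (0, 1]", call. = FALSE)
  }
  if (any(nCandidates < 1)) stop("nCandidates must be >= 1", call. = FALSE)
  logP <- pbinom(observed - 1, nPositions, p0, lower.tail = FALSE,
                 log.p = TRUE) / log(10)
  pmax(0, -(log10(nCandidates) + logP))
}

#' Candidate-space settings for motif discovery
#'
#' Bundles the enumeration bounds for the three candidate kinds: exact
#' words of length `kMin..kMax`; degenerate variants of over-represented
#' exact words with up to `maxDegeneratePositions` two-fold IUPAC symbols
#' (R, Y, S, W, K, M); and bipartite pairs of exact half-sites of length
#' `halfMin..halfMax` separated by `gapMin..gapMax` unconstrained (N)
#' positions. The seeding caps bound the combinatorial space: degenerate
#' variants are generated from the `seedsPerLength` most over-represented
#' exact words per length that pass a loose uncorrected significance
#' pre-filter (`preFilterSig` in -log10 units), and bipartite pairs from
#' the `halfSeeds` most frequent half-sites per half length.
#'
#' @param kMin,kMax Exact-word length bounds (defaults 5, 8).
#' @param maxDegeneratePositions Max two-fold symbols per degenerate
#'   candidate (default 3).
#' @param gapMin,gapMax Bipartite gap bounds in bp (defaults 4, 10).
#' @param halfMin,halfMax Bipartite half-site length bounds (3, 5).
#' @param seedsPerLength Exact seeds per word length for degenerate
#'   generalization (default 4).
#' @param halfSeeds Half-site seeds per half length (default 4).
#' @param maxDegenerateCandidates Cap on degenerate variants scored per
#'   run (default 2000).
#' @param preFilterSig Uncorrected -log10 p threshold a seed word must
#'   pass (default 3).
#' @return A named list of class `"CandidateSpec"`.
#' @export
candidateSpec <- function(kMin = 5L, kMax = 8L,
                          maxDegeneratePositions = 3L,
                          gapMin = 4L, gapMax = 10L,
                          halfMin = 3L, halfMax = 5L,
                          seedsPerLength = 4L, halfSeeds = 4L,
                          maxDegenerateCandidates = 2000L,
                          preFilterSig = 3) {
  stopifnot(kMin >= 1L, kMin <= kMax, gapMin <= gapMax,
            halfMin >= 1L, halfMin <= halfMax,
            maxDegeneratePositions >= 0L)
  structure(list(kMin = as.integer(kMin), kMax = as.integer(kMax),
                 maxDegeneratePositions = as.integer(maxDegeneratePositions),
                 gapMin = as.integer(gapMin), gapMax = as.integer(gapMax),
                 halfMin = as.integer(halfMin), halfMax = as.integer(halfMax),
                 seedsPerLength = as.integer(seedsPerLength),
                 halfSeeds = as.integer(halfSeeds),
                 maxDegenerateCandidates = as.integer(maxDegenerateCandidates),
                 preFilterSig = preFilterSig),
            class = "CandidateSpec")
}

## exact-word counts over both strands with the palindrome rule: a
## self-reverse-complementary word's minus-strand sites coincide with its
## plus-strand sites and are counted once. Returns forward and
## reverse-strand tables plus the combined total.
.exactWordCounts <- function(fwdMasked, rcMasked, k, bothStrands) {
  cf <- colSums(Biostrings::oligonucleotideFrequency(fwdMasked, k))
  if (!bothStrands) {
    return(list(fwd = cf, rev = NULL, total = cf))
  }
  cr <- colSums(Biostrings::oligonucleotideFrequency(rcMasked, k))
  words <- names(cf)
  rcWords <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(words)))
  total <- cf + cr
  pal <- words == rcWords
  total[pal] <- cf[pal]
  list(fwd = cf, rev = cr, total = total)
}

## concrete ACGT expansions of a consensus containing 2-fold symbols
.expandConsensus <- function(word) {
  sets <- lapply(strsplit(word, "", fixed = TRUE)[[1L]], iupacBases)
  do.call(paste0, expand.grid(sets, stringsAsFactors = FALSE))
}

## count a same-width degenerate word from the exact-word tables: its
## occurrences are the summed occurrences of its concrete expansions.
## A site whose concrete word e has revcomp(e) also in the expansion
## set matches the consensus on both strands and must be counted once
## (matching the scanConsensus dedup), so those sites are subtracted.
.degenerateCountFromTables <- function(word, tabs, bothStrands) {
  exps <- .expandConsensus(word)
  nf <- sum(tabs$fwd[exps])
  if (!bothStrands) return(nf)
  rcExps <- vapply(exps, revcompConsensus, "")
  dbl <- sum(tabs$fwd[exps[rcExps %in% exps]])
  nf + sum(tabs$rev[exps]) - dbl
}

## start positions of an exact word in each (masked) sequence, all
## overlapping occurrences, via vectorized substring comparison
.wordStarts <- function(word, seqChars) {
  k <- nchar(word)
  lapply(seqChars, function(ch) {
    n <- length(ch)
    if (n < k) return(integer(0))
    hit <- ch[seq_len(n - k + 1L)] == substr(word, 1L, 1L)
    for (j in seq_len(k - 1L)) {
      hit <- hit & ch[seq_len(n - k + 1L) + j] == substr(word, j + 1L,
                                                         j + 1L)
    }
    which(hit)
  })
}

## order-0 match probability for a vector of exact ACGT words
.exactWordP0 <- function(words, bg) {
  if (bg@order == 0L) {
    lf <- log(bg@freq)
    lp <- numeric(length(words))
    for (b in c("A", "C", "G", "T")) {
      nb <- nchar(words) - nchar(gsub(b, "", words, fixed = TRUE))
      lp <- lp + nb * lf[[b]]
    }
    exp(lp)
  } else {
    vapply(words, wordProbability, 0, bg = bg)
  }
}

## count occurrences of one (possibly degenerate/gapped) consensus
.consensusCount <- function(pat, fwdMasked, bothStrands) {
  fx <- c(pattern = FALSE, subject = TRUE)
  n <- sum(Biostrings::vcountPattern(pat, fwdMasked, fixed = fx))
  if (!bothStrands) return(n)
  rc <- revcompConsensus(pat)
  if (rc == pat) return(n)
  n + sum(Biostrings::vcountPattern(rc, fwdMasked, fixed = fx))
}

.TWOFOLD_FOR_BASE <- list(
  A = c("R", "W", "M"), C = c("Y", "S", "M"),
  G = c("R", "S", "K"), T = c("Y", "W", "K"))

## degenerate variants of a seed word with 1..maxDeg generalized positions
.degenerateVariants <- function(word, maxDeg) {
  chars <- strsplit(word, "", fixed = TRUE)[[1L]]
  k <- length(chars)
  out <- character(0)
  for (j in seq_len(min(maxDeg, k))) {
    posSets <- utils::combn(k, j, simplify = FALSE)
    for (ps in posSets) {
      opts <- lapply(chars[ps], function(b) .TWOFOLD_FOR_BASE[[b]])
      grid <- expand.grid(opts, stringsAsFactors = FALSE)
      for (r in seq_len(nrow(grid))) {
        v <- chars
        v[ps] <- as.character(grid[r, ])
        out[length(out) + 1L] <- paste(v, collapse = "")
      }
    }
  }
  unique(out)
}

#' Discover statistically significant motifs in a gene set
#'
#' Enumerates exact, degenerate and bipartite candidate consensi (see
#' [candidateSpec()]), scores every candidate with [sigValue()] against
#' the background, keeps the maximum Sig when the same consensus arises
#' from several kinds, and returns the top motifs with full occurrence
#' lists. The Bonferroni denominator C is the total number of candidates
#' actually scored in the run and is recorded in the report. Output
#' order: Sig descending, then consensus lexicographically; the final
#' count, coverage and Sig of each reported motif are recomputed from a
#' full [scanConsensus()] re-scan.
#'
#' @param genes A [GeneSet-class] with at least 2 genes.
#' @param spec A [candidateSpec()].
#' @param bg A [Background-class]; default estimated from `genes`
#'   (order 0).
#' @param topM Maximum motifs returned (default 25).
#' @param minSig Minimum Sig to report (default 0, i.e. any candidate
#'   significant after correction).
#' @param bothStrands Scan both strands (default TRUE).
#' @return A [MotifReport-class].
#' @export
discoverMotifs <- function(genes, spec = candidateSpec(), bg = NULL,
                           topM = 25L, minSig = 0, bothStrands = TRUE) {
  stopifnot(is(genes, "GeneSet"), inherits(spec, "CandidateSpec"),
            topM >= 1L)
  if (length(genes) < 2L) {
    stop("motif discovery needs at least 2 genes", call. = FALSE)
  }
  if (is.null(bg)) bg <- estimateBackground(genes, order = 0L)
  seqs <- upstreamSeqs(genes)
  fwdMasked <- .maskN(seqs)
  rcMasked <- Biostrings::reverseComplement(fwdMasked)
  w <- Biostrings::width(seqs)
  ## a self-reverse-complementary consensus matches a site on both
  ## strands at once; its sites are reported once, so the number of
  ## Bernoulli trials is the number of windows, not twice that
  nPosFor <- function(width, selfRc = FALSE) {
    f <- if (bothStrands && !selfRc) 2L else 1L
    sum(pmax(w - width + 1L, 0L)) * f
  }

  cand <- list()   # per kind: data.frame(consensus, count, p0, width)
  nScored <- 0

  ## ---- exact words ----
  seedPool <- list()
  tables <- list()
  allK <- sort(unique(c(spec$kMin:spec$kMax, spec$halfMin:spec$halfMax)))
  for (k in allK) {
    tabs <- .exactWordCounts(fwdMasked, rcMasked, k, bothStrands)
    tables[[as.character(k)]] <- tabs
    counts <- tabs$total
    isCand <- k >= spec$kMin && k <= spec$kMax
    if (isCand) nScored <- nScored + 4^k
    keep <- counts >= 2L
    words <- names(counts)[keep]
    cnt <- unname(counts[keep])
    if (!length(words)) next
    p0 <- .exactWordP0(words, bg)
    selfRc <- words == vapply(words, revcompConsensus, "")
    np <- ifelse(selfRc, nPosFor(k, selfRc = TRUE), nPosFor(k))
    rawSig <- -pbinom(cnt - 1, np, pmin(p0, 1), lower.tail = FALSE,
                      log.p = TRUE) / log(10)
    df <- data.frame(consensus = words, count = cnt, p0 = p0,
                     width = k, rawSig = rawSig, stringsAsFactors = FALSE)
    seedPool[[as.character(k)]] <- df
    if (isCand) {
      cand[[length(cand) + 1L]] <- df[, c("consensus", "count", "p0", "width")]
    }
  }

  ## ---- degenerate variants of over-represented exact words ----
  degWords <- character(0)
  for (k in spec$kMin:spec$kMax) {
    df <- seedPool[[as.character(k)]]
    if (is.null(df)) next
    df <- df[df$rawSig >= spec$preFilterSig, , drop = FALSE]
    if (!nrow(df)) next
    df <- df[order(-df$rawSig, df$consensus), , drop = FALSE]
    seeds <- head(df$consensus, spec$seedsPerLength)
    for (s in seeds) {
      room <- spec$maxDegenerateCandidates - length(degWords)
      if (room <= 0L) break
      v <- .degenerateVariants(s, spec$maxDegeneratePositions)
      degWords <- c(degWords, head(setdiff(v, degWords), room))
    }
  }
  if (length(degWords)) {
    ## a same-width degenerate word's count is the summed count of its
    ## concrete expansions, read off the exact-word tables
    cnt <- vapply(degWords, function(wd) {
      .degenerateCountFromTables(wd, tables[[as.character(nchar(wd))]],
                                 bothStrands)
    }, 0)
    p0 <- vapply(degWords, wordProbability, 0, bg = bg)
    cand[[length(cand) + 1L]] <- data.frame(
      consensus = degWords, count = as.integer(cnt), p0 = p0,
      width = nchar(degWords), stringsAsFactors = FALSE)
    nScored <- nScored + length(degWords)
  }

  ## ---- bipartite half-site pairs ----
  halves <- character(0)
  for (l in spec$halfMin:spec$halfMax) {
    df <- seedPool[[as.character(l)]]
    if (is.null(df)) next
    df <- df[order(-df$count, df$consensus), , drop = FALSE]
    halves <- c(halves, head(df$consensus, spec$halfSeeds))
  }
  if (length(halves) >= 1L) {
    combos <- expand.grid(h1 = halves, h2 = halves,
                          gap = spec$gapMin:spec$gapMax,
                          stringsAsFactors = FALSE)
    pats <- paste0(combos$h1, strrep("N", combos$gap), combos$h2)
    keep <- !duplicated(pats)
    combos <- combos[keep, , drop = FALSE]
    pats <- pats[keep]
    ## count joint occurrences by joining half-site start positions
    seqChars <- strsplit(as.character(fwdMasked), "", fixed = TRUE)
    needed <- unique(c(combos$h1, combos$h2,
                       if (bothStrands) vapply(c(combos$h1, combos$h2),
                                               revcompConsensus, "")))
    starts <- lapply(stats::setNames(needed, needed), .wordStarts,
                     seqChars = seqChars)
    pairCount <- function(w1, w2, shift) {
      s1 <- starts[[w1]]; s2 <- starts[[w2]]
      sum(vapply(seq_along(s1), function(i) {
        sum((s1[[i]] + shift) %in% s2[[i]])
      }, 0L))
    }
    cnt <- vapply(seq_len(nrow(combos)), function(r) {
      h1 <- combos$h1[r]; h2 <- combos$h2[r]; gap <- combos$gap[r]
      n <- pairCount(h1, h2, nchar(h1) + gap)
      if (bothStrands && revcompConsensus(pats[r]) != pats[r]) {
        ## minus strand: rc(h2) .. gap .. rc(h1) on the forward sequence
        rh1 <- revcompConsensus(h1); rh2 <- revcompConsensus(h2)
        n <- n + pairCount(rh2, rh1, nchar(rh2) + gap)
      }
      n
    }, 0L)
    sel <- cnt >= 2L
    nScored <- nScored + length(pats)
    if (any(sel)) {
      p0 <- .exactWordP0(combos$h1[sel], bg) * .exactWordP0(combos$h2[sel], bg)
      cand[[length(cand) + 1L]] <- data.frame(
        consensus = pats[sel], count = as.integer(cnt[sel]), p0 = p0,
        width = nchar(pats[sel]), stringsAsFactors = FALSE)
    }
  }

  all <- do.call(rbind, cand)
  report0 <- function() {
    new("MotifReport", consensus = character(0), count = integer(0),
        sig = numeric(0), coverage = numeric(0), occurrences = list(),
        nGenes = length(genes), regionLength = regionLength(genes),
        nCandidates = max(nScored, 1))
  }
  if (is.null(all) || !nrow(all)) return(report0())

  C <- max(nScored, 1)
  allSelfRc <- all$consensus == vapply(all$consensus, revcompConsensus, "")
  all$np <- mapply(nPosFor, all$width, allSelfRc)
  all$sig <- sigValue(all$count, all$np, pmin(all$p0, 1), C)
  ## ensemble rule: same consensus from several kinds keeps the max Sig
  all <- all[order(-all$sig, all$consensus), , drop = FALSE]
  all <- all[!duplicated(all$consensus), , drop = FALSE]
  all <- all[all$sig >= minSig & all$sig > 0, , drop = FALSE]
  if (!nrow(all)) return(report0())
  all <- head(all, topM)

  ## finalists: occurrences, count, coverage, Sig from a full re-scan
  occ <- lapply(all$consensus, scanConsensus, genes = genes,
                bothStrands = bothStrands)
  count <- vapply(occ, nrow, 0L)
  coverage <- vapply(occ, function(o) length(unique(o$gene)), 0L) /
    length(genes)
  sig <- sigValue(count, all$np, pmin(all$p0, 1), C)
  o <- order(-sig, all$consensus)
  keep <- sig[o] >= minSig & sig[o] > 0
  o <- o[keep]
  new("MotifReport", consensus = all$consensus[o],
      count = count[o], sig = sig[o], coverage = coverage[o],
      occurrences = occ[o], nGenes = length(genes),
      regionLength = regionLength(genes), nCandidates = C)
}
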