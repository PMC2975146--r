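## Independent oracles used to cross-check the implementation. These are
## deliberately written with plain-R loops and closed forms, sharing no
## code with the package internals they verify.

.oracleIupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

.oracleRevcomp <- function(consensus) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
            S = "S", W = "W", K = "M", M = "K", B = "V", D = "H",
            H = "D", V = "B", N = "N")
  paste(rev(comp[strsplit(consensus, "")[[1]]]), collapse = "")
}

## brute-force scanner: slides a window, checks each IUPAC symbol
## against the subject character (subject N matches nothing), dedupes
## sites matched on both strands keeping "+"
bruteScan <- function(consensus, genes, bothStrands = TRUE) {
  pats <- list(`+` = consensus)
  if (bothStrands) pats$`-` <- .oracleRevcomp(consensus)
  ids <- geneIds(genes)
  seqs <- as.character(upstreamSeqs(genes))
  out <- data.frame(gene = character(0), distance = integer(0),
                    strand = character(0), stringsAsFactors = FALSE)
  for (gi in seq_along(ids)) {
    ch <- strsplit(seqs[gi], "")[[1]]
    len <- length(ch)
    seen <- integer(0)
    for (strand in names(pats)) {
      pc <- strsplit(pats[[strand]], "")[[1]]
      w <- length(pc)
      if (len < w) next
      for (s in seq_len(len - w + 1)) {
        hit <- TRUE
        for (j in seq_len(w)) {
          if (ch[s + j - 1] == "N" ||
              !(ch[s + j - 1] %in% .oracleIupac[[pc[j]]])) {
            hit <- FALSE
            break
          }
        }
        if (hit && !(s %in% seen)) {
          seen <- c(seen, s)
          out <- rbind(out, data.frame(
            gene = ids[gi], distance = as.integer(len - (s + w - 1) + 1),
            strand = strand, stringsAsFactors = FALSE))
        }
      }
    }
  }
  out <- out[order(match(out$gene, ids), out$distance, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

## exact binomial upper tail by direct log-space term summation
binomTailOracle <- function(obs, n, p) {
  if (obs <= 0) return(1)
  i <- obs:n
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

## exact hypergeometric upper tail by combinatorial term summation
hyperTailOracle <- function(x, K, n, N) {
  if (x <= 0) return(1)
  i <- x:min(K, n)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

## independent exhaustive PWM alignment: returns the score table over
## every offset and orientation with overlap >= minOv
bruteAlignTable <- function(query, target) {
  wq <- ncol(query); wt <- ncol(target)
  minOv <- min(4, wq, wt)
  rc <- function(m) m[4:1, rev(seq_len(ncol(m))), drop = FALSE]
  rows <- list()
  for (orient in c("+", "-")) {
    tg <- if (orient == "+") target else rc(target)
    for (off in seq(-wt + 1, wq - 1)) {
      q1 <- max(1, 1 + off); q2 <- min(wq, wt + off)
      if (q2 - q1 + 1 < minOv) next
      tot <- 0
      for (q in q1:q2) {
        tot <- tot + sqrt(sum((query[, q] - tg[, q - off])^2))
      }
      rows[[length(rows) + 1]] <- data.frame(
        offset = off, orientation = orient, overlap = q2 - q1 + 1,
        score = tot / (q2 - q1 + 1))
    }
  }
  do.call(rbind, rows)
}

## random valid PWM of a given width
randomPwm <- function(w) {
  m <- matrix(stats::rexp(4 * w), nrow = 4)
  m <- sweep(m, 2, colSums(m), "/")
  rownames(m) <- c("A", "C", "G", "T")
  m
}

## tiny GeneSet literal
gs <- function(..., L = NULL) {
  seqs <- c(...)
  if (is.null(L)) L <- max(nchar(seqs))
  GeneSet(seqs, regionLength = L)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
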