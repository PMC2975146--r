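## IUPAC nucleotide code tables and small deterministic helpers shared
## across modules.

.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Bases admitted by one IUPAC symbol
#'
#' @param symbol A single IUPAC nucleotide character.
#' @return Character vector of the concrete bases (subset of A, C, G, T)
#'   the symbol admits.
#' @examples
#' iupacBases("W")
#' @export
iupacBases <- function(symbol) {
  b <- .IUPAC[[toupper(symbol)]]
  if (is.null(b)) {
    stop("invalid IUPAC symbol: '", symbol, "'", call. = FALSE)
  }
  b
}

.checkConsensus <- function(consensus) {
  if (!is.character(consensus) || length(consensus) != 1L ||
      is.na(consensus) || !nzchar(consensus)) {
    stop("consensus must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(toupper(consensus), "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(.IUPAC))
  if (length(bad)) {
    stop("invalid IUPAC character '", chars[bad[1L]],
         "' at position ", bad[1L], " of consensus '", consensus, "'",
         call. = FALSE)
  }
  chars
}

#' Reverse complement of an IUPAC consensus string
#'
#' @param consensus IUPAC consensus string.
#' @return The reverse-complemented consensus, uppercased.
#' @examples
#' revcompConsensus("AYTNNCGT")
#' @export
revcompConsensus <- function(consensus) {
  chars <- .checkConsensus(consensus)
  paste(rev(unname(.IUPAC_COMPLEMENT[chars])), collapse = "")
}

## ---- deterministic per-string uniforms (MINSTD with Schrage) -----------

## Used to key layout initial positions to gene ids so that results are
## invariant to input order. Not a statistical RNG for simulation.
.MINSTD_M <- 2147483647
.MINSTD_A <- 16807
.MINSTD_Q <- 127773
.MINSTD_R <- 2836

.minstdNext <- function(x) {
  hi <- x %/% .MINSTD_Q
  lo <- x %% .MINSTD_Q
  t <- .MINSTD_A * lo - .MINSTD_R * hi
  if (t <= 0) t <- t + .MINSTD_M
  t
}

.stringHash <- function(s) {
  b <- utf8ToInt(s)
  h <- 5381
  for (x in b) h <- (h * 131 + x) %% .MINSTD_M
  h
}

## n uniforms in (0,1) keyed jointly by a string and an integer seed
.keyedUniforms <- function(s, seed, n = 2L) {
  x <- (.stringHash(s) + (as.numeric(seed) %% .MINSTD_M) * 48271) %%
    (.MINSTD_M - 1) + 1
  ## burn-in decorrelates nearby seeds/ids
  for (i in 1:3) x <- .minstdNext(x)
  u <- numeric(n)
  for (i in seq_len(n)) {
    x <- .minstdNext(x)
    u[i] <- x / .MINSTD_M
  }
  u
}

## Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
.withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

## derive a child seed from a parent seed and a label, kept < 2^31
.childSeed <- function(seed, label) {
  as.integer(.stringHash(paste0(label, ":", seed)) %% 2147483647)
}
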