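## Matching discovered consensus motifs against a database of known
## binding-site matrices: exhaustive offset/orientation alignment under
## a per-column Euclidean distance, plus an empirical E-value from a
## column-shuffle null.

#' Convert an IUPAC consensus to a position weight matrix
#'
#' Per column, the bases admitted by the symbol share
#' `1 - nDisallowed * pseudo` equally and every disallowed base gets
#' `pseudo`; `N` gives a uniform column. Columns sum to 1 exactly.
#'
#' @param consensus IUPAC consensus string.
#' @param pseudo Pseudo-probability for disallowed bases, in
#'   `[0, 0.25)` (default 0.01).
#' @return A 4 x w matrix, rows A, C, G, T.
#' @examples
#' consensusToPwm("W", pseudo = 0.01)[, 1]  # 0.49 0.01 0.01 0.49
#' @export
consensusToPwm <- function(consensus, pseudo = 0.01) {
  chars <- .checkConsensus(consensus)
  stopifnot(pseudo >= 0, pseudo < 0.25)
  bases <- c("A", "C", "G", "T")
  pwm <- vapply(chars, function(s) {
    adm <- iupacBases(s)
    off <- setdiff(bases, adm)
    col <- numeric(4L); names(col) <- bases
    col[off] <- pseudo
    col[adm] <- (1 - length(off) * pseudo) / length(adm)
    col
  }, numeric(4L))
  dim(pwm) <- c(4L, length(chars))
  rownames(pwm) <- bases
  pwm
}

#' Reverse complement of a PWM
#'
#' @param pwm A 4 x w matrix with rows A, C, G, T.
#' @return The reverse-complement PWM (columns reversed, A/T and C/G
#'   rows swapped).
#' @export
revcompPwm <- function(pwm) {
  out <- pwm[c(4L, 3L, 2L, 1L), rev(seq_len(ncol(pwm))), drop = FALSE]
  rownames(out) <- c("A", "C", "G", "T")
  out
}

#' Best gapless alignment score between two PWMs
#'
#' Slides the target over the query at every offset with overlap of at
#' least `min(4, min(widths))` columns, in both orientations, and
#' returns the minimum mean per-column Euclidean distance over the
#' overlap (0 = identical columns at the best alignment). Ties are
#' broken by larger overlap, then smaller absolute offset, then
#' orientation `+`.
#'
#' @param query,target 4 x w probability matrices.
#' @return A list with `score`, `offset` (target start relative to
#'   query start), `orientation` (`"+"` or `"-"`) and `overlap`.
#' @export
pwmAlignScore <- function(query, target) {
  wq <- ncol(query); wt <- ncol(target)
  stopifnot(wq >= 1L, wt >= 1L)
  minOv <- min(4L, wq, wt)
  best <- NULL
  for (orient in c("+", "-")) {
    tg <- if (orient == "+") target else revcompPwm(target)
    for (off in (-wt + 1L):(wq - 1L)) {
      qIdx <- max(1L, 1L + off):min(wq, wt + off)
      tIdx <- qIdx - off
      ov <- length(qIdx)
      if (ov < minOv) next
      d <- sqrt(colSums((query[, qIdx, drop = FALSE] -
                           tg[, tIdx, drop = FALSE])^2))
      score <- mean(d)
      cand <- list(score = score, offset = off, orientation = orient,
                   overlap = ov)
      if (is.null(best) ||
          score < best$score - 1e-12 ||
          (abs(score - best$score) <= 1e-12 &&
           (ov > best$overlap ||
            (ov == best$overlap &&
             (abs(off) < abs(best$offset) ||
              (abs(off) == abs(best$offset) &&
               orient == "+" && best$orientation == "-")))))) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    stop("no alignment with overlap >= ", minOv, " columns", call. = FALSE)
  }
  best
}

#' Empirical E-values against a motif database
#'
#' For each database entry the query's observed alignment score is
#' compared with the scores against `nShuffles` column-shuffled versions
#' of that entry (a seeded permutation null that preserves column
#' composition). The E-value is
#' `(1 + #{null <= observed}) / (nShuffles + 1) * dbSize`, i.e. the
#' expected number of equal-or-better matches in a database of this
#' size under the null; its attainable minimum is
#' `dbSize / (nShuffles + 1)`.
#'
#' @param query A 4 x w PWM.
#' @param db Named list of PWMs.
#' @param nShuffles Shuffles per target (default 500, minimum 100).
#' @param seed Integer seed; results are deterministic given the seed.
#' @return A data.frame `target`, `score`, `offset`, `orientation`,
#'   `evalue`, in database order.
#' @export
empiricalEvalue <- function(query, db, nShuffles = 500L, seed = 1L) {
  if (!length(db)) stop("empty motif database", call. = FALSE)
  if (nShuffles < 100L) stop("nShuffles must be >= 100", call. = FALSE)
  dbSize <- length(db)
  out <- vector("list", dbSize)
  for (t in seq_along(db)) {
    target <- db[[t]]
    obs <- pwmAlignScore(query, target)
    nBetter <- .withSeed(.childSeed(seed, names(db)[t]), {
      hits <- 0L
      for (s in seq_len(nShuffles)) {
        perm <- sample.int(ncol(target))
        nullScore <- pwmAlignScore(query,
                                   target[, perm, drop = FALSE])$score
        if (nullScore <= obs$score + 1e-12) hits <- hits + 1L
      }
      hits
    })
    out[[t]] <- data.frame(target = names(db)[t], score = obs$score,
                           offset = obs$offset,
                           orientation = obs$orientation,
                           evalue = (1 + nBetter) / (nShuffles + 1) * dbSize,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Match a motif report against a database of known motifs
#'
#' Every motif in the report is converted to a PWM, aligned against the
#' whole database and assigned empirical E-values; matches at or below
#' the E-value threshold are returned with the motif's coverage carried
#' through from the report.
#'
#' @param report A [MotifReport-class].
#' @param db Named list of PWMs (see [readMotifDb()]).
#' @param maxEvalue E-value threshold; default `0.01 * length(db)`.
#' @param nShuffles,seed Passed to [empiricalEvalue()].
#' @param pseudo Passed to [consensusToPwm()].
#' @return A data.frame `motif`, `target`, `evalue`, `coverage`,
#'   `offset`, `orientation`, `score`, sorted by evalue then motif and
#'   target.
#' @export
matchReport <- function(report, db, maxEvalue = 0.01 * length(db),
                        nShuffles = 500L, seed = 1L, pseudo = 0.01) {
  stopifnot(is(report, "MotifReport"))
  if (!length(db)) stop("empty motif database", call. = FALSE)
  rows <- vector("list", length(report))
  for (i in seq_along(report@consensus)) {
    cons <- report@consensus[i]
    ev <- empiricalEvalue(consensusToPwm(cons, pseudo), db,
                          nShuffles = nShuffles, seed = seed)
    keep <- ev$evalue <= maxEvalue
    if (!any(keep)) next
    rows[[i]] <- data.frame(motif = cons, target = ev$target[keep],
                            evalue = ev$evalue[keep],
                            coverage = report@coverage[i],
                            offset = ev$offset[keep],
                            orientation = ev$orientation[keep],
                            score = ev$score[keep],
                            stringsAsFactors = FALSE)
  }
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(out)) rownames(out) <- NULL
  if (is.null(out)) {
    out <- data.frame(motif = character(0), target = character(0),
                      evalue = numeric(0), coverage = numeric(0),
                      offset = integer(0), orientation = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  }
  out[order(out$evalue, out$motif, out$target), , drop = FALSE]
}
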