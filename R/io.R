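## On-disk formats: FASTA gene sets, tab-delimited motif reports,
## two-column annotation TSV, motif databases (MEME format or
## name + IUPAC consensus TSV), profile-matrix TSV. All text is UTF-8,
## tab-delimited, LF-terminated. Readers never silently repair: every
## invariant violation is a hard error naming its location.

#' Construct a GeneSet from sequences
#'
#' @param sequences Named character vector or [Biostrings::DNAStringSet]
#'   of upstream sequences (gene start at the right end).
#' @param regionLength Upstream window length L in bp (default 800).
#' @return A [GeneSet-class].
#' @export
GeneSet <- function(sequences, regionLength = 800L) {
  if (is.character(sequences)) {
    seqs <- toupper(sequences)
    bad <- regexpr("[^ACGTN]", seqs)
    if (any(bad > 0L)) {
      i <- which(bad > 0L)[1L]
      stop("non-ACGTN character in sequence for gene '",
           names(seqs)[i], "' at position ", bad[i], call. = FALSE)
    }
    sequences <- Biostrings::DNAStringSet(seqs)
  }
  new("GeneSet", upstream = sequences,
      regionLength = as.integer(regionLength))
}

#' Read a gene set from a FASTA file of upstream sequences
#'
#' Each record is one gene's upstream region, 5'->3' on the coding strand
#' with the gene start at the right end. Ids are taken verbatim from the
#' first whitespace-delimited token of the header; file order is kept.
#'
#' @param path Path to a FASTA file.
#' @param regionLength Upstream window length L in bp (default 800).
#'   Sequences longer than L are a hard error (pre-trim upstream of the
#'   call); shorter sequences are accepted and keep their length.
#' @return A [GeneSet-class].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1", "ACGTACGT", ">g2", "TTTTACGT"), fa)
#' readGeneSet(fa, regionLength = 8)
#' @export
readGeneSet <- function(path, regionLength = 800L) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: '", ids[duplicated(ids)][1L], "'",
         call. = FALSE)
  }
  names(seqs) <- ids
  if (length(seqs)) {
    w <- Biostrings::width(seqs)
    if (any(w > regionLength)) {
      i <- which(w > regionLength)[1L]
      stop("sequence for gene '", ids[i], "' has length ", w[i],
           " > regionLength ", regionLength,
           "; trim sequences before reading", call. = FALSE)
    }
    chr <- toupper(as.character(seqs))
    bad <- regexpr("[^ACGTN]", chr)
    if (any(bad > 0L)) {
      i <- which(bad > 0L)[1L]
      stop("non-ACGTN character in record '", ids[i],
           "' at position ", bad[i], call. = FALSE)
    }
    seqs <- Biostrings::DNAStringSet(chr)
    names(seqs) <- ids
  }
  new("GeneSet", upstream = seqs, regionLength = as.integer(regionLength))
}

#' Write a GeneSet to FASTA
#'
#' @param genes A [GeneSet-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeGeneSet <- function(genes, path) {
  Biostrings::writeXStringSet(upstreamSeqs(genes), path, format = "fasta")
  invisible(path)
}

## ---- motif report ------------------------------------------------------

.fmtNum <- function(x) sprintf("%.6g", x)

#' Write a motif report as tab-delimited text
#'
#' Columns: consensus, count, sig, coverage, occurrences; occurrences are
#' semicolon-joined `gene:distance:strand` triples. A `#` header records
#' the gene-set size, region length and the number of candidates scored,
#' so that `readMotifReport()` round-trips the full object.
#'
#' @param report A [MotifReport-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeMotifReport <- function(report, path) {
  stopifnot(is(report, "MotifReport"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("# nGenes=%d regionLength=%d nCandidates=%s",
                     report@nGenes, report@regionLength,
                     .fmtNum(report@nCandidates)), con, sep = "\n")
  writeLines("consensus\tcount\tsig\tcoverage\toccurrences", con, sep = "\n")
  for (i in seq_along(report@consensus)) {
    occ <- report@occurrences[[i]]
    occStr <- if (nrow(occ)) {
      paste(sprintf("%s:%d:%s", occ$gene, occ$distance, occ$strand),
            collapse = ";")
    } else ""
    writeLines(paste(report@consensus[i], report@count[i],
                     .fmtNum(report@sig[i]), .fmtNum(report@coverage[i]),
                     occStr, sep = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' Read a tab-delimited motif report
#'
#' @param path Path written by [writeMotifReport()].
#' @return A [MotifReport-class].
#' @export
readMotifReport <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "#")) {
    stop("missing '#' metadata header in ", path, call. = FALSE)
  }
  meta <- regmatches(lines[1L],
    regexec("nGenes=(\\d+) regionLength=(\\d+) nCandidates=(\\S+)",
            lines[1L]))[[1L]]
  if (length(meta) != 4L) {
    stop("malformed metadata header in ", path, call. = FALSE)
  }
  nGenes <- as.integer(meta[2L])
  L <- as.integer(meta[3L])
  nCand <- as.numeric(meta[4L])
  if (length(lines) < 2L ||
      lines[2L] != "consensus\tcount\tsig\tcoverage\toccurrences") {
    stop("missing column header in ", path, call. = FALSE)
  }
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  n <- length(body)
  consensus <- character(n); count <- integer(n)
  sig <- numeric(n); coverage <- numeric(n); occ <- vector("list", n)
  for (i in seq_len(n)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    if (!length(f) %in% c(4L, 5L)) {
      stop("line ", i + 2L, ": expected 5 tab-separated fields",
           call. = FALSE)
    }
    consensus[i] <- f[1L]
    count[i] <- as.integer(f[2L])
    sig[i] <- as.numeric(f[3L])
    coverage[i] <- as.numeric(f[4L])
    occStr <- if (length(f) == 5L) f[5L] else ""
    if (nzchar(occStr)) {
      trip <- strsplit(strsplit(occStr, ";", fixed = TRUE)[[1L]],
                       ":", fixed = TRUE)
      bad <- which(vapply(trip, length, 0L) != 3L)
      if (length(bad)) {
        stop("line ", i + 2L, ": malformed occurrence triple '",
             paste(trip[[bad[1L]]], collapse = ":"), "'", call. = FALSE)
      }
      d <- as.integer(vapply(trip, `[`, "", 2L))
      s <- vapply(trip, `[`, "", 3L)
      if (anyNA(d) || any(d < 1L) || any(d > L)) {
        stop("line ", i + 2L, ": occurrence distance outside [1, ",
             L, "]", call. = FALSE)
      }
      if (!all(s %in% c("+", "-"))) {
        stop("line ", i + 2L, ": strand must be '+' or '-'", call. = FALSE)
      }
      occ[[i]] <- data.frame(gene = vapply(trip, `[`, "", 1L),
                             distance = d, strand = s,
                             stringsAsFactors = FALSE)
    } else {
      occ[[i]] <- data.frame(gene = character(0), distance = integer(0),
                             strand = character(0),
                             stringsAsFactors = FALSE)
    }
    if (nrow(occ[[i]]) != count[i]) {
      stop("line ", i + 2L, ": count=", count[i], " but ",
           nrow(occ[[i]]), " occurrence triples", call. = FALSE)
    }
  }
  new("MotifReport", consensus = consensus, count = count, sig = sig,
      coverage = coverage, occurrences = occ, nGenes = nGenes,
      regionLength = L, nCandidates = nCand)
}

## ---- annotation --------------------------------------------------------

#' Read a two-column gene-to-category annotation table
#'
#' A local stand-in for a functional-annotation service: each line is
#' `gene<TAB>category`. Repeated pairs are deduplicated; genes absent
#' from the file simply map to an empty set on lookup.
#'
#' @param path Path to the TSV file.
#' @return A named list, gene id -> character vector of category ids.
#' @export
readAnnotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(structure(list(), names = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 0L)
  if (any(nf != 2L)) {
    stop("line ", which(nf != 2L)[1L], ": expected 2 tab-separated columns",
         call. = FALSE)
  }
  g <- vapply(fields, `[`, "", 1L)
  c_ <- vapply(fields, `[`, "", 2L)
  lapply(split(c_, factor(g, levels = unique(g))), unique)
}

#' Write an annotation list as a two-column TSV
#'
#' @param annotation Named list, gene id -> categories.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeAnnotation <- function(annotation, path) {
  g <- rep(names(annotation), lengths(annotation))
  c_ <- unlist(annotation, use.names = FALSE)
  writeLines(if (length(g)) paste(g, c_, sep = "\t") else character(0),
             con = path)
  invisible(path)
}

## ---- motif database ----------------------------------------------------

.checkPwm <- function(pwm, name) {
  if (!is.matrix(pwm) || nrow(pwm) != 4L || ncol(pwm) < 1L) {
    stop("motif '", name, "': PWM must be a 4 x w matrix with w >= 1",
         call. = FALSE)
  }
  if (any(abs(colSums(pwm) - 1) > 1e-9) || any(pwm < 0)) {
    stop("motif '", name, "': PWM columns must be non-negative and sum to 1",
         call. = FALSE)
  }
  rownames(pwm) <- c("A", "C", "G", "T")
  pwm
}

.readMemeDb <- function(lines, path) {
  starts <- grep("^MOTIF\\s+", lines)
  if (!length(starts)) {
    stop("no MOTIF entries found in MEME file ", path, call. = FALSE)
  }
  db <- list()
  for (s in starts) {
    name <- strsplit(sub("^MOTIF\\s+", "", lines[s]), "\\s+")[[1L]][1L]
    hdr <- grep("^letter-probability matrix", lines[s:length(lines)])[1L]
    if (is.na(hdr)) {
      stop("motif '", name, "': missing letter-probability matrix",
           call. = FALSE)
    }
    i <- s + hdr - 1L
    w <- suppressWarnings(as.integer(
      sub(".*w\\s*=\\s*(\\d+).*", "\\1", lines[i])))
    rows <- list()
    j <- i + 1L
    while (j <= length(lines)) {
      ln <- trimws(lines[j])
      if (!nzchar(ln) || grepl("^(MOTIF|URL)", ln)) break
      vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1L]]))
      if (anyNA(vals) || length(vals) != 4L) break
      rows[[length(rows) + 1L]] <- vals
      j <- j + 1L
    }
    if (!length(rows)) {
      stop("motif '", name, "': zero-width motif", call. = FALSE)
    }
    if (!is.na(w) && length(rows) != w) {
      stop("motif '", name, "': matrix has ", length(rows),
           " rows but header declares w=", w, call. = FALSE)
    }
    pwm <- t(do.call(rbind, rows))
    if (!is.null(db[[name]])) {
      stop("duplicate motif name '", name, "' in ", path, call. = FALSE)
    }
    db[[name]] <- .checkPwm(pwm, name)
  }
  db
}

#' Read a motif database
#'
#' Accepts either MEME minimal motif format (`MOTIF` blocks with
#' `letter-probability matrix` sections) or a two-column TSV of
#' `name<TAB>IUPAC consensus`, in which case each consensus is converted
#' to a PWM by [consensusToPwm()].
#'
#' @param path Path to the database file.
#' @param pseudo Pseudo-probability for disallowed bases when converting
#'   consensus entries (see [consensusToPwm()]).
#' @return Named list of PWMs (4 x w matrices, rows A, C, G, T; columns
#'   summing to 1).
#' @export
readMotifDb <- function(path, pseudo = 0.01) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (any(grepl("^MEME version|^MOTIF\\s+", lines))) {
    return(.readMemeDb(lines, path))
  }
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty motif database: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 0L)
  if (any(nf != 2L)) {
    stop("line ", which(nf != 2L)[1L],
         ": expected 'name<TAB>consensus'", call. = FALSE)
  }
  nm <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate motif name '", nm[duplicated(nm)][1L], "'",
         call. = FALSE)
  }
  cons <- vapply(fields, `[`, "", 2L)
  if (any(!nzchar(cons))) {
    stop("zero-width motif '", nm[!nzchar(cons)][1L], "'", call. = FALSE)
  }
  db <- lapply(cons, consensusToPwm, pseudo = pseudo)
  names(db) <- nm
  db
}

#' Write a motif database in MEME minimal format
#'
#' @param db Named list of PWMs.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeMotifDb <- function(db, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", ""), con, sep = "\n")
  for (nm in names(db)) {
    pwm <- .checkPwm(db[[nm]], nm)
    writeLines(c(paste("MOTIF", nm),
                 sprintf("letter-probability matrix: alength= 4 w= %d",
                         ncol(pwm))), con, sep = "\n")
    for (j in seq_len(ncol(pwm))) {
      writeLines(paste(sprintf("%.6f", pwm[, j]), collapse = " "),
                 con, sep = "\n")
    }
    writeLines("", con, sep = "\n")
  }
  invisible(path)
}

## ---- profile matrix ----------------------------------------------------

#' Write a ProfileMatrix as TSV
#'
#' Header: `gene` then `"<consensus>@bin<i>"` columns; a `#` line records
#' the bin geometry so reading restores the object exactly.
#'
#' @param profiles A [ProfileMatrix-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeProfileMatrix <- function(profiles, path) {
  stopifnot(is(profiles, "ProfileMatrix"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("# nBins=%d binWidth=%d", profiles@nBins,
                     profiles@binWidth), con, sep = "\n")
  writeLines(paste(c("gene", colnames(profiles@counts)), collapse = "\t"),
             con, sep = "\n")
  m <- profiles@counts
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], m[i, ]), collapse = "\t"),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read a ProfileMatrix written by [writeProfileMatrix()]
#'
#' @param path Input path.
#' @return A [ProfileMatrix-class].
#' @export
readProfileMatrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1L], "#")) {
    stop("missing metadata header in ", path, call. = FALSE)
  }
  meta <- regmatches(lines[1L],
    regexec("nBins=(\\d+) binWidth=(\\d+)", lines[1L]))[[1L]]
  nBins <- as.integer(meta[2L]); binWidth <- as.integer(meta[3L])
  hdr <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  cols <- hdr[-1L]
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  genes <- vapply(fields, `[`, "", 1L)
  m <- matrix(0L, nrow = length(genes), ncol = length(cols),
              dimnames = list(genes, cols))
  for (i in seq_along(fields)) {
    v <- as.integer(fields[[i]][-1L])
    if (length(v) != length(cols)) {
      stop("line ", i + 2L, ": expected ", length(cols) + 1L, " columns",
           call. = FALSE)
    }
    m[i, ] <- v
  }
  motifs <- unique(sub("@bin\\d+$", "", cols))
  new("ProfileMatrix", counts = m, motifs = motifs, nBins = nBins,
      binWidth = binWidth)
}

#' Write cluster labels as a two-column TSV
#'
#' @param labels Named character vector (gene -> cluster label).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeLabels <- function(labels, path) {
  writeLines(paste(names(labels), labels, sep = "\t"), con = path)
  invisible(path)
}
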