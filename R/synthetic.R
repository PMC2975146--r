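## Synthetic fixtures: seeded generation of background promoters,
## planted motifs with controlled per-quartile positional distributions,
## subset-enriched annotation tables, and a motif database holding the
## planted motifs under known transcription-factor-like names. Every
## generator is deterministic given its seed and the manifest records
## enough to regenerate a bundle bit-identically.

#' Sample background upstream sequences
#'
#' i.i.d. (order-0) or first-order Markov sequences drawn from the
#' background model with R's RNG under the given seed (the caller's RNG
#' state is restored afterwards).
#'
#' @param nGenes Number of genes (ids `g001`, `g002`, ...).
#' @param L Sequence length in bp (default 800).
#' @param bg A [Background-class] (default uniform order 0).
#' @param seed Integer seed.
#' @param prefix Gene-id prefix (default `"g"`).
#' @return A [GeneSet-class].
#' @export
sampleBackground <- function(nGenes, L = 800L, bg = background(),
                             seed = 1L, prefix = "g") {
  stopifnot(nGenes >= 0L, L >= 1L, is(bg, "Background"))
  bases <- c("A", "C", "G", "T")
  ids <- sprintf("%s%03d", prefix, seq_len(nGenes))
  if (nGenes == 0L) {
    return(new("GeneSet", upstream = Biostrings::DNAStringSet(),
               regionLength = as.integer(L)))
  }
  seqs <- .withSeed(seed, {
    vapply(seq_len(nGenes), function(i) {
      if (bg@order == 0L) {
        paste(sample(bases, L, replace = TRUE, prob = bg@freq),
              collapse = "")
      } else {
        s <- character(L)
        s[1L] <- sample(bases, 1L, prob = bg@freq)
        for (j in seq_len(L - 1L)) {
          s[j + 1L] <- sample(bases, 1L, prob = bg@transition[s[j], ])
        }
        paste(s, collapse = "")
      }
    }, "")
  })
  names(seqs) <- ids
  GeneSet(seqs, regionLength = L)
}

#' Specification of one planted-motif subset
#'
#' @param subsetId Subset label.
#' @param nGenes Genes in the subset.
#' @param consensus IUPAC consensus to plant (each occurrence is a fresh
#'   concrete instantiation, degenerate symbols resolved uniformly).
#' @param occurrencesPerGene Occurrences planted per gene: an integer
#'   for a fixed count, or a non-integer rate for Poisson counts.
#' @param quartileWeights Non-negative weights over the B upstream bins,
#'   summing to 1; each occurrence's bin is drawn from these.
#' @param strandProbPlus Probability an occurrence is planted on the
#'   coding strand (default 0.5).
#' @return A named list of class `"PlantSpec"`.
#' @export
plantSpec <- function(subsetId, nGenes, consensus,
                      occurrencesPerGene = 1,
                      quartileWeights = c(0.25, 0.25, 0.25, 0.25),
                      strandProbPlus = 0.5) {
  .checkConsensus(consensus)
  if (abs(sum(quartileWeights) - 1) > 1e-9 || any(quartileWeights < 0)) {
    stop("quartileWeights must be non-negative and sum to 1",
         call. = FALSE)
  }
  stopifnot(strandProbPlus >= 0, strandProbPlus <= 1, nGenes >= 1)
  structure(list(subsetId = subsetId, nGenes = as.integer(nGenes),
                 consensus = toupper(consensus),
                 occurrencesPerGene = occurrencesPerGene,
                 quartileWeights = quartileWeights,
                 strandProbPlus = strandProbPlus),
            class = "PlantSpec")
}

.instantiateConsensus <- function(consensus) {
  chars <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  paste(vapply(chars, function(s) {
    b <- iupacBases(s)
    if (length(b) == 1L) b else sample(b, 1L)
  }, ""), collapse = "")
}

#' Plant motif occurrences into background sequences
#'
#' Genes are assigned to subsets in input order (the first
#' `specs[[1]]$nGenes` genes to the first subset, and so on; the spec
#' sizes must sum to the gene count). For every gene, an occurrence
#' count is drawn, then each occurrence samples a bin from the subset's
#' quartile weights and a uniform in-bin position such that the whole
#' instance lies inside the bin; the background is overwritten in place
#' (sequence length never changes) with a concrete instantiation of the
#' consensus, reverse-complemented with probability
#' `1 - strandProbPlus`. Instances never overlap within a gene
#' (positions are rejection-sampled; a gene that cannot be placed after
#' bounded retries is a hard error).
#'
#' @param genes A [GeneSet-class] of background sequences.
#' @param specs List of [plantSpec()] objects partitioning the genes.
#' @param seed Integer seed.
#' @param nBins Number of upstream bins the weights refer to (default 4).
#' @return A list with `genes` (the modified [GeneSet-class]) and
#'   `truth` (named character vector gene -> subset id).
#' @export
plantMotifs <- function(genes, specs, seed = 1L, nBins = 4L) {
  stopifnot(is(genes, "GeneSet"))
  ids <- geneIds(genes)
  sizes <- vapply(specs, function(s) s$nGenes, 0L)
  if (sum(sizes) != length(ids)) {
    stop("plant specs cover ", sum(sizes), " genes but the GeneSet has ",
         length(ids), call. = FALSE)
  }
  L <- regionLength(genes)
  binWidth <- L %/% nBins
  seqs <- as.character(upstreamSeqs(genes))
  truth <- character(length(ids)); names(truth) <- ids
  geneIdx <- 0L
  .withSeed(seed, {
    for (sp in specs) {
      w <- nchar(sp$consensus)
      if (w > binWidth) {
        stop("consensus '", sp$consensus, "' (", w,
             " bp) does not fit inside a ", binWidth, " bp bin",
             call. = FALSE)
      }
      if (length(sp$quartileWeights) != nBins) {
        stop("quartileWeights of subset '", sp$subsetId, "' has ",
             length(sp$quartileWeights), " entries; expected ", nBins,
             call. = FALSE)
      }
      for (g in seq_len(sp$nGenes)) {
        geneIdx <- geneIdx + 1L
        id <- ids[geneIdx]
        truth[id] <- sp$subsetId
        nOcc <- if (sp$occurrencesPerGene == round(sp$occurrencesPerGene)) {
          as.integer(sp$occurrencesPerGene)
        } else {
          rpois(1L, sp$occurrencesPerGene)
        }
        if (nOcc == 0L) next
        len <- nchar(seqs[geneIdx])
        occupied <- integer(0)   # occupied sequence positions
        for (o in seq_len(nOcc)) {
          placed <- FALSE
          for (try in seq_len(100L)) {
            b <- sample.int(nBins, 1L, prob = sp$quartileWeights)
            ## instance spans distances d .. d+w-1, all inside bin b
            dmax <- b * binWidth - w + 1L
            dmin <- (b - 1L) * binWidth + 1L
            if (dmax < dmin) next
            d <- dmin + sample.int(dmax - dmin + 1L, 1L) - 1L
            ## sequence coords: distance 1 = rightmost base
            e <- len - d + 1L          # right end of instance
            s <- e - w + 1L            # left end
            if (s < 1L) next
            if (any(s:e %in% occupied)) next
            inst <- .instantiateConsensus(sp$consensus)
            if (stats::runif(1L) > sp$strandProbPlus) {
              inst <- revcompConsensus(inst)
            }
            substr(seqs[geneIdx], s, e) <- inst
            occupied <- c(occupied, s:e)
            placed <- TRUE
            break
          }
          if (!placed) {
            stop("could not place occurrence ", o, " of '",
                 sp$consensus, "' in gene '", id,
                 "' without overlap after 100 retries", call. = FALSE)
          }
        }
      }
    }
  })
  out <- GeneSet(stats::setNames(seqs, ids), regionLength = L)
  list(genes = out, truth = truth)
}

#' Generate a subset-enriched annotation table
#'
#' Each subset receives `nCategoriesPerSubset` private categories
#' covering a `coverage` fraction of its genes (plus spill-over to
#' non-members at `noiseRate`); `backgroundCategories` unrelated
#' categories are sprinkled over all genes independently.
#'
#' @param truth Named character vector gene -> subset id.
#' @param nCategoriesPerSubset Private categories per subset (default 2).
#' @param backgroundCategories Subset-agnostic categories (default 3).
#' @param coverage Fraction of subset members carrying each private
#'   category (default 1).
#' @param noiseRate Probability a non-member also carries a private
#'   category (default 0).
#' @param backgroundRate Probability a gene carries each background
#'   category (default 0.3).
#' @param seed Integer seed.
#' @return Named list, gene id -> character vector of categories.
#' @export
makeAnnotation <- function(truth, nCategoriesPerSubset = 2L,
                           backgroundCategories = 3L, coverage = 1,
                           noiseRate = 0, backgroundRate = 0.3,
                           seed = 1L) {
  stopifnot(coverage >= 0, coverage <= 1, noiseRate >= 0, noiseRate <= 1)
  genes <- names(truth)
  ann <- stats::setNames(vector("list", length(genes)), genes)
  .withSeed(seed, {
    for (s in unique(truth)) {
      members <- genes[truth == s]
      others <- genes[truth != s]
      for (ci in seq_len(nCategoriesPerSubset)) {
        cat_ <- sprintf("%s_cat%d", s, ci)
        nCov <- round(coverage * length(members))
        hit <- if (nCov > 0) sample(members, nCov) else character(0)
        spill <- others[stats::runif(length(others)) < noiseRate]
        for (g in c(hit, spill)) ann[[g]] <- c(ann[[g]], cat_)
      }
    }
    for (bi in seq_len(backgroundCategories)) {
      cat_ <- sprintf("bg_cat%d", bi)
      hit <- genes[stats::runif(length(genes)) < backgroundRate]
      for (g in hit) ann[[g]] <- c(ann[[g]], cat_)
    }
  })
  ann[vapply(ann, is.null, TRUE)] <- NULL
  lapply(ann, unique)
}

## scenario presets; sizes chosen so a full pipeline run stays desk-scale
.SCENARIOS <- list(
  paper_like_g1s = list(
    desc = paste("three 15-gene subsets sharing a CGCG-core motif with",
                 "positional bias on bins 3-4, 2 and 1 respectively"),
    L = 800L, nBins = 4L,
    plants = list(
      list(subsetId = "A", nGenes = 15L, consensus = "CGCGWH",
           occurrencesPerGene = 3, quartileWeights = c(0, 0, 0.5, 0.5)),
      list(subsetId = "B", nGenes = 15L, consensus = "DWCGCGW",
           occurrencesPerGene = 3, quartileWeights = c(0, 1, 0, 0)),
      list(subsetId = "C", nGenes = 15L, consensus = "DNWCGCGW",
           occurrencesPerGene = 3, quartileWeights = c(1, 0, 0, 0))),
    db = c("SBF-like" = "CGCGWH", "MBF-like" = "DNWCGCGW",
           "CORE-like" = "DWCGCGW", "DECOY-AT" = "TTATAWAW",
           "DECOY-GC" = "GGCCSSGG")),
  two_subsets_shared_core = list(
    desc = paste("two 15-gene subsets whose planted motifs share the",
                 "identical 4-bp core CGCG, planted on bin 2 vs bin 1"),
    L = 800L, nBins = 4L,
    plants = list(
      list(subsetId = "A", nGenes = 15L, consensus = "ACGCGT",
           occurrencesPerGene = 3, quartileWeights = c(0, 1, 0, 0)),
      list(subsetId = "B", nGenes = 15L, consensus = "TCGCGA",
           occurrencesPerGene = 3, quartileWeights = c(1, 0, 0, 0))),
    db = c("MBF-like" = "ACGCGT", "SBF-like" = "TCGCGA",
           "DECOY-AT" = "TTATAWAW")),
  null = list(
    desc = "pure background, one nominal subset, nothing planted",
    L = 800L, nBins = 4L,
    plants = list(
      list(subsetId = "all", nGenes = 20L, consensus = "ACGCGT",
           occurrencesPerGene = 0, quartileWeights = c(1, 0, 0, 0))),
    db = c("MBF-like" = "ACGCGT"))
)

#' Build a complete synthetic fixture bundle
#'
#' Scenario presets: `"paper_like_g1s"` (three subsets sharing a CGCG
#' core with distinct positional biases on bins 3-4 / 2 / 1),
#' `"two_subsets_shared_core"` (two subsets, identical 4-bp core,
#' bins 2 vs 1) and `"null"` (pure background, nothing planted). The
#' manifest records every parameter and the seed; regenerating from the
#' same scenario and seed is bit-identical.
#'
#' @param scenario Scenario name.
#' @param seed Integer seed.
#' @return A [FixtureBundle-class].
#' @export
makeFixture <- function(scenario = c("paper_like_g1s",
                                     "two_subsets_shared_core", "null"),
                        seed = 1L) {
  if (!is.character(scenario) || !scenario[1L] %in% names(.SCENARIOS)) {
    stop("unknown scenario '", scenario[1L], "'; available: ",
         paste(names(.SCENARIOS), collapse = ", "), call. = FALSE)
  }
  scenario <- scenario[1L]
  sc <- .SCENARIOS[[scenario]]
  specs <- lapply(sc$plants, function(p) do.call(plantSpec, p))
  nGenes <- sum(vapply(specs, function(s) s$nGenes, 0L))
  bgGenes <- sampleBackground(nGenes, L = sc$L, bg = background(),
                              seed = .childSeed(seed, "background"))
  planted <- plantMotifs(bgGenes, specs,
                         seed = .childSeed(seed, "plant"),
                         nBins = sc$nBins)
  ann <- makeAnnotation(planted$truth,
                        seed = .childSeed(seed, "annotation"))
  db <- lapply(sc$db, consensusToPwm)
  names(db) <- names(sc$db)
  manifest <- list(scenario = scenario, seed = as.integer(seed),
                   description = sc$desc, L = sc$L, nBins = sc$nBins,
                   plants = sc$plants, db = as.list(sc$db),
                   background = "uniform order-0")
  new("FixtureBundle", genes = planted$genes, truth = planted$truth,
      annotation = ann, motifDb = db, manifest = manifest)
}

#' Write a fixture bundle to a directory
#'
#' Emits `upstream.fa`, `truth.tsv`, `annotation.tsv`, `motifs.meme`
#' and `manifest.json`.
#'
#' @param bundle A [FixtureBundle-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
writeFixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGeneSet(bundle@genes, file.path(dir, "upstream.fa"))
  writeLabels(bundle@truth, file.path(dir, "truth.tsv"))
  writeAnnotation(bundle@annotation, file.path(dir, "annotation.tsv"))
  writeMotifDb(bundle@motifDb, file.path(dir, "motifs.meme"))
  jsonlite::write_json(bundle@manifest,
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
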