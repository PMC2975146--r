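## Pipeline orchestration: discover motifs on the starting gene set,
## profile them by quartile, cluster the gene-motif vectors into peaks,
## then re-discover, enrich and database-match each sufficiently large
## subset. All stage outputs are written as plain text files under one
## output directory and a machine-readable summary ties them together.

#' Build a validated pipeline configuration
#'
#' Defaults follow the per-module defaults. Unknown names in `...` are
#' rejected.
#'
#' @param ... Overrides of: `regionLength` (800), `nBins` (4),
#'   `topM` (25), `minSig` (0), `bothStrands` (TRUE), `bgOrder` (0),
#'   `metric` ("cosine"), `kNeighbors` (10), `minProminence` (0.1),
#'   `gridSize` (128), `bandwidth` (NULL = Scott rule),
#'   `minSubsetSize` (5), `fold` (100), `fdr` (0.05),
#'   `nShuffles` (200), `maxEvaluePerDbMotif` (0.01), `seed` (1),
#'   plus the [candidateSpec()] fields `kMin`, `kMax`,
#'   `maxDegeneratePositions`, `gapMin`, `gapMax`, `seedsPerLength`,
#'   `halfSeeds`, `maxDegenerateCandidates`, `preFilterSig`.
#' @return A named list of class `"RunConfig"`.
#' @export
runConfig <- function(...) {
  defaults <- list(
    regionLength = 800L, nBins = 4L, topM = 25L, minSig = 0,
    bothStrands = TRUE, bgOrder = 0L, metric = "cosine",
    kNeighbors = 10L, minProminence = 0.1, gridSize = 128L,
    bandwidth = NULL, minSubsetSize = 5L, fold = 100, fdr = 0.05,
    nShuffles = 200L, maxEvaluePerDbMotif = 0.01, seed = 1L,
    kMin = 5L, kMax = 8L, maxDegeneratePositions = 3L,
    gapMin = 4L, gapMax = 10L, seedsPerLength = 4L, halfSeeds = 4L,
    maxDegenerateCandidates = 2000L, preFilterSig = 3)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) &&
      is.null(names(over))) {
    over <- over[[1L]]
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, over, keep.null = TRUE)
  structure(cfg, class = "RunConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys mirror [runConfig()].
#' @return A `"RunConfig"` list.
#' @export
readRunConfig <- function(path) {
  runConfig(yaml::read_yaml(path))
}

.candidateSpecFromConfig <- function(cfg) {
  candidateSpec(kMin = cfg$kMin, kMax = cfg$kMax,
                maxDegeneratePositions = cfg$maxDegeneratePositions,
                gapMin = cfg$gapMin, gapMax = cfg$gapMax,
                seedsPerLength = cfg$seedsPerLength,
                halfSeeds = cfg$halfSeeds,
                maxDegenerateCandidates = cfg$maxDegenerateCandidates,
                preFilterSig = cfg$preFilterSig)
}

.logStage <- function(verbose, ...) {
  if (verbose) message(format(Sys.time(), "%H:%M:%S"), " | ", ...)
}

#' Run the full motif-landscape pipeline
#'
#' Stages: (1) motif discovery on the starting gene set; (2) quartile
#' profiling into gene-motif vectors; (3) landscape clustering into
#' peaks; (4) for every peak with at least `minSubsetSize` genes,
#' motif re-discovery, category enrichment against the starting set
#' (with subset-vs-parent status flags) and matching of the subset's
#' motifs against the database. All intermediate files are written
#' under `outDir`; the returned (and written) summary lists them plus
#' per-subset headline results. Deterministic given the seed; the
#' summary contains no timestamps.
#'
#' @param genes A [GeneSet-class], or a FASTA path.
#' @param annotation Named list gene -> categories, or a TSV path, or
#'   NULL to skip enrichment.
#' @param motifDb Named list of PWMs, or a database file path, or NULL
#'   to skip matching.
#' @param outDir Output directory.
#' @param config A [runConfig()].
#' @param verbose Log stage progress to stderr (default TRUE).
#' @return The run summary, invisibly (also written to
#'   `summary.json`).
#' @export
runPipeline <- function(genes, annotation = NULL, motifDb = NULL,
                        outDir = "motif-landscape-out",
                        config = runConfig(), verbose = TRUE) {
  stopifnot(inherits(config, "RunConfig"))
  if (is.character(genes)) {
    genes <- readGeneSet(genes, regionLength = config$regionLength)
  }
  if (is.character(annotation)) annotation <- readAnnotation(annotation)
  if (is.character(motifDb)) motifDb <- readMotifDb(motifDb)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  spec <- .candidateSpecFromConfig(config)
  bg <- estimateBackground(genes, order = config$bgOrder)

  .logStage(verbose, "discover: ", length(genes), " genes")
  report <- discoverMotifs(genes, spec = spec, bg = bg,
                           topM = config$topM, minSig = config$minSig,
                           bothStrands = config$bothStrands)
  reportPath <- file.path(outDir, "report.tsv")
  writeMotifReport(report, reportPath)
  if (length(report) == 0L) {
    stop("stage discover: no significant motifs in the starting set",
         call. = FALSE)
  }

  .logStage(verbose, "profile: ", length(report), " motifs x ",
            config$nBins, " bins")
  profiles <- buildProfileMatrix(report, genes, nBins = config$nBins)
  profilesPath <- file.path(outDir, "profiles.tsv")
  writeProfileMatrix(profiles, profilesPath)

  .logStage(verbose, "cluster")
  lp <- layoutParams(kNeighbors = config$kNeighbors, seed = config$seed)
  landscape <- clusterGenes(profiles, params = lp,
                            metric = config$metric,
                            bandwidth = config$bandwidth,
                            gridSize = config$gridSize,
                            minProminence = config$minProminence)
  labels <- clusterLabels(landscape)
  labelsPath <- file.path(outDir, "labels.tsv")
  writeLabels(labels, labelsPath)
  landscapePath <- file.path(outDir, "landscape.json")
  jsonlite::write_json(
    list(params = landscape@params,
         peaks = landscapePeaks(landscape),
         coords = data.frame(gene = rownames(geneCoords(landscape)),
                             x = geneCoords(landscape)[, 1L],
                             y = geneCoords(landscape)[, 2L])),
    landscapePath, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ## per-subset re-analysis
  parentEnrich <- if (!is.null(annotation)) {
    enrichSubset(geneIds(genes), geneIds(genes), annotation)
  } else NULL
  peakIds <- landscapePeaks(landscape)$peak
  subsets <- list()
  for (pk in peakIds) {
    members <- names(labels)[labels == pk]
    info <- list(peak = pk, nGenes = length(members), genes = members)
    if (length(members) < config$minSubsetSize) {
      info$skipped <- paste0("below minSubsetSize (",
                             config$minSubsetSize, ")")
      subsets[[pk]] <- info
      next
    }
    .logStage(verbose, "subset ", pk, ": ", length(members), " genes")
    subDir <- file.path(outDir, paste0("subset_", pk))
    dir.create(subDir, showWarnings = FALSE)
    subGenes <- genes[members]
    subReport <- discoverMotifs(subGenes, spec = spec, bg = bg,
                                topM = config$topM,
                                minSig = config$minSig,
                                bothStrands = config$bothStrands)
    writeMotifReport(subReport, file.path(subDir, "report.tsv"))
    topDf <- head(as.data.frame(subReport), 5L)
    info$topMotifs <- topDf
    if (!is.null(annotation)) {
      subEnrich <- enrichSubset(members, geneIds(genes), annotation)
      cmp <- compareToParent(subEnrich, parentEnrich,
                             fold = config$fold, fdr = config$fdr)
      enr <- merge(subEnrich, cmp[, c("category", "status")],
                   by = "category", sort = FALSE)
      enr <- enr[order(enr$p, enr$category), , drop = FALSE]
      utils::write.table(enr, file.path(subDir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      info$enriched <- enr[enr$q < config$fdr,
                           c("category", "p", "q", "status"),
                           drop = FALSE]
    }
    if (!is.null(motifDb) && length(subReport) > 0L) {
      matches <- matchReport(subReport, motifDb,
                             maxEvalue = config$maxEvaluePerDbMotif *
                               length(motifDb),
                             nShuffles = config$nShuffles,
                             seed = config$seed)
      utils::write.table(matches, file.path(subDir, "matches.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      info$topMatches <- head(matches, 5L)
    }
    subsets[[pk]] <- info
  }

  summary <- list(
    config = unclass(config),
    nGenes = length(genes),
    files = list(report = reportPath, profiles = profilesPath,
                 labels = labelsPath, landscape = landscapePath),
    nMotifs = length(report),
    topMotifs = head(as.data.frame(report), 5L),
    nPeaks = length(peakIds),
    nUnclustered = sum(labels == "unclustered"),
    subsets = subsets)
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(summary)
}
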