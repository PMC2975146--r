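test_that("background sampling is seeded and composition-faithful", {
  expect_identical(length(sampleBackground(0, 800, seed = 1)), 0L)
  g1 <- sampleBackground(5, 300, seed = 42)
  g2 <- sampleBackground(5, 300, seed = 42)
  expect_identical(as.character(upstreamSeqs(g1)),
                   as.character(upstreamSeqs(g2)))
  ## law of large numbers: 200 x 800 uniform draws
  big <- sampleBackground(200, 800, seed = 7)
  freq <- colSums(Biostrings::letterFrequency(
    upstreamSeqs(big), c("A", "C", "G", "T"))) / (200 * 800)
  expect_true(all(abs(freq - 0.25) < 0.02))
  ## order-1 sampling respects a biased transition row
  tr <- matrix(0.25, 4, 4); tr[1, ] <- c(0.97, 0.01, 0.01, 0.01)
  g3 <- sampleBackground(20, 400, background(order = 1, transition = tr),
                         seed = 3)
  s <- paste(as.character(upstreamSeqs(g3)), collapse = "")
  aa <- length(gregexpr("AA", s, fixed = TRUE)[[1]])
  expect_gt(aa, 1000)  # ~0.97 of positions after an A stay A
})

test_that("planted occurrences obey quartile weights and strand choice", {
  bg <- sampleBackground(30, 800, seed = 2)
  pl <- plantMotifs(bg, list(plantSpec("s", 30, "ACGTTGCA", 2,
                                       quartileWeights = c(0, 1, 0, 0),
                                       strandProbPlus = 1)), seed = 12)
  occ <- scanConsensus("ACGTTGCA", pl$genes, bothStrands = FALSE)
  expect_gte(nrow(occ), 60)  # every plant present verbatim (+ strand)
  planted <- occ[occ$distance > 200 & occ$distance <= 400, ]
  expect_gte(nrow(planted), 60)
})

test_that("bin-1/bin-2 half-and-half planting concentrates as binomial", {
  bg <- sampleBackground(250, 800, seed = 4)
  pl <- plantMotifs(bg, list(plantSpec("s", 250, "TGCATGCA", 4,
                                       quartileWeights = c(0.5, 0.5, 0, 0))),
                    seed = 14)
  occ <- scanConsensus("TGCATGCA", pl$genes)
  occ <- occ[occ$distance <= 400, ]   # planted ones (background ~ none)
  frac1 <- mean(occ$distance <= 200)
  expect_gt(nrow(occ), 900)
  expect_lt(abs(frac1 - 0.5), 0.05)
})

test_that("plants overwrite in place and never overlap", {
  bg <- sampleBackground(10, 800, seed = 5)
  pl <- plantMotifs(bg, list(plantSpec("s", 10, "ACGTACGT", 3)),
                    seed = 15)
  expect_identical(unname(Biostrings::width(upstreamSeqs(pl$genes))),
                   rep(800L, 10))
  ## a consensus too wide for a bin is a hard error
  expect_error(plantMotifs(bg, list(plantSpec("s", 10,
    strrep("A", 300), 1))), "fit")
  ## subset sizes must partition the genes
  expect_error(plantMotifs(bg, list(plantSpec("s", 4, "ACGT", 1))),
               "cover")
})

test_that("annotation generator yields exactly-covering private categories", {
  truth <- stats::setNames(rep(c("A", "B", "C"), each = 15),
                           sprintf("g%03d", 1:45))
  ann <- makeAnnotation(truth, nCategoriesPerSubset = 1,
                        backgroundCategories = 0, coverage = 1,
                        noiseRate = 0, seed = 6)
  aGenes <- names(truth)[truth == "A"]
  withA <- names(ann)[vapply(ann, function(x) "A_cat1" %in% x, TRUE)]
  expect_setequal(withA, aGenes)
  ## its enrichment in its own subset is strong (oracle check)
  p <- hypergeomUpperTail(15, 15, 15, 45)
  expect_lt(p, 0.01)
  rows <- enrichSubset(aGenes, names(truth), ann)
  expect_equal(rows$p[rows$category == "A_cat1"], p, tolerance = 1e-9)
  expect_length(makeAnnotation(truth, 0, 0, seed = 1), 0)
})

test_that("fixture bundles regenerate bit-identically from scenario+seed", {
  f1 <- makeFixture("two_subsets_shared_core", seed = 11)
  f2 <- makeFixture("two_subsets_shared_core", seed = 11)
  expect_identical(as.character(upstreamSeqs(f1@genes)),
                   as.character(upstreamSeqs(f2@genes)))
  expect_identical(f1@truth, f2@truth)
  expect_identical(f1@annotation, f2@annotation)
  expect_identical(f1@manifest, f2@manifest)
  expect_error(makeFixture("no_such_thing"), "unknown scenario")
})

test_that("shared-core scenario plants motifs with an identical 4-bp core", {
  f <- makeFixture("two_subsets_shared_core", seed = 1)
  cons <- vapply(f@manifest$plants, function(p) p$consensus, "")
  core <- substr(cons[1], 2, 5)
  expect_identical(core, substr(cons[2], 2, 5))
  expect_identical(nchar(core), 4L)
})

test_that("null scenario carries one subset and no planted signal", {
  f <- makeFixture("null", seed = 9)
  expect_identical(unname(unique(f@truth)), "all")
  ## nothing planted: the nominal consensus count is at background level
  occ <- scanConsensus("ACGCGT", f@genes)
  expect_lt(nrow(occ), 25)
})

test_that("fixture files are written and readable back", {
  dir <- withr::local_tempdir()
  f <- makeFixture("null", seed = 2)
  writeFixture(f, dir)
  genes <- readGeneSet(file.path(dir, "upstream.fa"), 800)
  expect_identical(geneIds(genes), geneIds(f@genes))
  ann <- readAnnotation(file.path(dir, "annotation.tsv"))
  expect_identical(ann[order(names(ann))],
                   f@annotation[order(names(f@annotation))])
  db <- readMotifDb(file.path(dir, "motifs.meme"))
  expect_named(db, names(f@motifDb))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_identical(manifest$scenario, "null")
})
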