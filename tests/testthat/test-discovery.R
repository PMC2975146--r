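test_that("scanConsensus finds exact matches at the right distance", {
  ## ACGCGT ends 150 bp from the right edge => distance 150
  seq1 <- paste0(strrep("A", 644), "ACGCGT", strrep("G", 149))
  expect_identical(nchar(seq1), 799L)
  genes <- gs(g1 = seq1, L = 800)
  occ <- scanConsensus("ACGCGT", genes, bothStrands = FALSE)
  expect_identical(occ$distance, 150L)
  expect_identical(occ$strand, "+")
  expect_identical(occ$gene, "g1")
})

test_that("reverse-strand matches carry strand '-' and need bothStrands", {
  ## CCGTA's reverse complement TACGG is planted; CCGTA itself is absent
  genes <- gs(g1 = paste0(strrep("A", 100), "TACGG", strrep("A", 95)))
  expect_identical(nrow(scanConsensus("CCGTA", genes,
                                      bothStrands = FALSE)), 0L)
  occ <- scanConsensus("CCGTA", genes, bothStrands = TRUE)
  expect_identical(occ$strand, "-")
  expect_identical(occ$distance, 96L)
})

test_that("bipartite and degenerate scans agree with the brute oracle", {
  set.seed(42)
  for (cons in c("AYTNNNNNNNNCGT", "RCGCGW", "ACGCGT", "TRRCCA")) {
    seqs <- vapply(1:6, function(i) {
      paste(sample(c("A", "C", "G", "T", "N"), 300, replace = TRUE,
                   prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
            collapse = "")
    }, "")
    names(seqs) <- paste0("g", 1:6)
    ## plant one concrete instance of the first consensus shape
    seqs[1] <- paste0(substr(seqs[1], 1, 100), "ATTACGTACGTACGT",
                      substr(seqs[1], 116, 300))
    genes <- GeneSet(seqs, regionLength = 300)
    expect_identical(scanConsensus(cons, genes), bruteScan(cons, genes),
                     info = cons)
  }
})

test_that("subject N is never matched, not even by consensus N", {
  genes <- gs(g1 = "AANAA")
  expect_identical(nrow(scanConsensus("ANA", genes)), 0L)
  expect_identical(nrow(scanConsensus("AA", genes)), 2L)
  ## the same windows match once the N is a real base
  expect_identical(nrow(scanConsensus("ANA", gs(g1 = "AACAA"))), 1L)
})

test_that("overlapping matches are all reported", {
  genes <- gs(g1 = "AAAAAA")
  occ <- scanConsensus("AAA", genes, bothStrands = FALSE)
  expect_identical(nrow(occ), 4L)
})

test_that("scanConsensus rejects invalid consensus characters", {
  genes <- gs(g1 = "ACGT")
  expect_error(scanConsensus("ACGX", genes), "invalid IUPAC")
  expect_error(scanConsensus("", genes), "non-empty")
})

test_that("wordProbability follows the background model", {
  bg <- background()
  expect_equal(wordProbability("N", bg), 1)
  expect_equal(wordProbability("A", bg), 0.25)
  expect_equal(wordProbability("WS", bg), 0.25)
  bg2 <- background(c(0.4, 0.1, 0.1, 0.4))
  expect_equal(wordProbability("W", bg2), 0.8)
  expect_equal(wordProbability("AN", bg2), 0.4)
})

test_that("order-1 wordProbability equals enumeration over admitted strings", {
  tr <- matrix(c(0.5, 0.2, 0.2, 0.1,
                 0.25, 0.25, 0.25, 0.25,
                 0.1, 0.4, 0.4, 0.1,
                 0.3, 0.3, 0.2, 0.2), nrow = 4, byrow = TRUE)
  bg <- background(c(0.3, 0.2, 0.2, 0.3), order = 1, transition = tr)
  bases <- c("A", "C", "G", "T")
  enumP <- function(cons) {
    sets <- lapply(strsplit(cons, "")[[1]], iupacBases)
    total <- 0
    for (word in do.call(paste0, expand.grid(sets,
                                             stringsAsFactors = FALSE))) {
      ch <- match(strsplit(word, "")[[1]], bases)
      p <- bg@freq[ch[1]]
      for (j in seq_along(ch)[-1]) p <- p * tr[ch[j - 1], ch[j]]
      total <- total + p
    }
    unname(total)
  }
  for (cons in c("ACG", "RYW", "ANT", "WN")) {
    expect_equal(wordProbability(cons, bg), enumP(cons), info = cons)
  }
})

test_that("sigValue matches closed forms and the exact tail oracle", {
  expect_equal(sigValue(0, 100, 0.01, 5), 0)
  expect_equal(sigValue(10, 10, 0.1, 1), 10)
  ## derived values from the independent summation oracle
  expect_equal(sigValue(5, 100, 0.01, 1000),
               max(0, -log10(min(1, 1000 * binomTailOracle(5, 100, 0.01)))),
               tolerance = 1e-12)
  oracle8 <- -log10(1000 * binomTailOracle(8, 100, 0.01))
  expect_gt(oracle8, 0)
  expect_equal(sigValue(8, 100, 0.01, 1000), oracle8, tolerance = 1e-9)
  ## monotone in the observed count
  sigs <- sigValue(0:50, 1000, 0.01, 10)
  expect_true(all(diff(sigs) >= 0))
  expect_error(sigValue(11, 10, 0.1, 1), "exceeds")
  expect_error(sigValue(-1, 10, 0.1, 1), ">= 0")
  expect_error(sigValue(1, 10, 0, 1), "p0")
})

test_that("discovery ranks a planted word first with full coverage", {
  bgGenes <- sampleBackground(20, 800, seed = 7)
  pl <- plantMotifs(bgGenes, list(plantSpec("s", 20, "ACGCGT", 2)),
                    seed = 107)
  rep <- discoverMotifs(pl$genes)
  expect_gt(length(rep), 0)
  expect_identical(motifConsensus(rep)[1], "ACGCGT")
  expect_equal(rep@coverage[1], 1)
  ## independent exhaustive count for the winner
  expect_identical(rep@count[1], nrow(bruteScan("ACGCGT", pl$genes)))
})

test_that("every reported motif's count and coverage match a brute scan", {
  bgGenes <- sampleBackground(10, 400, seed = 11)
  pl <- plantMotifs(bgGenes, list(plantSpec("s", 10, "TGACTCA", 1)),
                    seed = 111)
  rep <- discoverMotifs(pl$genes, topM = 8)
  expect_gt(length(rep), 0)
  for (i in seq_along(rep@consensus)) {
    oracle <- bruteScan(rep@consensus[i], pl$genes)
    expect_identical(rep@count[i], nrow(oracle), info = rep@consensus[i])
    expect_identical(rep@count[i], nrow(rep@occurrences[[i]]))
    expect_equal(rep@coverage[i], length(unique(oracle$gene)) / 10)
  }
})

test_that("a consensus reachable from several kinds appears only once", {
  bgGenes <- sampleBackground(15, 600, seed = 3)
  pl <- plantMotifs(bgGenes, list(plantSpec("s", 15, "ACGCGT", 2)),
                    seed = 103)
  rep <- discoverMotifs(pl$genes)
  expect_false(anyDuplicated(motifConsensus(rep)) > 0)
})

test_that("discovery is deterministic: identical inputs, identical bytes", {
  bgGenes <- sampleBackground(12, 500, seed = 9)
  pl <- plantMotifs(bgGenes, list(plantSpec("s", 12, "GATTACA", 1)),
                    seed = 109)
  r1 <- discoverMotifs(pl$genes)
  r2 <- discoverMotifs(pl$genes)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeMotifReport(r1, f1); writeMotifReport(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("discovery rejects degenerate inputs", {
  expect_error(discoverMotifs(gs(g1 = "ACGT")), "at least 2")
})
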