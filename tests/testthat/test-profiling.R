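test_that("bin assignment uses left-open 200-bp bins by ceiling division", {
  expect_identical(binOf(1, 200, 4), 1L)
  expect_identical(binOf(200, 200, 4), 1L)
  expect_identical(binOf(201, 200, 4), 2L)
  expect_identical(binOf(620, 200, 4), 4L)
  expect_identical(binOf(800, 200, 4), 4L)
  expect_error(binOf(0, 200, 4), "out of range")
  expect_error(binOf(801, 200, 4), "out of range")
})

test_that("profile rows follow the forced bin layout", {
  genes <- gs(g1 = strrep("A", 800), g2 = strrep("A", 800))
  occ <- data.frame(gene = "g1", distance = c(150L, 350L, 620L),
                    strand = "+", stringsAsFactors = FALSE)
  rep <- new("MotifReport", consensus = "CCC", count = 3L, sig = 1,
             coverage = 0.5, occurrences = list(occ), nGenes = 2L,
             regionLength = 800L, nCandidates = 1)
  pm <- buildProfileMatrix(rep, genes)
  expect_identical(unname(profileCounts(pm)["g1", ]), c(1L, 1L, 0L, 1L))
  expect_identical(unname(profileCounts(pm)["g2", ]), c(0L, 0L, 0L, 0L))
  expect_identical(colnames(profileCounts(pm)),
                   paste0("CCC@bin", 1:4))
})

test_that("an empty report yields a zero-column matrix with all genes", {
  genes <- gs(g1 = strrep("A", 800), g2 = strrep("A", 800))
  rep <- new("MotifReport", consensus = character(0), count = integer(0),
             sig = numeric(0), coverage = numeric(0),
             occurrences = list(), nGenes = 2L, regionLength = 800L,
             nCandidates = 1)
  pm <- buildProfileMatrix(rep, genes)
  expect_identical(dim(pm), c(2L, 0L))
  expect_identical(rownames(profileCounts(pm)), c("g1", "g2"))
})

test_that("occurrences of unknown genes are a hard error", {
  genes <- gs(g1 = strrep("A", 800))
  occ <- data.frame(gene = "gX", distance = 10L, strand = "+",
                    stringsAsFactors = FALSE)
  rep <- new("MotifReport", consensus = "CCC", count = 1L, sig = 1,
             coverage = 1, occurrences = list(occ), nGenes = 1L,
             regionLength = 800L, nCandidates = 1)
  expect_error(buildProfileMatrix(rep, genes), "gX")
})

test_that("bin counts conserve per-gene occurrence totals on random fixtures", {
  set.seed(202)
  for (trial in 1:20) {
    nGenes <- sample(3:8, 1)
    ids <- paste0("g", seq_len(nGenes))
    genes <- GeneSet(stats::setNames(
      vapply(ids, function(i) strrep("A", 800), ""), ids),
      regionLength = 800)
    motifs <- paste0("M", 1:3, "CG")  # distinct labels
    occs <- lapply(motifs, function(m) {
      n <- sample(0:15, 1)
      data.frame(gene = sample(ids, n, replace = TRUE),
                 distance = sample(800, n, replace = TRUE),
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    rep <- new("MotifReport", consensus = motifs,
               count = vapply(occs, nrow, 0L),
               sig = rep(1, 3), coverage = vapply(occs, function(o)
                 length(unique(o$gene)) / nGenes, 0),
               occurrences = occs, nGenes = nGenes,
               regionLength = 800L, nCandidates = 1)
    pm <- buildProfileMatrix(rep, genes)
    m <- profileCounts(pm)
    for (j in seq_along(motifs)) {
      block <- m[, (j - 1) * 4 + 1:4, drop = FALSE]
      tab <- table(factor(occs[[j]]$gene, levels = ids))
      expect_identical(unname(rowSums(block)), as.numeric(tab))
      ## independent ceiling-division oracle per occurrence
      for (r in seq_len(nrow(occs[[j]]))) {
        b <- as.integer((occs[[j]]$distance[r] + 199) %/% 200)
        expect_identical(binOf(occs[[j]]$distance[r], 200, 4), b)
      }
    }
  }
})

test_that("permuting gene order permutes rows and nothing else", {
  ids <- paste0("g", 1:5)
  seqs <- stats::setNames(replicate(5, strrep("A", 800)), ids)
  genes <- GeneSet(seqs, regionLength = 800)
  occ <- data.frame(gene = c("g3", "g1", "g5"),
                    distance = c(10L, 300L, 700L), strand = "+",
                    stringsAsFactors = FALSE)
  rep <- new("MotifReport", consensus = "CCC", count = 3L, sig = 1,
             coverage = 0.6, occurrences = list(occ), nGenes = 5L,
             regionLength = 800L, nCandidates = 1)
  pm1 <- buildProfileMatrix(rep, genes)
  perm <- c(4, 2, 5, 1, 3)
  pm2 <- buildProfileMatrix(rep, genes[perm])
  expect_identical(profileCounts(pm2), profileCounts(pm1)[perm, ])
})

test_that("profile distances follow their definitions", {
  expect_equal(profileDistance(c(1, 2, 3), c(1, 2, 3), "cosine"), 0)
  expect_equal(profileDistance(c(1, 0), c(0, 1), "cosine"), 1)
  expect_equal(profileDistance(c(0, 0), c(1, 2), "cosine"), 1)
  expect_equal(profileDistance(c(0, 0), c(0, 0), "cosine"), 1)
  expect_equal(profileDistance(c(1, 0, 1, 0), c(0, 1, 0, 1),
                               "euclidean"), 2)
  expect_error(profileDistance(1:2, 1:3), "dimension")
})
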