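## small helper: ProfileMatrix literal from a plain matrix
pmOf <- function(m, nBins = 2L) {
  motifs <- paste0("M", seq_len(ncol(m) / nBins))
  colnames(m) <- paste0(rep(motifs, each = nBins), "@bin",
                        rep(seq_len(nBins), length(motifs)))
  new("ProfileMatrix", counts = m, motifs = motifs,
      nBins = as.integer(nBins), binWidth = 100L)
}

test_that("similarity graph weights reflect profile distances", {
  m <- rbind(g1 = c(2L, 0L), g2 = c(2L, 0L), g3 = c(0L, 3L))
  g <- similarityGraph(pmOf(m, 1L), k = 2)
  e <- g$edges
  w12 <- e$weight[e$from == 1 & e$to == 2]
  w13 <- e$weight[e$from == 1 & e$to == 3]
  expect_equal(w12, 1)   # identical rows
  expect_equal(w13, 0)   # orthogonal one-hots under cosine
  expect_error(similarityGraph(pmOf(m, 1L), k = 3), "smaller")
})

test_that("two identical triplets with k=2 give two disjoint triangles", {
  m <- rbind(a1 = c(5L, 0L), a2 = c(5L, 0L), a3 = c(5L, 0L),
             b1 = c(0L, 7L), b2 = c(0L, 7L), b3 = c(0L, 7L))
  g <- similarityGraph(pmOf(m, 1L), k = 2)
  e <- g$edges
  ## oracle: exhaustive pairwise distances say neighbours are in-group
  expect_identical(nrow(e), 6L)             # 2 triangles
  grp <- rep(c(1, 2), each = 3)
  expect_true(all(grp[e$from] == grp[e$to]))
})

test_that("force layout is seeded, order-invariant and handles one node", {
  m <- rbind(a = c(1L, 0L), b = c(0L, 1L), c = c(1L, 1L))
  g <- similarityGraph(pmOf(m, 1L), k = 1)
  l1 <- forceLayout(g, layoutParams(seed = 4))
  l2 <- forceLayout(g, layoutParams(seed = 4))
  expect_identical(l1$coords, l2$coords)
  l3 <- forceLayout(g, layoutParams(seed = 5))
  expect_false(identical(l1$coords, l3$coords))
  single <- list(nodes = "solo", edges = data.frame(
    from = integer(0), to = integer(0), weight = numeric(0)))
  ls <- forceLayout(single, layoutParams(seed = 1))
  expect_identical(ls$iterations, 1L)
  expect_identical(rownames(ls$coords), "solo")
})

test_that("unconnected cliques end further apart than their spreads", {
  m <- rbind(matrix(rep(c(4L, 0L), each = 20), ncol = 2,
                    dimnames = list(paste0("a", 1:20), NULL)),
             matrix(rep(c(0L, 4L), each = 20), ncol = 2,
                    dimnames = list(paste0("b", 1:20), NULL)))
  for (sd in 1:5) {
    g <- similarityGraph(pmOf(m, 1L), k = 5)
    co <- forceLayout(g, layoutParams(seed = sd))$coords
    cA <- colMeans(co[1:20, ]); cB <- colMeans(co[21:40, ])
    between <- sqrt(sum((cA - cB)^2))
    spreadA <- mean(dist(co[1:20, ])); spreadB <- mean(dist(co[21:40, ]))
    expect_gt(between, spreadA)
    expect_gt(between, spreadB)
  }
})

test_that("density surface is a proper kernel density", {
  co <- cbind(c(0.2, 0.8), c(0.2, 0.8))
  rownames(co) <- c("a", "b")
  ld <- densityLandscape(co, bandwidth = 0.05, gridSize = 96)
  expect_true(all(ld$density >= 0))
  ## integrates to about n
  cell <- diff(ld$gridX[1:2]) * diff(ld$gridY[1:2])
  expect_equal(sum(ld$density) * cell, 2, tolerance = 0.01)
  ## two far-separated points: two near-equal local maxima
  pk <- extractPeaks(ld, co, minProminence = 0.2)
  expect_identical(nrow(pk$peaks), 2L)
  expect_equal(pk$peaks$height[1], pk$peaks$height[2], tolerance = 0.05)
  ## single point: maximum lands at the nearest grid cell
  ld1 <- densityLandscape(co[1, , drop = FALSE], bandwidth = 0.05)
  idx <- which(ld1$density == max(ld1$density), arr.ind = TRUE)
  expect_lt(abs(ld1$gridX[idx[1]] - 0.2), 0.05)
  expect_lt(abs(ld1$gridY[idx[2]] - 0.2), 0.05)
})

test_that("prominence gates peaks and labels follow basins", {
  set.seed(1)
  co <- rbind(matrix(rnorm(40, 0, 0.03), ncol = 2) + 0.2,
              matrix(rnorm(40, 0, 0.03), ncol = 2) + 0.8)
  rownames(co) <- paste0("g", 1:40)
  ld <- densityLandscape(co, bandwidth = 0.05)
  pk <- extractPeaks(ld, co, minProminence = 0.2)
  expect_identical(nrow(pk$peaks), 2L)
  expect_identical(sort(as.integer(table(pk$labels))), c(20L, 20L))
  ## a 0.999 prominence gate keeps only the global maximum
  pk1 <- extractPeaks(ld, co, minProminence = 0.999)
  expect_identical(nrow(pk1$peaks), 1L)
  ## peak count is monotone non-increasing in the gate
  counts <- vapply(c(0.05, 0.2, 0.5, 0.8, 0.999), function(p)
    nrow(extractPeaks(ld, co, p)$peaks), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("perfectly separated profile groups are recovered exactly", {
  for (sd in 1:5) {
    m <- rbind(matrix(rep(c(3L, 0L, 0L), each = 6), ncol = 3),
               matrix(rep(c(0L, 3L, 0L), each = 6), ncol = 3),
               matrix(rep(c(0L, 0L, 3L), each = 6), ncol = 3))
    rownames(m) <- paste0("g", 1:18)
    truth <- rep(c("A", "B", "C"), each = 6)
    res <- clusterGenes(pmOf(m, 1L), params = layoutParams(
      kNeighbors = 5, seed = sd))
    expect_equal(ari(clusterLabels(res)[rownames(m)], truth), 1,
                 info = paste("seed", sd))
  }
})

test_that("degenerate and edge cases behave as specified", {
  ## two identical genes: one peak holding both
  m2 <- rbind(g1 = c(2L, 1L), g2 = c(2L, 1L))
  res <- clusterGenes(pmOf(m2, 1L), params = layoutParams(kNeighbors = 1))
  expect_identical(nrow(landscapePeaks(res)), 1L)
  expect_identical(unname(clusterLabels(res)), c("peak1", "peak1"))
  ## all-zero profiles refuse to cluster
  m0 <- rbind(g1 = c(0L, 0L), g2 = c(0L, 0L))
  expect_error(clusterGenes(pmOf(m0, 1L)), "zero")
  ## zero-profile genes are labelled unclustered, others normally
  m1 <- rbind(g1 = c(2L, 0L), g2 = c(2L, 0L), g3 = c(0L, 0L))
  res1 <- clusterGenes(pmOf(m1, 1L), params = layoutParams(kNeighbors = 2))
  expect_identical(unname(clusterLabels(res1)["g3"]), "unclustered")
})

test_that("duplicating every profile preserves the number of peaks", {
  m <- rbind(matrix(rep(c(3L, 0L), each = 8), ncol = 2,
                    dimnames = list(paste0("a", 1:8), NULL)),
             matrix(rep(c(0L, 3L), each = 8), ncol = 2,
                    dimnames = list(paste0("b", 1:8), NULL)))
  res1 <- clusterGenes(pmOf(m, 1L), params = layoutParams(
    kNeighbors = 4, seed = 2))
  md <- rbind(m, m)
  rownames(md) <- c(rownames(m), paste0(rownames(m), "dup"))
  res2 <- clusterGenes(pmOf(md, 1L), params = layoutParams(
    kNeighbors = 4, seed = 2))
  expect_identical(nrow(landscapePeaks(res1)), nrow(landscapePeaks(res2)))
})

test_that("labels are invariant to gene input order", {
  set.seed(5)
  m <- rbind(matrix(rep(c(3L, 0L), each = 7), ncol = 2),
             matrix(rep(c(0L, 4L), each = 7), ncol = 2))
  rownames(m) <- paste0("g", 1:14)
  res1 <- clusterGenes(pmOf(m, 1L), params = layoutParams(
    kNeighbors = 3, seed = 8))
  perm <- sample(14)
  res2 <- clusterGenes(pmOf(m[perm, ], 1L), params = layoutParams(
    kNeighbors = 3, seed = 8))
  l1 <- clusterLabels(res1); l2 <- clusterLabels(res2)
  expect_identical(l1[sort(names(l1))], l2[sort(names(l2))])
})
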