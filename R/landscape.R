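## Landscape clustering: a force-directed layout of the gene-motif
## vectors on a plane, run under a geometric annealing schedule until
## movement ceases, followed by kernel-density estimation of the
## resulting point "terrain" and extraction of prominence-filtered
## density peaks with steepest-ascent basin assignment. The number of
## clusters is never preset: it is whatever the terrain supports.

#' Layout and annealing parameters
#'
#' @param kNeighbors Neighbours per gene in the similarity graph
#'   (default 10; must be smaller than the number of genes).
#' @param attractionScale,repulsionScale Force scales of the spring
#'   attraction along edges and the inverse-distance pairwise repulsion.
#' @param coolingFactor Geometric cooling factor in (0, 1), default 0.95.
#' @param initialTemperature Starting step cap, as a fraction of the
#'   unit layout square (default 0.25).
#' @param convergenceTol Stop when the largest per-iteration displacement
#'   falls below this (default `1e-3 * sqrt(2)`, i.e. one thousandth of
#'   the initial plane diagonal).
#' @param maxIterations Hard iteration cap (default 2000).
#' @param seed Integer seed keying the initial random scatter.
#' @return A named list of class `"LayoutParams"`.
#' @export
layoutParams <- function(kNeighbors = 10L, attractionScale = 1,
                         repulsionScale = 1, coolingFactor = 0.95,
                         initialTemperature = 0.25,
                         convergenceTol = 1e-3 * sqrt(2),
                         maxIterations = 2000L, seed = 1L) {
  stopifnot(coolingFactor > 0, coolingFactor < 1, convergenceTol > 0,
            kNeighbors >= 1L, maxIterations >= 1L)
  structure(list(kNeighbors = as.integer(kNeighbors),
                 attractionScale = attractionScale,
                 repulsionScale = repulsionScale,
                 coolingFactor = coolingFactor,
                 initialTemperature = initialTemperature,
                 convergenceTol = convergenceTol,
                 maxIterations = as.integer(maxIterations),
                 seed = as.integer(seed)),
            class = "LayoutParams")
}

#' Mutualized k-nearest-neighbour similarity graph over genes
#'
#' Each gene is connected to its k nearest neighbours under the chosen
#' profile metric; an edge is kept if either endpoint lists the other.
#' Edge weight is `1 - d / dmax` where `dmax` is the largest pairwise
#' distance in the matrix (so weights lie in `[0, 1]`; identical
#' profiles get weight 1, maximally distant ones weight 0). No
#' self-loops.
#'
#' @param profiles A [ProfileMatrix-class].
#' @param metric `"cosine"` (default) or `"euclidean"`.
#' @param k Number of neighbours; must be `< n` genes.
#' @return A list with `nodes` (gene ids) and `edges` (data.frame
#'   `from`, `to`, `weight`, with `from < to` by node index).
#' @export
similarityGraph <- function(profiles, metric = "cosine", k = 10L) {
  stopifnot(is(profiles, "ProfileMatrix"))
  m <- profileCounts(profiles)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 genes", call. = FALSE)
  if (k >= n) stop("k (", k, ") must be smaller than the number of genes (",
                   n, ")", call. = FALSE)
  d <- .pairwiseDistances(m, metric)
  dmax <- max(d)
  ## a numerically-zero spread means all profiles are identical
  wgt <- if (dmax > 1e-9) 1 - d / dmax else matrix(1, n, n)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    o <- order(d[i, -i])      # ties: first index, deterministic
    nb <- setdiff(seq_len(n), i)[o][seq_len(k)]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)         # mutualized: either endpoint suffices
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  list(nodes = rownames(m),
       edges = data.frame(from = idx[, 1L], to = idx[, 2L],
                          weight = wgt[idx], stringsAsFactors = FALSE))
}

#' Force-directed layout with geometric annealing
#'
#' Nodes start uniformly scattered on the unit square at positions keyed
#' to their ids and the seed (so the layout is invariant to input
#' order). Each iteration every node moves along the sum of spring
#' attraction along its edges (proportional to weight times distance)
#' and inverse-distance pairwise repulsion, with the step length capped
#' by the current temperature; the temperature is multiplied by the
#' cooling factor each iteration and iteration stops when the largest
#' displacement falls below the convergence tolerance (or at the
#' iteration cap).
#'
#' @param graph A graph from [similarityGraph()].
#' @param params A [layoutParams()].
#' @return A list with `coords` (n x 2 matrix, rownames node ids) and
#'   `iterations`.
#' @export
forceLayout <- function(graph, params = layoutParams()) {
  nodes <- graph$nodes
  n <- length(nodes)
  pos <- t(vapply(nodes, .keyedUniforms, numeric(2L),
                  seed = params$seed, n = 2L))
  rownames(pos) <- nodes
  if (n == 1L) return(list(coords = pos, iterations = 1L))
  e <- graph$edges
  kconst <- sqrt(1 / n)
  temp <- params$initialTemperature
  iter <- 0L
  repeat {
    iter <- iter + 1L
    dx <- outer(pos[, 1L], pos[, 1L], "-")
    dy <- outer(pos[, 2L], pos[, 2L], "-")
    dd <- sqrt(dx^2 + dy^2)
    dd[dd < 1e-9] <- 1e-9
    ## repulsion: away from every other node, ~ 1/distance
    rep_ <- params$repulsionScale * kconst^2 / dd
    diag(rep_) <- 0
    fx <- rowSums(rep_ * dx / dd)
    fy <- rowSums(rep_ * dy / dd)
    ## attraction along edges, ~ weight * distance^2 / k (spring)
    if (nrow(e)) {
      i <- e$from; j <- e$to
      exd <- pos[j, 1L] - pos[i, 1L]
      eyd <- pos[j, 2L] - pos[i, 2L]
      ed <- sqrt(exd^2 + eyd^2)
      ed[ed < 1e-9] <- 1e-9
      f <- params$attractionScale * e$weight * ed^2 / kconst
      axc <- f * exd / ed
      ayc <- f * eyd / ed
      fx <- fx + tabulate2(i, axc, n) - tabulate2(j, axc, n)
      fy <- fy + tabulate2(i, ayc, n) - tabulate2(j, ayc, n)
    }
    fl <- sqrt(fx^2 + fy^2)
    fl[fl < 1e-12] <- 1e-12
    step <- pmin(fl, temp)
    pos[, 1L] <- pos[, 1L] + fx / fl * step
    pos[, 2L] <- pos[, 2L] + fy / fl * step
    temp <- temp * params$coolingFactor
    if (max(step) < params$convergenceTol || iter >= params$maxIterations) {
      break
    }
  }
  list(coords = pos, iterations = iter)
}

## sum values v by integer group index i into a length-n vector
tabulate2 <- function(i, v, n) {
  out <- numeric(n)
  s <- rowsum(v, group = i)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

#' Gaussian kernel density surface over layout coordinates
#'
#' Isotropic Gaussian KDE on a square grid covering the bounding box of
#' the points padded by three bandwidths. Each kernel integrates to 1,
#' so the surface integrates to approximately the number of genes.
#'
#' @param coords n x 2 coordinate matrix.
#' @param bandwidth Kernel standard deviation; default half the
#'   Scott rule, `0.5 * sigma * n^(-1/6)` with `sigma` the root mean
#'   coordinate variance (floored at 1e-3 for degenerate point sets).
#'   The halving deliberately undersmooths relative to the
#'   density-estimation optimum: the surface is used for mode
#'   detection, where Scott's rule is known to blur nearby modes into
#'   shoulders.
#' @param gridSize Grid cells per axis (default 128).
#' @return A list with `density` (gridSize x gridSize matrix, rows = x),
#'   `gridX`, `gridY` (cell-centre coordinates) and `bandwidth`.
#' @export
densityLandscape <- function(coords, bandwidth = NULL, gridSize = 128L) {
  stopifnot(is.matrix(coords), ncol(coords) == 2L, nrow(coords) >= 1L)
  n <- nrow(coords)
  if (is.null(bandwidth)) {
    sigma <- sqrt(mean(c(var(coords[, 1L]), var(coords[, 2L])),
                       na.rm = TRUE))
    if (!is.finite(sigma) || sigma < 1e-3) sigma <- 1e-3
    bandwidth <- 0.5 * sigma * n^(-1 / 6)
    if (n >= 2L) {
      ## the layout keeps even identical items a small equilibrium
      ## distance apart; never resolve that packing distance as
      ## separate modes
      nn <- as.matrix(stats::dist(coords))
      diag(nn) <- Inf
      bandwidth <- max(bandwidth, 0.75 * mean(apply(nn, 1L, min)))
    }
  }
  stopifnot(bandwidth > 0)
  pad <- 3 * bandwidth
  gx <- seq(min(coords[, 1L]) - pad, max(coords[, 1L]) + pad,
            length.out = gridSize)
  gy <- seq(min(coords[, 2L]) - pad, max(coords[, 2L]) + pad,
            length.out = gridSize)
  kx <- exp(-outer(gx, coords[, 1L], "-")^2 / (2 * bandwidth^2))
  ky <- exp(-outer(gy, coords[, 2L], "-")^2 / (2 * bandwidth^2))
  dens <- (kx %*% t(ky)) / (2 * pi * bandwidth^2)
  list(density = dens, gridX = gx, gridY = gy, bandwidth = bandwidth)
}

## 8-neighbour offsets on the grid
.NEIGH <- cbind(dx = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                dy = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))

## steepest-ascent pointer for every grid cell (0 = local maximum).
## Plateaus (exact value ties, e.g. on symmetric surfaces) are resolved
## by a total order (value, then lower linear index), matching the
## tie order of the persistence sweep.
.ascentPointers <- function(dens) {
  nx <- nrow(dens); ny <- ncol(dens)
  self <- matrix(seq_len(nx * ny), nx, ny)
  bestIdx <- self
  bestVal <- dens
  for (k in seq_len(nrow(.NEIGH))) {
    dx <- .NEIGH[k, 1L]; dy <- .NEIGH[k, 2L]
    xs <- max(1L, 1L - dx):min(nx, nx - dx)
    ys <- max(1L, 1L - dy):min(ny, ny - dy)
    shifted <- matrix(-Inf, nx, ny)
    shifted[xs, ys] <- dens[xs + dx, ys + dy]
    candIdx <- self + dx + dy * nx
    upd <- shifted > bestVal |
      (shifted == bestVal & is.finite(shifted) & candIdx < bestIdx)
    bestVal[upd] <- shifted[upd]
    bestIdx[upd] <- candIdx[upd]
  }
  best <- bestIdx
  best[bestIdx == self] <- 0L
  best
}

#' Extract density peaks and assign genes to basins
#'
#' Local maxima of the density grid are filtered by topographic
#' prominence (height above the highest saddle connecting the maximum
#' to any higher terrain, computed by a watershed/persistence sweep);
#' maxima with prominence below `minProminence` times the global
#' maximum are discarded. Every gene then follows a discrete
#' steepest-ascent path from its nearest grid cell; genes whose path
#' ends at a retained peak get that peak's label, all others are
#' `"unclustered"`.
#'
#' @param landscape Result of [densityLandscape()].
#' @param coords The coordinates the landscape was computed from.
#' @param minProminence Fraction of the global maximum height
#'   (default 0.1), in (0, 1).
#' @return A list with `peaks` (data.frame `peak`, `ix`, `iy`, `x`, `y`,
#'   `height`, `prominence`, height-descending) and `labels` (named
#'   character vector over the rows of `coords`).
#' @export
extractPeaks <- function(landscape, coords, minProminence = 0.1) {
  dens <- landscape$density
  if (!length(dens)) stop("empty density grid", call. = FALSE)
  stopifnot(minProminence > 0, minProminence < 1)
  nx <- nrow(dens); ny <- ncol(dens)
  gmax <- max(dens)

  ## persistence sweep: process cells from high to low, union-find on
  ## components; a local max "dies" (its prominence is fixed) when its
  ## component merges into a higher-peaked one.
  ord <- order(dens, decreasing = TRUE)
  parent <- integer(nx * ny)            # 0 = unprocessed
  compPeak <- integer(nx * ny)          # root -> peak cell index
  prominence <- rep(NA_real_, nx * ny)  # peak cell -> prominence
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (cell in ord) {
    x <- (cell - 1L) %% nx + 1L
    y <- (cell - 1L) %/% nx + 1L
    roots <- integer(0)
    for (k in seq_len(nrow(.NEIGH))) {
      xn <- x + .NEIGH[k, 1L]; yn <- y + .NEIGH[k, 2L]
      if (xn < 1L || xn > nx || yn < 1L || yn > ny) next
      ncell <- xn + (yn - 1L) * nx
      if (parent[ncell] != 0L) roots <- c(roots, findRoot(ncell))
    }
    roots <- unique(roots)
    if (!length(roots)) {
      parent[cell] <- cell
      compPeak[cell] <- cell
      next
    }
    hts <- dens[compPeak[roots]]
    main <- roots[which.max(hts)]
    parent[cell] <- main
    for (r in setdiff(roots, main)) {
      ## r's peak dies at this saddle height
      prominence[compPeak[r]] <- dens[compPeak[r]] - dens[cell]
      parent[r] <- main
    }
  }
  ## the global maximum never dies; its prominence is its height
  top <- compPeak[findRoot(which.max(dens))]
  prominence[top] <- dens[top]
  peakCells <- which(!is.na(prominence))
  keep <- peakCells[prominence[peakCells] >= minProminence * gmax]
  keep <- keep[order(-dens[keep], keep)]
  peakIds <- paste0("peak", seq_along(keep))
  px <- (keep - 1L) %% nx + 1L
  py <- (keep - 1L) %/% nx + 1L
  peaks <- data.frame(peak = peakIds, ix = px, iy = py,
                      x = landscape$gridX[px], y = landscape$gridY[py],
                      height = dens[keep],
                      prominence = prominence[keep],
                      stringsAsFactors = FALSE)

  ## steepest-ascent basin per gene
  ptr <- .ascentPointers(dens)
  cellOf <- function(x, y) {
    ix <- which.min(abs(landscape$gridX - x))
    iy <- which.min(abs(landscape$gridY - y))
    ix + (iy - 1L) * nx
  }
  peakLabelOf <- rep(NA_integer_, nx * ny)
  peakLabelOf[keep] <- seq_along(keep)
  labels <- character(nrow(coords))
  maxSteps <- nx * ny
  for (g in seq_len(nrow(coords))) {
    cell <- cellOf(coords[g, 1L], coords[g, 2L])
    for (s in seq_len(maxSteps)) {
      nxt <- ptr[cell]
      if (nxt == 0L) break
      cell <- nxt
    }
    labels[g] <- if (!is.na(peakLabelOf[cell])) {
      peakIds[peakLabelOf[cell]]
    } else "unclustered"
  }
  names(labels) <- rownames(coords)
  list(peaks = peaks, labels = labels)
}

#' Cluster genes by their motif-profile landscape
#'
#' Composition of [similarityGraph()], [forceLayout()],
#' [densityLandscape()] and [extractPeaks()]: the full
#' terrain-clustering procedure from profile matrix to peak-labelled
#' genes. Genes whose
#' profile is all zero are always labelled `"unclustered"`.
#'
#' @param profiles A [ProfileMatrix-class] with at least 2 genes and at
#'   least one nonzero row.
#' @param params A [layoutParams()]; `kNeighbors` is truncated to
#'   `n - 1` when the gene set is small.
#' @param metric Profile metric (default `"cosine"`).
#' @param bandwidth KDE bandwidth; default Scott-style rule.
#' @param gridSize Density grid resolution (default 128).
#' @param minProminence Peak prominence threshold (default 0.1).
#' @return A [LandscapeResult-class].
#' @export
clusterGenes <- function(profiles, params = layoutParams(),
                         metric = "cosine", bandwidth = NULL,
                         gridSize = 128L, minProminence = 0.1) {
  stopifnot(is(profiles, "ProfileMatrix"))
  m <- profileCounts(profiles)
  if (nrow(m) < 2L) stop("need at least 2 genes", call. = FALSE)
  if (all(m == 0L)) {
    stop("all gene profiles are zero; no motifs to cluster on ",
         "(lower minSig upstream)", call. = FALSE)
  }
  k <- min(params$kNeighbors, nrow(m) - 1L)
  params$kNeighbors <- k
  graph <- similarityGraph(profiles, metric = metric, k = k)
  layout <- forceLayout(graph, params)
  landscape <- densityLandscape(layout$coords, bandwidth = bandwidth,
                                gridSize = gridSize)
  pk <- extractPeaks(landscape, layout$coords,
                     minProminence = minProminence)
  labels <- pk$labels
  labels[rowSums(m) == 0L] <- "unclustered"
  new("LandscapeResult", coords = layout$coords,
      density = landscape$density, gridX = landscape$gridX,
      gridY = landscape$gridY, peaks = pk$peaks, labels = labels,
      params = list(metric = metric, kNeighbors = k,
                    attractionScale = params$attractionScale,
                    repulsionScale = params$repulsionScale,
                    coolingFactor = params$coolingFactor,
                    initialTemperature = params$initialTemperature,
                    convergenceTol = params$convergenceTol,
                    maxIterations = params$maxIterations,
                    seed = params$seed,
                    bandwidth = landscape$bandwidth,
                    gridSize = gridSize,
                    minProminence = minProminence,
                    iterations = layout$iterations))
}
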