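## Functional-category enrichment of gene subsets against a universe
## (by default the starting co-expressed set), with hypergeometric
## upper-tail p-values, Benjamini-Hochberg adjustment, and a
## subset-vs-parent comparison that flags improved and newly emergent
## categories.

#' Hypergeometric upper-tail probability
#'
#' `P[X >= x]` for X hypergeometric with `K` category genes in a
#' universe of `N`, drawing the subset of size `n`. Computed in log
#' space via [stats::phyper()].
#'
#' @param x Overlap (category genes inside the subset).
#' @param K Category size in the universe.
#' @param n Subset size.
#' @param N Universe size.
#' @return The upper-tail probability; 1 when `x = 0`.
#' @examples
#' hypergeomUpperTail(4, K = 5, n = 8, N = 20)
#' @export
hypergeomUpperTail <- function(x, K, n, N) {
  if (any(K < 0) || any(K > N) || any(n < 0) || any(n > N) ||
      any(x < 0) || any(x > pmin(K, n))) {
    stop("require 0 <= K <= N, 0 <= n <= N, 0 <= x <= min(K, n)",
         call. = FALSE)
  }
  exp(phyper(x - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up FDR adjustment with monotonicity enforcement;
#' output order matches input order.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return q-values in input order.
#' @export
bhAdjust <- function(pvalues) {
  if (any(pvalues <= 0) || any(pvalues > 1) || anyNA(pvalues)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = "BH")
}

#' Category enrichment of a gene subset
#'
#' Tests every annotation category with at least one subset member for
#' over-representation in the subset relative to the universe. Counts
#' are computed against the universe only (annotation entries for genes
#' outside it are ignored). Categories whose subset overlap is exactly
#' one gene are reported but flagged (`singleton = TRUE`).
#'
#' @param subset Character vector of gene ids; must be contained in
#'   `universe`.
#' @param universe Character vector of gene ids.
#' @param annotation Named list, gene id -> character vector of
#'   categories (as from [readAnnotation()]).
#' @return A data.frame with columns `category`, `N`, `K`, `n`, `x`,
#'   `p`, `q`, `singleton`, sorted by p ascending then category id.
#' @export
enrichSubset <- function(subset, universe, annotation) {
  subset <- unique(subset); universe <- unique(universe)
  if (!all(subset %in% universe)) {
    stop("subset contains genes outside the universe: ",
         paste(head(setdiff(subset, universe), 3L), collapse = ", "),
         call. = FALSE)
  }
  ann <- annotation[names(annotation) %in% universe]
  if (!length(ann)) {
    return(data.frame(category = character(0), N = integer(0),
                      K = integer(0), n = integer(0), x = integer(0),
                      p = numeric(0), q = numeric(0),
                      singleton = logical(0), stringsAsFactors = FALSE))
  }
  g <- rep(names(ann), lengths(ann))
  cat_ <- unlist(ann, use.names = FALSE)
  N <- length(universe)
  n <- length(subset)
  Ktab <- table(cat_)
  inSub <- g %in% subset
  xtab <- table(cat_[inSub])
  cats <- names(xtab)          # only categories with >= 1 subset member
  if (!length(cats)) {
    return(enrichSubset(subset, universe, list()))
  }
  K <- as.integer(Ktab[cats])
  x <- as.integer(xtab[cats])
  p <- hypergeomUpperTail(x, K, n, N)
  res <- data.frame(category = cats, N = N, K = K, n = n, x = x, p = p,
                    q = bhAdjust(p), singleton = x == 1L,
                    stringsAsFactors = FALSE)
  res[order(res$p, res$category), , drop = FALSE]
}

#' Compare subset enrichments to parent-set enrichments
#'
#' Classifies each category appearing in either result:
#' `"new"` if significant in the subset (q below `fdr`) but not in the
#' parent; `"improved"` if significant in both with the subset p smaller
#' by at least `fold`; `"absent"` if the category has no subset row;
#' `"unchanged"` otherwise. Both inputs must have been computed against
#' the same universe and annotation.
#'
#' @param subsetRows,parentRows Results of [enrichSubset()].
#' @param fold Minimum p-value improvement factor for `"improved"`
#'   (default 100, i.e. two orders of magnitude).
#' @param fdr Significance gate on BH q-values (default 0.05).
#' @return A data.frame `category`, `pSubset`, `qSubset`, `pParent`,
#'   `status`, sorted by subset p (absent categories last).
#' @export
compareToParent <- function(subsetRows, parentRows, fold = 100,
                            fdr = 0.05) {
  cats <- union(subsetRows$category, parentRows$category)
  iS <- match(cats, subsetRows$category)
  iP <- match(cats, parentRows$category)
  pS <- subsetRows$p[iS]; qS <- subsetRows$q[iS]
  pP <- parentRows$p[iP]; qP <- parentRows$q[iP]
  status <- character(length(cats))
  for (i in seq_along(cats)) {
    status[i] <- if (is.na(pS[i])) {
      "absent"
    } else if (!is.na(qS[i]) && qS[i] < fdr &&
               (is.na(qP[i]) || qP[i] >= fdr)) {
      "new"
    } else if (!is.na(qS[i]) && qS[i] < fdr && !is.na(qP[i]) &&
               qP[i] < fdr && pP[i] / pS[i] >= fold) {
      "improved"
    } else "unchanged"
  }
  out <- data.frame(category = cats, pSubset = pS, qSubset = qS,
                    pParent = pP, status = status,
                    stringsAsFactors = FALSE)
  out[order(is.na(out$pSubset), out$pSubset, out$category), ,
      drop = FALSE]
}
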