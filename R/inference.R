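#' Jaccard dissimilarity between two barcode sets
#'
#' d(X, Y) = 1 - |X intersect Y| / |X union Y|, the clustering distance for
#' lineage reconstruction. Undefined (error) when both sets are empty;
#' callers must pre-filter unlabeled cells.
#'
#' @param x,y integer vectors (barcode-type ids).
#' @return dissimilarity in [0, 1].
#' @examples
#' jaccardDissimilarity(c(1, 2), c(2, 3))  # 2/3
#' @export
jaccardDissimilarity <- function(x, y) {
  x <- unique(x); y <- unique(y)
  u <- length(union(x, y))
  if (u == 0L) stop("Jaccard dissimilarity is undefined for two empty sets")
  1 - length(intersect(x, y)) / u
}

## pairwise Jaccard dissimilarity over a list of non-empty sets, via the
## sparse cell x barcode incidence matrix: |X ∩ Y| = X Y^T, |X ∪ Y| = |X| +
## |Y| - |X ∩ Y|.
.jaccardMatrix <- function(sets) {
  n <- length(sets)
  lens <- lengths(sets)
  stopifnot(all(lens > 0L))
  if (n == 1L) {
    d <- matrix(0, 1, 1)
    return(d)
  }
  j <- unlist(sets, use.names = FALSE)
  ju <- sort.int(unique(j))
  X <- Matrix::sparseMatrix(i = rep.int(seq_len(n), lens),
                            j = match(j, ju), x = 1,
                            dims = c(n, length(ju)))
  inter <- as.matrix(Matrix::tcrossprod(X))
  un <- outer(lens, lens, "+") - inter
  d <- 1 - inter / un
  diag(d) <- 0
  d
}

.cellKeys <- function(generation, cellId) {
  if (length(cellId) == 0L) return(character(0))
  paste0("g", generation, ":c", cellId)
}

#' Pairwise dissimilarity matrix over observed labeled cells
#'
#' Aggregates the observed cells from all snapshots, drops those with empty
#' observed sets, orders the rest deterministically by (generation, cell_id)
#' and evaluates the Jaccard dissimilarity for every pair.
#'
#' @param table an [ObservedCellTable-class].
#' @return symmetric numeric matrix with zero diagonal; dimnames are
#'   \code{"g<generation>:c<cell_id>"} keys; attribute \code{nExcluded}
#'   counts the empty-set cells left out.
#' @export
buildDistanceMatrix <- function(table) {
  stopifnot(is(table, "ObservedCellTable"))
  keep <- which(lengths(table@sets) > 0L)
  if (length(keep) == 0L) stop("no labeled cells: every observed set is empty")
  ord <- keep[order(table@generation[keep], table@cellId[keep])]
  d <- .jaccardMatrix(table@sets[ord])
  dimnames(d) <- list(.cellKeys(table@generation[ord], table@cellId[ord]),
                      .cellKeys(table@generation[ord], table@cellId[ord]))
  attr(d, "nExcluded") <- nCells(table) - length(keep)
  d
}

#' Single-linkage dendrogram of a dissimilarity matrix
#'
#' Standard agglomerative single-linkage ('bottom-up') clustering. Under
#' single linkage the flat clusters at any threshold D are exactly the
#' connected components of the graph whose edges join pairs at dissimilarity
#' at most D — which is what makes it the faithful realisation of the
#' "any non-zero overlap" lineage-building rule.
#'
#' @param distanceMatrix symmetric dissimilarity matrix (from
#'   [buildDistanceMatrix()]), or anything [stats::as.dist()] accepts.
#' @return an object of class \code{hclust} (merge heights nondecreasing).
#' @export
singleLinkageDendrogram <- function(distanceMatrix) {
  d <- stats::as.dist(distanceMatrix)
  if (attr(d, "Size") < 2L)
    stop("need at least two cells to build a dendrogram")
  stats::hclust(d, method = "single")
}

## flat clusters of `dend` at dissimilarity threshold D (merges with height
## <= D are inside clusters), renumbered in order of first appearance
.cutAt <- function(dend, threshold) {
  cl <- stats::cutree(dend, h = threshold)
  as.integer(match(cl, unique(cl)))
}

#' Cut at the any-overlap threshold (D just below 1)
#'
#' Joins two cells whenever they are connected by a chain of pairs sharing
#' at least one barcode. Implemented as a flat cut at 1 - 1e-9: observed
#' dissimilarities are rationals bounded away from 1 by at least
#' 1/|X union Y|, so any threshold strictly below 1 and above the largest
#' attainable non-unit dissimilarity yields the same partition.
#'
#' @param dend an \code{hclust} dendrogram from [singleLinkageDendrogram()].
#' @return integer cluster vector (named by cell key when the input matrix
#'   carried dimnames), with attributes \code{threshold} and
#'   \code{strategy}.
#' @export
cutAnyOverlap <- function(dend) {
  cl <- .cutAt(dend, 1 - 1e-9)
  attr(cl, "threshold") <- 1 - 1e-9
  attr(cl, "strategy") <- "any_overlap"
  cl
}

#' Cut at the minimal-dissimilarity threshold (D = 0)
#'
#' Merges cells only when their observed sets are identical (dissimilarity
#' exactly 0). This realises the maximal cluster count the dendrogram
#' supports — the reading in which the number of cells proxies the maximal
#' possible number of lineages.
#'
#' @inheritParams cutAnyOverlap
#' @return integer cluster vector with attributes \code{threshold},
#'   \code{strategy}.
#' @export
cutMin <- function(dend) {
  cl <- .cutAt(dend, 0)
  attr(cl, "threshold") <- 0
  attr(cl, "strategy") <- "min_d"
  cl
}

#' Cut at the threshold matching a known lineage count (D*)
#'
#' Scans candidate thresholds — the dendrogram's merge heights plus 0 — and
#' picks the one whose flat-cluster count is closest to \code{target}; ties
#' prefer the smaller threshold (more clusters). Requires knowing the true
#' lineage count, which real experiments typically do not.
#'
#' @inheritParams cutAnyOverlap
#' @param target desired number of clusters (>= 1).
#' @return integer cluster vector with attributes \code{threshold},
#'   \code{strategy}.
#' @export
cutByTargetCount <- function(dend, target) {
  target <- as.integer(target)
  if (is.na(target) || target < 1L) stop("target must be a positive integer")
  n <- length(dend$order)
  cand <- sort.int(unique(c(0, dend$height)))
  ## cluster count at threshold t: n minus the merges at height <= t
  counts <- n - vapply(cand, function(t) sum(dend$height <= t), integer(1))
  best <- which(abs(counts - target) == min(abs(counts - target)))[1L]
  cl <- .cutAt(dend, cand[best])
  attr(cl, "threshold") <- cand[best]
  attr(cl, "strategy") <- "true_count"
  cl
}

#' Reconstruct lineages from an observed-cell table
#'
#' End-to-end inference: drops empty-set cells, clusters the remainder by
#' Jaccard single linkage, and cuts under the requested threshold strategy.
#' Cells carrying identical observed sets are collapsed to one node before
#' the quadratic distance/dendrogram step and re-expanded afterwards — an
#' exact shortcut, since identical sets sit at dissimilarity 0 and therefore
#' always co-cluster at the thresholds used (all >= 0), and the flat-cluster
#' count is unchanged by the collapse.
#'
#' @param table an [ObservedCellTable-class].
#' @param strategy \code{"any_overlap"}, \code{"min_d"} or
#'   \code{"true_count"}.
#' @param truthCount true lineage count; required for \code{"true_count"}.
#' @return a [LineageAssignment-class]; empty-set cells get \code{NA}
#'   cluster ids.
#' @examples
#' set.seed(1)
#' cohort <- integrateUniform(100, barcodePool(1e4), moi = 0.5)
#' traj <- propagate(cohort, generations = 5, snapshotGenerations = c(0, 5))
#' obs <- applyDropout(traj, 0.1)
#' inferLineages(obs, "any_overlap")
#' @export
inferLineages <- function(table,
                          strategy = c("any_overlap", "min_d", "true_count"),
                          truthCount = NULL) {
  stopifnot(is(table, "ObservedCellTable"))
  strategy <- match.arg(strategy)
  if (strategy == "true_count" && is.null(truthCount))
    stop("strategy 'true_count' requires truthCount")
  keep <- which(lengths(table@sets) > 0L)
  if (length(keep) == 0L) stop("no labeled cells: every observed set is empty")
  ord <- keep[order(table@generation[keep], table@cellId[keep])]
  sets <- table@sets[ord]

  key <- vapply(sets, paste, "", collapse = ";")
  uniq <- match(key, unique(key))          # cell -> unique-set index
  uSets <- sets[!duplicated(key)]
  nu <- length(uSets)

  if (nu == 1L) {
    uCl <- 1L
    thr <- switch(strategy, any_overlap = 1 - 1e-9, min_d = 0,
                  true_count = 0)
  } else {
    dend <- singleLinkageDendrogram(.jaccardMatrix(uSets))
    uCl <- switch(strategy,
                  any_overlap = cutAnyOverlap(dend),
                  min_d = cutMin(dend),
                  true_count = cutByTargetCount(dend, truthCount))
    thr <- attr(uCl, "threshold")
  }

  cluster <- rep(NA_integer_, nCells(table))
  cluster[ord] <- as.integer(uCl)[uniq]
  new("LineageAssignment", cellId = table@cellId,
      generation = table@generation, cluster = cluster,
      strategy = strategy, threshold = as.numeric(thr),
      nExcluded = nCells(table) - length(keep))
}
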