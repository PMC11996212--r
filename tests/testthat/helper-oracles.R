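# Independently coded oracles used against the package's implementations.
# Kept deliberately naive: correctness by inspection, not speed.

# connected components of the set-overlap graph (edges: shared barcode),
# by iterative union-find
overlapComponentsOracle <- function(sets) {
  n <- length(sets)
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      if (length(intersect(sets[[i]], sets[[j]])) > 0L) {
        ri <- findRoot(i); rj <- findRoot(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), findRoot, integer(1))
  match(roots, unique(roots))
}

# components of the graph with edges d[i,j] <= height
distanceComponentsOracle <- function(d, height) {
  n <- nrow(d)
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      if (d[i, j] <= height) {
        ri <- findRoot(i); rj <- findRoot(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), findRoot, integer(1))
  match(roots, unique(roots))
}

# TRUE iff two label vectors describe the same partition of 1..n
samePartition <- function(a, b) {
  stopifnot(length(a) == length(b))
  identical(match(a, unique(a)), match(b, unique(b)))
}

# Fowlkes-Mallows by explicit pair counting over the co-membership matrices
fmBrute <- function(a, b) {
  up <- upper.tri(matrix(0, length(a), length(a)))
  coA <- outer(a, a, "==")[up]
  coB <- outer(b, b, "==")[up]
  tp <- sum(coA & coB)
  pa <- sum(coA)
  pb <- sum(coB)
  if (pa == 0 && pb == 0) return(1)
  tp / sqrt(pa * pb)
}

# V-measure from first principles on the joint label distribution
vBrute <- function(truth, pred) {
  n <- length(truth)
  pt <- table(truth) / n
  pp <- table(pred) / n
  hT <- -sum(ifelse(pt > 0, pt * log(pt), 0))
  hP <- -sum(ifelse(pp > 0, pp * log(pp), 0))
  joint <- table(truth, pred) / n
  hTgP <- 0
  for (j in colnames(joint)) {
    pj <- sum(joint[, j])
    if (pj > 0) {
      cond <- joint[, j] / pj
      hTgP <- hTgP + pj * -sum(ifelse(cond > 0, cond * log(cond), 0))
    }
  }
  hPgT <- 0
  for (i in rownames(joint)) {
    pi <- sum(joint[i, ])
    if (pi > 0) {
      cond <- joint[i, ] / pi
      hPgT <- hPgT + pi * -sum(ifelse(cond > 0, cond * log(cond), 0))
    }
  }
  h <- if (hT == 0) 1 else 1 - hTgP / hT
  c <- if (hP == 0) 1 else 1 - hPgT / hP
  if (h + c == 0) 0 else 2 * h * c / (h + c)
}

# probability two cells with the same L integrated barcodes read identically
# (and not both empty), by exhaustive enumeration of all 4^L joint dropout
# patterns
identicalReadEnumeration <- function(pDrop, L) {
  if (L == 0L) return(0)
  outcomeProb <- c(`11` = (1 - pDrop)^2, `10` = (1 - pDrop) * pDrop,
                   `01` = pDrop * (1 - pDrop), `00` = pDrop^2)
  total <- 0
  for (pattern in seq_len(4^L) - 1L) {
    digits <- (pattern %/% 4^(seq_len(L) - 1L)) %% 4L  # 0..3 per barcode
    keys <- c("11", "10", "01", "00")[digits + 1L]
    set1 <- which(substr(keys, 1, 1) == "1")
    set2 <- which(substr(keys, 2, 2) == "1")
    if (length(set1) > 0L && identical(set1, set2))
      total <- total + prod(outcomeProb[keys])
  }
  total
}

# random observed-cell table fixture: n cells, sets drawn from 0..B-1
randomSetsTable <- function(n, B, meanSize = 2, emptyFraction = 0) {
  sizes <- pmin(B, stats::rpois(n, meanSize - 1) + 1L)
  sizes[stats::runif(n) < emptyFraction] <- 0L
  sets <- lapply(sizes, function(k)
    if (k == 0L) integer(0) else sort.int(sample.int(B, k)) - 1L)
  new("ObservedCellTable", cellId = seq_len(n),
      generation = rep(0L, n), sets = sets,
      founderId = rep(NA_integer_, n))
}

# table built directly from a list of sets (one snapshot, cells 1..n)
tableFromSets <- function(sets, founder = rep(NA_integer_, length(sets))) {
  new("ObservedCellTable", cellId = seq_along(sets),
      generation = rep(0L, length(sets)), sets = lapply(sets, as.integer),
      founderId = as.integer(founder))
}

# assignment built directly from cluster labels over one snapshot
assignmentFromLabels <- function(labels, strategy = "any_overlap") {
  new("LineageAssignment", cellId = seq_along(labels),
      generation = rep(0L, length(labels)), cluster = as.integer(labels),
      strategy = strategy, threshold = 0.5,
      nExcluded = 0L)
}
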