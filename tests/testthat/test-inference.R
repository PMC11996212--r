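test_that("Jaccard dissimilarity follows the set formula", {
  expect_equal(jaccardDissimilarity(7, 7), 0)
  expect_equal(jaccardDissimilarity(c(1, 2), c(3, 4)), 1)
  expect_equal(jaccardDissimilarity(c(1, 2), c(2, 3)), 2 / 3)
  expect_error(jaccardDissimilarity(integer(0), integer(0)), "empty")
})

test_that("distance matrix equals brute-force pairwise evaluation", {
  # degenerate and tiny hand cases
  one <- tableFromSets(list(5L))
  expect_equal(unname(buildDistanceMatrix(one)), matrix(0, 1, 1),
               ignore_attr = TRUE)
  d3 <- buildDistanceMatrix(tableFromSets(list(1L, 1L, 2L)))
  expect_equal(d3[upper.tri(d3)], c(0, 1, 1))

  # random sets: exact equality with a double loop over jaccardDissimilarity
  set.seed(5)
  tab <- randomSetsTable(50, 30, meanSize = 3)
  d <- buildDistanceMatrix(tab)
  sets <- barcodeSets(tab)
  for (i in 1:49) for (j in (i + 1):50)
    expect_identical(d[i, j], jaccardDissimilarity(sets[[i]], sets[[j]]))

  # cross-check against vegan's binary Jaccard on the incidence matrix
  inc <- t(vapply(sets, function(s) as.integer(0:29 %in% s), integer(30)))
  dv <- as.matrix(vegan::vegdist(inc, method = "jaccard", binary = TRUE))
  expect_equal(unname(d), unname(dv), tolerance = 1e-12, ignore_attr = TRUE)

  # empty-set cells are excluded and counted
  set.seed(6)
  tabE <- randomSetsTable(40, 20, emptyFraction = 0.3)
  dE <- buildDistanceMatrix(tabE)
  expect_equal(nrow(dE) + attr(dE, "nExcluded"), 40L)
  allEmpty <- tableFromSets(list(integer(0), integer(0)))
  expect_error(buildDistanceMatrix(allEmpty), "labeled")
})

test_that("single-linkage flat clusters are overlap-graph components", {
  # all pairwise distances 1: every merge at height 1
  dend1 <- singleLinkageDendrogram(buildDistanceMatrix(
    tableFromSets(list(1L, 2L, 3L))))
  expect_true(all(dend1$height == 1))

  # chain distances 0.1, 0.2: merge heights in order
  m <- matrix(c(0, 0.1, 0.9, 0.1, 0, 0.2, 0.9, 0.2, 0), 3, 3)
  expect_equal(singleLinkageDendrogram(m)$height, c(0.1, 0.2))

  # random instances: flat clusters at any height equal the connected
  # components of the graph with edges d <= height
  set.seed(7)
  for (rep in 1:10) {
    tab <- randomSetsTable(30, 12, meanSize = 2)
    d <- buildDistanceMatrix(tab)
    dend <- singleLinkageDendrogram(d)
    for (h in c(0, 0.3, 0.6, 1 - 1e-9)) {
      cl <- stats::cutree(dend, h = h)
      expect_true(samePartition(cl, distanceComponentsOracle(d, h)))
    }
  }
})

test_that("threshold cuts realise the three lineage-building strategies", {
  dendOf <- function(sets)
    singleLinkageDendrogram(buildDistanceMatrix(tableFromSets(sets)))

  # any-overlap: transitive closure of barcode sharing
  cl <- cutAnyOverlap(dendOf(list(1L, c(1L, 2L), 3L)))
  expect_true(samePartition(cl, c(1, 1, 2)))
  cl <- cutAnyOverlap(dendOf(list(1L, 2L, 3L)))
  expect_true(samePartition(cl, 1:3))
  cl <- cutAnyOverlap(dendOf(list(1L, c(1L, 2L), c(2L, 3L))))
  expect_true(samePartition(cl, c(1, 1, 1)))

  # min-d: identical observed sets merge, nothing else
  cl <- cutMin(dendOf(list(1L, 1L, 2L)))
  expect_true(samePartition(cl, c(1, 1, 2)))
  cl <- cutMin(dendOf(list(1L, c(1L, 2L), c(2L, 3L))))
  expect_true(samePartition(cl, 1:3))
  cl <- cutMin(dendOf(list(c(1L, 2L), c(1L, 2L), c(1L, 3L))))
  expect_true(samePartition(cl, c(1, 1, 2)))

  # target-count cut: extremes and an engineered 4-component instance
  sets <- list(1L, 1L, 2L, c(2L, 3L))
  dend <- dendOf(sets)
  expect_equal(attr(cutByTargetCount(dend, 4), "threshold"), 0)
  cl1 <- cutByTargetCount(dend, 1)
  expect_equal(attr(cl1, "threshold"), max(dend$height))

  comp <- lapply(1:4, function(k) {
    base <- (k - 1L) * 10L
    lapply(1:5, function(i) c(base, base + i))   # anchor keeps each block connected
  })
  sets20 <- unlist(comp, recursive = FALSE)
  truthLab <- rep(1:4, each = 5)
  cl4 <- cutByTargetCount(dendOf(sets20), 4)
  expect_true(samePartition(cl4, truthLab))

  expect_error(cutByTargetCount(dend, 0), "positive")
})

test_that("cluster count is non-increasing in the threshold", {
  set.seed(9)
  tab <- randomSetsTable(60, 15, meanSize = 2)
  dend <- singleLinkageDendrogram(buildDistanceMatrix(tab))
  ks <- vapply(seq(0, 1, by = 0.05), function(h)
    length(unique(stats::cutree(dend, h = h))), integer(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("inferLineages matches the uncollapsed cell-level route", {
  # the duplicate-set collapse inside inferLineages must be invisible:
  # clustering the full cell-level matrix gives the same partition
  set.seed(10)
  for (rep in 1:8) {
    tab <- randomSetsTable(40, 8, meanSize = 2, emptyFraction = 0.2)
    if (sum(lengths(barcodeSets(tab)) > 0L) < 3) next
    d <- buildDistanceMatrix(tab)
    dend <- singleLinkageDendrogram(d)
    for (strat in c("any_overlap", "min_d")) {
      full <- if (strat == "any_overlap") cutAnyOverlap(dend) else cutMin(dend)
      got <- clusterIds(inferLineages(tab, strat))
      got <- got[!is.na(got)]
      expect_true(samePartition(got, as.integer(full)))
    }
    nLab <- sum(lengths(barcodeSets(tab)) > 0L)
    fullT <- cutByTargetCount(dend, max(1L, nLab %/% 2L))
    gotT <- clusterIds(inferLineages(tab, "true_count",
                                     truthCount = max(1L, nLab %/% 2L)))
    expect_true(samePartition(gotT[!is.na(gotT)], as.integer(fullT)))
  }
})

test_that("inferLineages validates inputs and records exclusions", {
  expect_error(inferLineages(tableFromSets(list(integer(0))), "min_d"),
               "labeled")
  tab <- tableFromSets(list(1L, 2L, integer(0)))
  expect_error(inferLineages(tab, "true_count"), "truthCount")
  a <- inferLineages(tab, "min_d")
  expect_equal(a@nExcluded, 1L)
  expect_true(is.na(clusterIds(a)[3]))
  expect_equal(a@threshold, 0)
  b <- inferLineages(tab, "any_overlap")
  expect_equal(b@strategy, "any_overlap")
  expect_lt(b@threshold, 1)
})

test_that("threshold strategies coincide at low MOI and high complexity", {
  # at MOI 0.25 and B/S = 100 the dissimilarities are essentially binary,
  # so the three strategies give near-identical partitions
  set.seed(12)
  agree <- replicate(20, {
    sim <- simulateExperiment(S = 200, B = 2e4, moi = 0.25, pDrop = 0.1,
                              strategy = "any_overlap", generations = 5,
                              propagationSnapshots = c(0, 5))
    tab <- sim$table
    ids <- function(s, tc = NULL) {
      cl <- clusterIds(inferLineages(tab, s, truthCount = tc))
      cl[!is.na(cl)]
    }
    nLineagesInData <- length(unique(
      founderIds(tab)[lengths(barcodeSets(tab)) > 0L]))
    a <- ids("any_overlap"); m <- ids("min_d")
    t <- ids("true_count", tc = nLineagesInData)
    min(fowlkesMallows(a, m), fowlkesMallows(a, t), fowlkesMallows(m, t))
  })
  expect_gte(mean(agree), 0.95)
})
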