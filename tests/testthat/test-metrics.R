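test_that("MOI estimation inverts the Poisson labeled fraction", {
  expect_equal(labeledFractionTheory(0), 0)
  expect_equal(labeledFractionTheory(1), 1 - exp(-1))
  expect_error(labeledFractionTheory(-0.1), "nonnegative")
  expect_equal(estimateMoi(0), 0)
  expect_error(estimateMoi(1), "infinite")
  expect_error(estimateMoi(-0.1), "nonnegative")

  # identity on a grid of MOI values
  M <- seq(0, 5, by = 0.25)
  expect_equal(estimateMoi(labeledFractionTheory(M)), M, tolerance = 1e-12)

  # back-calculation from published labeled fractions (two-decimal rounding)
  expect_equal(round(estimateMoi(0.0700), 2), 0.07)
  expect_equal(round(estimateMoi(0.1218), 2), 0.13)
  expect_equal(round(estimateMoi(0.2035), 2), 0.23)
  expect_equal(labeledFractionTheory(0.13), 0.1219, tolerance = 1e-4)
})

test_that("true propagated lineages are the labeled founders with descendants", {
  # all founders unlabeled: zero lineages
  empty <- new("CellCohort", founderId = 1:3,
               barcodeSets = rep(list(integer(0)), 3), poolComplexity = 5L)
  trE <- propagate(empty, generations = 2, snapshotGenerations = c(0, 2))
  tabE <- applyDropout(trE, 0)
  expect_equal(truePropagatedLineages(trE, tabE)$nLineages, 0L)

  # no passaging losses, pDrop = 0: lineage count = labeled founder count
  set.seed(2)
  co <- integrateUniform(40, barcodePool(1e3), moi = 1)
  tr <- propagate(co, generations = 3, snapshotGenerations = c(0, 3),
                  passagingPeriod = 4)
  tab <- applyDropout(tr, 0)
  truth <- truePropagatedLineages(tr, tab)
  expect_equal(truth$nLineages, sum(lengths(barcodeSets(co)) > 0L))

  # labeled founder count ~ Binomial(S, 1 - e^-M)
  set.seed(3)
  S <- 100; M <- 1
  lab <- replicate(200, sum(lengths(barcodeSets(
    integrateUniform(S, barcodePool(1e4), moi = M))) > 0L))
  p <- labeledFractionTheory(M)
  expect_lt(abs(mean(lab) - S * p), 3 * sqrt(S * p * (1 - p) / 200))

  # founders losing every barcode to dropout stay in the denominator with
  # empty blocks
  one <- new("CellCohort", founderId = 1L, barcodeSets = list(0L),
             poolComplexity = 2L)
  tr1 <- propagate(one, generations = 1, snapshotGenerations = 1)
  tab1 <- applyDropout(tr1, 1)
  truth1 <- truePropagatedLineages(tr1, tab1)
  expect_equal(truth1$nLineages, 1L)
  expect_length(truth1$blocks[["1"]], 0L)
})

test_that("accurate-lineage ratio demands exact cluster-block equality", {
  truth <- list(blocks = list(`1` = c("g0:c1", "g0:c2"), `2` = "g0:c3"),
                nLineages = 2L)
  expect_equal(accurateLineageRatio(assignmentFromLabels(c(1, 1, 2)), truth), 1)
  expect_equal(accurateLineageRatio(assignmentFromLabels(c(1, 1, 1)), truth), 0)
  expect_equal(accurateLineageRatio(assignmentFromLabels(c(1, 2, 3)), truth), 0.5)
  # a cluster with extra cells does not match its block
  truth3 <- list(blocks = list(`1` = c("g0:c1", "g0:c2"), `2` = "g0:c3",
                               `3` = "g0:c4"),
                 nLineages = 3L)
  expect_equal(accurateLineageRatio(assignmentFromLabels(c(1, 1, 1, 2)), truth3),
               1 / 3)
})

test_that("Fowlkes-Mallows agrees with explicit pair counting", {
  expect_equal(fowlkesMallows(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  # one block of 4 vs two blocks of 2: TP = 2, TP+FP = 2, TP+FN = 6
  expect_equal(fowlkesMallows(c(1, 1, 2, 2), c(1, 1, 1, 1)), 2 / sqrt(2 * 6))
  expect_equal(fowlkesMallows(1:4, 1:4), 1)   # all-singletons pair
  expect_error(fowlkesMallows(1:4, c(1, 1, 2, 3)), "singletons")

  set.seed(4)
  for (rep in 1:10) {
    n <- sample(20:100, 1)
    a <- sample.int(6, n, replace = TRUE)
    b <- sample.int(6, n, replace = TRUE)
    expect_equal(fowlkesMallows(a, b), fmBrute(a, b), tolerance = 1e-12)
  }

  # independent random partitions score low
  set.seed(5)
  n <- 200
  a <- sample.int(40, n, replace = TRUE)
  b <- sample.int(40, n, replace = TRUE)
  expect_lt(fowlkesMallows(a, b), 0.5)
})

test_that("V-measure agrees with the entropy formulas", {
  expect_equal(vMeasure(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(vMeasure(rep(1, 4), 1:4), 0)   # homogeneity 1, completeness 0
  expect_equal(vMeasure(rep(1, 5), rep(1, 5)), 1)   # degenerate single-single

  # 3-block truth with two blocks merged: hand entropy computation
  truth <- c(1, 1, 2, 2, 3, 3)
  pred <- c(1, 1, 1, 1, 2, 2)
  hT <- -3 * (1 / 3) * log(1 / 3)
  hTgP <- (4 / 6) * (-2 * 0.5 * log(0.5))   # merged cluster splits 2 truths
  h <- 1 - hTgP / hT
  hP <- -(4 / 6) * log(4 / 6) - (2 / 6) * log(2 / 6)
  cm <- 1 - 0 / hP                           # each truth block in one cluster
  expect_equal(vMeasure(truth, pred), 2 * h * cm / (h + cm), tolerance = 1e-12)

  set.seed(6)
  for (rep in 1:10) {
    n <- sample(20:100, 1)
    a <- sample.int(5, n, replace = TRUE)
    b <- sample.int(5, n, replace = TRUE)
    expect_equal(vMeasure(a, b), vBrute(a, b), tolerance = 1e-12)
  }
})

test_that("accuracy report assembles consistent scores", {
  set.seed(7)
  sim <- simulateExperiment(S = 100, B = 1e4, moi = 0.5, pDrop = 0.1,
                            strategy = "any_overlap", generations = 5,
                            propagationSnapshots = c(0, 5))
  rep <- sim$report
  expect_s4_class(rep, "AccuracyReport")
  lst <- as.list(rep)
  expect_true(all(unlist(lst[c("accurate_lineage_ratio", "labeled_fraction",
                               "fm_index", "v_measure")]) >= 0))
  expect_equal(lst$n_true_lineages, sim$truth$nLineages)
  expect_equal(lst$n_clustered_cells + lst$n_excluded_cells,
               nCells(sim$table))
  expect_equal(rep@accuratePerInitialCell,
               lst$n_accurate_lineages / 100)
})
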