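#' Expected labeled fraction under Poisson integration
#'
#' The fraction of infected (labeled) cells at MOI M is 1 - exp(-M): the
#' complement of the Poisson zero class.
#'
#' @param M MOI (nonnegative; vectorised).
#' @return labeled fraction in [0, 1).
#' @export
labeledFractionTheory <- function(M) {
  if (any(M < 0)) stop("M must be nonnegative")
  -expm1(-M)
}

#' Estimate the MOI from a measured labeled fraction
#'
#' Inverts the Poisson labeled-fraction relation: M = -log(1 - f). This is
#' the standard back-calculation used to report MOI from the percentage of
#' barcode-positive cells.
#'
#' @param f labeled fraction in [0, 1) (vectorised).
#' @return MOI estimate.
#' @examples
#' estimateMoi(0.1218)   # about 0.13
#' @export
estimateMoi <- function(f) {
  if (any(f < 0)) stop("labeled fraction must be nonnegative")
  if (any(f >= 1)) stop("labeled fraction of 1 implies infinite MOI")
  -log1p(-f)
}

#' Ground-truth partition of the propagated lineages
#'
#' A true propagated lineage is a founder with a non-empty integrated set
#' and at least one live descendant in at least one recorded snapshot after
#' generation 0 — it must actually have propagated. (For a degenerate
#' trajectory that records nothing beyond generation 0, the initial
#' snapshot is the population and its labeled founders count.) A lineage's
#' block contains the founder's observed cells, across all analysed
#' snapshots including generation 0, that still carry a non-empty
#' post-dropout set; founders whose every observation lost all barcodes
#' keep an empty block — they remain true propagated lineages that no
#' clustering can recover, which is how high dropout depresses the
#' accuracy ratio.
#'
#' @param trajectory the [Trajectory-class] the observations came from.
#' @param table the [ObservedCellTable-class] produced by [applyDropout()].
#' @return list with elements \code{blocks} (named list: founder id ->
#'   character vector of \code{"g<gen>:c<id>"} cell keys) and
#'   \code{nLineages} (number of true propagated lineages).
#' @export
truePropagatedLineages <- function(trajectory, table) {
  stopifnot(is(trajectory, "Trajectory"), is(table, "ObservedCellTable"))
  labeledFounders <- names(trajectory@founderSets)[
    lengths(trajectory@founderSets) > 0L]
  gens <- as.integer(names(trajectory@snapshots))
  propagated <- if (any(gens > 0L)) trajectory@snapshots[gens > 0L]
                else trajectory@snapshots
  present <- unique(unlist(lapply(propagated, function(s) s$founder_id),
                           use.names = FALSE))
  lineages <- intersect(labeledFounders, as.character(present))
  keep <- which(lengths(table@sets) > 0L &
                as.character(table@founderId) %in% lineages)
  keys <- .cellKeys(table@generation[keep], table@cellId[keep])
  blocks <- split(keys, as.character(table@founderId[keep]))
  empty <- setdiff(lineages, names(blocks))
  blocks[empty] <- list(character(0))
  list(blocks = blocks[order(as.integer(names(blocks)))],
       nLineages = length(lineages))
}

#' Accurately identified lineage ratio
#'
#' The number of truth blocks recovered exactly — some inferred cluster
#' equals the block as a set, with no missing and no extra cells — divided
#' by the number of true propagated lineages.
#'
#' @param assignment a [LineageAssignment-class].
#' @param truth result of [truePropagatedLineages()].
#' @return ratio in [0, 1] (0 when there are no true lineages).
#' @export
accurateLineageRatio <- function(assignment, truth) {
  stopifnot(is(assignment, "LineageAssignment"))
  if (truth$nLineages == 0L) return(0)
  accurateLineageCount(assignment, truth) / truth$nLineages
}

#' Count of exactly recovered lineages
#'
#' @inheritParams accurateLineageRatio
#' @return integer count of truth blocks matched exactly by some cluster.
#' @export
accurateLineageCount <- function(assignment, truth) {
  stopifnot(is(assignment, "LineageAssignment"))
  ok <- !is.na(assignment@cluster)
  keys <- .cellKeys(assignment@generation[ok], assignment@cellId[ok])
  clusterSig <- vapply(split(keys, assignment@cluster[ok]),
                       function(k) paste(sort(k), collapse = "\r"), "")
  blockSig <- vapply(truth$blocks,
                     function(k) paste(sort(k), collapse = "\r"), "")
  sum(blockSig != "" & blockSig %in% clusterSig)
}

.contingency <- function(a, b) {
  stopifnot(length(a) == length(b))
  table(factor(a), factor(b))
}

#' Fowlkes-Mallows index between two partitions
#'
#' Pair-counting agreement: TP / sqrt((TP + FP)(TP + FN)) over all cell
#' pairs, where TP counts pairs co-clustered in both partitions. Equals 1
#' for identical partitions. When one partition has no co-clustered pair at
#' all the index is defined as 1 if both partitions are all-singletons and
#' is an error otherwise.
#'
#' @param labelsA,labelsB vectors of cluster labels over the same cells.
#' @return index in [0, 1].
#' @examples
#' fowlkesMallows(c(1, 1, 1, 1), c(1, 1, 2, 2))  # 2 / sqrt(12)
#' @export
fowlkesMallows <- function(labelsA, labelsB) {
  ct <- .contingency(labelsA, labelsB)
  tp <- sum(choose(ct, 2))
  pa <- sum(choose(rowSums(ct), 2))   # TP + FP
  pb <- sum(choose(colSums(ct), 2))   # TP + FN
  if (pa == 0 && pb == 0) return(1)   # both all-singletons
  if (pa == 0 || pb == 0)
    stop("Fowlkes-Mallows undefined: one partition is all-singletons, the other is not degenerate-free")
  tp / sqrt(pa * pb)
}

.entropyFromCounts <- function(n) {
  n <- n[n > 0]
  p <- n / sum(n)
  -sum(p * log(p))
}

#' V-measure between a truth partition and a clustering
#'
#' Harmonic mean (beta = 1) of homogeneity (each cluster holds cells of one
#' true lineage) and completeness (each true lineage lands in one cluster),
#' both computed from the contingency-table conditional entropies. A
#' partition pair with zero class entropy (single class and single cluster)
#' scores 1.
#'
#' @param truthLabels true lineage label per cell.
#' @param clusterLabels inferred cluster label per cell.
#' @return index in [0, 1].
#' @export
vMeasure <- function(truthLabels, clusterLabels) {
  ct <- .contingency(truthLabels, clusterLabels)
  n <- sum(ct)
  hC <- .entropyFromCounts(rowSums(ct))      # truth classes
  hK <- .entropyFromCounts(colSums(ct))      # clusters
  ## H(C|K): sum over clusters of their class entropy, weighted
  hCgK <- sum(apply(ct, 2, function(col)
    if (sum(col) == 0) 0 else sum(col) / n * .entropyFromCounts(col)))
  hKgC <- sum(apply(ct, 1, function(row)
    if (sum(row) == 0) 0 else sum(row) / n * .entropyFromCounts(row)))
  homogeneity <- if (hC == 0) 1 else 1 - hCgK / hC
  completeness <- if (hK == 0) 1 else 1 - hKgC / hK
  if (homogeneity + completeness == 0) return(0)
  2 * homogeneity * completeness / (homogeneity + completeness)
}

#' Score an inferred assignment against ground truth
#'
#' Assembles the full accuracy report for one simulated experiment: the
#' accurate-lineage ratio and its per-initial-cell version, the empirical
#' labeled fraction, and the two cell-level clustering scores evaluated on
#' the clustered (non-empty-set) cells with founder ids as the true labels.
#'
#' @param assignment a [LineageAssignment-class].
#' @param truth result of [truePropagatedLineages()].
#' @param table the [ObservedCellTable-class] that was clustered.
#' @param initialCells the number S of initially prepared cells (default:
#'   cells in the generation-0 snapshot of \code{table}).
#' @return an [AccuracyReport-class].
#' @export
accuracyReport <- function(assignment, truth, table, initialCells = NULL) {
  stopifnot(is(assignment, "LineageAssignment"),
            is(table, "ObservedCellTable"))
  if (is.null(initialCells)) {
    g0 <- table@generation == min(table@generation)
    initialCells <- sum(g0)
  }
  nAcc <- accurateLineageCount(assignment, truth)
  ok <- !is.na(assignment@cluster) & !is.na(table@founderId)
  fm <- vm <- NA_real_
  if (any(ok)) {
    ## one partition all-singletons while the other is not: TP = 0, so the
    ## pair-counting index takes its limiting value 0 here rather than the
    ## strict undefined-value error of fowlkesMallows()
    fm <- tryCatch(fowlkesMallows(table@founderId[ok], assignment@cluster[ok]),
                   error = function(e) 0)
    vm <- vMeasure(table@founderId[ok], assignment@cluster[ok])
  }
  new("AccuracyReport",
      accurateLineageRatio = if (truth$nLineages > 0) nAcc / truth$nLineages else 0,
      accuratePerInitialCell = nAcc / initialCells,
      labeledFraction = mean(lengths(table@sets) > 0L),
      fmIndex = fm, vMeasure = vm,
      counts = list(n_true_lineages = truth$nLineages,
                    n_accurate_lineages = nAcc,
                    n_inferred_clusters =
                      length(unique(assignment@cluster[!is.na(assignment@cluster)])),
                    n_clustered_cells = sum(!is.na(assignment@cluster)),
                    n_excluded_cells = assignment@nExcluded,
                    n_initial_cells = as.integer(initialCells)))
}
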