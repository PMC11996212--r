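#' @import methods
NULL

#' Barcode library pool
#'
#' A pool of \code{complexity} distinct barcode types together with their
#' relative abundances in the vector library. Barcode types are abstract
#' 0-based integer ids \code{0 .. B-1}; sequence content is out of scope.
#' An empty \code{weights} slot denotes the exactly uniform pool (all
#' \code{1/B}), which avoids materialising a length-\code{B} vector for
#' libraries of complexity up to 10^6 and beyond.
#'
#' @slot complexity integer, number of distinct barcode types (B >= 1).
#' @slot weights numeric, per-type relative abundances summing to 1, or
#'   \code{numeric(0)} for the uniform pool.
#' @seealso [barcodePool()]
#' @export
setClass("BarcodePool",
  representation(complexity = "integer", weights = "numeric"))

setValidity("BarcodePool", function(object) {
  B <- object@complexity
  w <- object@weights
  if (length(B) != 1L || is.na(B) || B < 1L)
    return("complexity must be a single integer >= 1")
  if (length(w) > 0L) {
    if (length(w) != B)
      return("weights must have length == complexity (or length 0 for uniform)")
    if (any(w < 0)) return("weights must be nonnegative")
    if (abs(sum(w) - 1) > 1e-12) return("weights must sum to 1 within 1e-12")
  }
  TRUE
})

#' Cohort of founder cells
#'
#' The outcome of a barcode-integration step: \code{S} founder cells, each
#' carrying a (possibly empty) integrated set of barcode-type ids. Cells with
#' empty sets are retained — they are the unlabeled fraction, whose size the
#' Poisson model predicts as \code{exp(-M)}.
#'
#' @slot founderId integer vector of unique founder (lineage) ids.
#' @slot barcodeSets list of sorted 0-based integer vectors, one per founder;
#'   each a subset of \code{0 .. poolComplexity-1}.
#' @slot poolComplexity integer, complexity B of the pool the sets were drawn
#'   from.
#' @export
setClass("CellCohort",
  representation(founderId = "integer", barcodeSets = "list",
                 poolComplexity = "integer"))

setValidity("CellCohort", function(object) {
  if (length(object@founderId) != length(object@barcodeSets))
    return("founderId and barcodeSets must have equal length")
  if (anyDuplicated(object@founderId))
    return("founder ids must be unique within a cohort")
  B <- object@poolComplexity
  bad <- vapply(object@barcodeSets, function(s)
    length(s) > 0L && (min(s) < 0L || max(s) >= B), logical(1))
  if (any(bad)) return("barcode ids must lie in [0, poolComplexity)")
  TRUE
})

#' Propagated population trajectory
#'
#' Time-indexed snapshots of a neutrally propagated barcoded population.
#' Each snapshot is a nondestructive full read of the population at one of
#' the configured generations; cells inherit their founder's integrated
#' barcode set, recorded once in \code{founderSets}.
#'
#' @slot snapshots named list (names = generation) of data.frames with
#'   columns \code{cell_id}, \code{founder_id}.
#' @slot founderSets named list mapping founder id (as character) to the
#'   founder's integrated barcode set.
#' @slot generations integer, total number of generations propagated.
#' @slot params list echoing the propagation configuration.
#' @export
setClass("Trajectory",
  representation(snapshots = "list", founderSets = "list",
                 generations = "integer", params = "list"))

setValidity("Trajectory", function(object) {
  for (snap in object@snapshots) {
    if (!all(c("cell_id", "founder_id") %in% names(snap)))
      return("each snapshot needs cell_id and founder_id columns")
    if (!all(as.character(snap$founder_id) %in% names(object@founderSets)))
      return("every founder_id in a snapshot must exist in founderSets")
  }
  TRUE
})

#' Post-dropout observations across snapshots
#'
#' The aggregated (cell, snapshot, observed barcode set) records the lineage
#' inference consumes: every cell of every configured snapshot, with its
#' integrated set thinned by the dropout process. Cells whose whole set
#' dropped out (and never-labeled cells) carry an empty set and are excluded
#' from clustering downstream but kept here, so labeled-fraction accounting
#' remains possible.
#'
#' @slot cellId integer, cell id within its snapshot.
#' @slot generation integer, snapshot generation of each record.
#' @slot sets list of sorted 0-based integer vectors (possibly empty).
#' @slot founderId integer, ground-truth founder id (NA when the table was
#'   read from an external barcode-call export with no truth available).
#' @export
setClass("ObservedCellTable",
  representation(cellId = "integer", generation = "integer",
                 sets = "list", founderId = "integer"))

setValidity("ObservedCellTable", function(object) {
  n <- length(object@cellId)
  if (length(object@generation) != n || length(object@sets) != n ||
      length(object@founderId) != n)
    return("cellId, generation, sets and founderId must have equal length")
  if (anyDuplicated(paste(object@generation, object@cellId)))
    return("(generation, cell_id) pairs must be unique")
  TRUE
})

#' Inferred lineage assignment
#'
#' Cluster membership per observed cell under one of the three threshold
#' strategies (\code{any_overlap} = D just below 1, \code{min_d} = D of 0,
#' \code{true_count} = D chosen to match a known lineage count). Cells with
#' empty observed sets have \code{NA} cluster ids and are counted in
#' \code{nExcluded}.
#'
#' @slot cellId,generation integers identifying each observed cell.
#' @slot cluster integer cluster id (NA for unassigned empty-set cells).
#' @slot strategy character, one of \code{"any_overlap"}, \code{"min_d"},
#'   \code{"true_count"}.
#' @slot threshold numeric dissimilarity threshold actually used.
#' @slot nExcluded integer, number of empty-set cells excluded.
#' @export
setClass("LineageAssignment",
  representation(cellId = "integer", generation = "integer",
                 cluster = "integer", strategy = "character",
                 threshold = "numeric", nExcluded = "integer"))

setValidity("LineageAssignment", function(object) {
  n <- length(object@cellId)
  if (length(object@generation) != n || length(object@cluster) != n)
    return("cellId, generation and cluster must have equal length")
  if (!object@strategy %in% c("any_overlap", "min_d", "true_count"))
    return("unknown strategy tag")
  TRUE
})

#' Lineage-recovery accuracy report
#'
#' Scores an inferred assignment against the ground-truth founder partition:
#' the accurate-lineage ratio (fraction of true propagated lineages recovered
#' as an exactly matching cluster), the same count scaled per initial cell,
#' the empirical labeled fraction, and the two cell-level clustering scores
#' (Fowlkes-Mallows index, V-measure).
#'
#' @slot accurateLineageRatio,accuratePerInitialCell,labeledFraction,fmIndex,vMeasure numeric scores in [0, 1].
#' @slot counts list: true lineages, accurately recovered lineages, inferred
#'   clusters, clustered cells, excluded empty-set cells, initial cells.
#' @export
setClass("AccuracyReport",
  representation(accurateLineageRatio = "numeric",
                 accuratePerInitialCell = "numeric",
                 labeledFraction = "numeric",
                 fmIndex = "numeric", vMeasure = "numeric",
                 counts = "list"))

setValidity("AccuracyReport", function(object) {
  r <- c(object@accurateLineageRatio, object@labeledFraction,
         object@fmIndex, object@vMeasure)
  r <- r[!is.na(r)]
  if (any(r < -1e-12 | r > 1 + 1e-12)) return("ratios must lie in [0, 1]")
  TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "BarcodePool", function(object) {
  kind <- if (length(object@weights) == 0L) "uniform" else "weighted"
  cat("BarcodePool:", object@complexity, "barcode types (", kind, ")\n")
})

setMethod("show", "CellCohort", function(object) {
  L <- lengths(object@barcodeSets)
  cat("CellCohort:", length(object@founderId), "founder cells,",
      sum(L > 0L), "labeled; pool complexity", object@poolComplexity, "\n")
  cat("  mean barcodes/cell:", format(mean(L), digits = 4), "\n")
})

setMethod("show", "Trajectory", function(object) {
  gens <- names(object@snapshots)
  cat("Trajectory:", object@generations, "generations; snapshots at",
      paste(gens, collapse = ", "), "\n")
  sizes <- vapply(object@snapshots, nrow, integer(1))
  cat("  snapshot sizes:", paste(sizes, collapse = ", "), "\n")
})

setMethod("show", "ObservedCellTable", function(object) {
  cat("ObservedCellTable:", length(object@cellId), "observations over",
      length(unique(object@generation)), "snapshot(s);",
      sum(lengths(object@sets) > 0L), "with non-empty barcode sets\n")
})

setMethod("show", "LineageAssignment", function(object) {
  k <- length(unique(object@cluster[!is.na(object@cluster)]))
  cat("LineageAssignment:", k, "clusters over",
      sum(!is.na(object@cluster)), "cells (strategy", object@strategy,
      ", threshold", format(object@threshold, digits = 4), ");",
      object@nExcluded, "empty-set cells unassigned\n")
})

setMethod("show", "AccuracyReport", function(object) {
  cat("AccuracyReport\n")
  cat("  accurate-lineage ratio :", format(object@accurateLineageRatio, digits = 4), "\n")
  cat("  accurate / initial cell:", format(object@accuratePerInitialCell, digits = 4), "\n")
  cat("  labeled fraction       :", format(object@labeledFraction, digits = 4), "\n")
  cat("  Fowlkes-Mallows index  :", format(object@fmIndex, digits = 4), "\n")
  cat("  V-measure              :", format(object@vMeasure, digits = 4), "\n")
})
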