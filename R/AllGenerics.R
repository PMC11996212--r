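#' Accessors for BarcodeTrace objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x a BarcodeTrace S4 object.
#' @param ... unused.
#' @return The requested component: counts as integers, sets as lists of
#'   0-based integer vectors, ids as integer vectors.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nCells", function(x, ...) standardGeneric("nCells"))

#' @rdname accessors
#' @export
setGeneric("barcodeSets", function(x, ...) standardGeneric("barcodeSets"))

#' @rdname accessors
#' @export
setGeneric("founderIds", function(x, ...) standardGeneric("founderIds"))

#' @rdname accessors
#' @export
setGeneric("poolComplexity", function(x, ...) standardGeneric("poolComplexity"))

#' @rdname accessors
#' @export
setGeneric("poolWeights", function(x, ...) standardGeneric("poolWeights"))

#' @rdname accessors
#' @export
setGeneric("snapshotGenerations", function(x, ...) standardGeneric("snapshotGenerations"))

#' @rdname accessors
#' @param generation which snapshot to extract.
#' @export
setGeneric("snapshot", function(x, generation, ...) standardGeneric("snapshot"))

#' @rdname accessors
#' @export
setGeneric("clusterIds", function(x, ...) standardGeneric("clusterIds"))

#' @rdname accessors
#' @export
setMethod("nCells", "CellCohort", function(x) length(x@founderId))

#' @rdname accessors
#' @export
setMethod("nCells", "ObservedCellTable", function(x) length(x@cellId))

#' @rdname accessors
#' @export
setMethod("barcodeSets", "CellCohort", function(x) x@barcodeSets)

#' @rdname accessors
#' @export
setMethod("barcodeSets", "ObservedCellTable", function(x) x@sets)

#' @rdname accessors
#' @export
setMethod("founderIds", "CellCohort", function(x) x@founderId)

#' @rdname accessors
#' @export
setMethod("founderIds", "ObservedCellTable", function(x) x@founderId)

#' @rdname accessors
#' @export
setMethod("poolComplexity", "BarcodePool", function(x) x@complexity)

#' @rdname accessors
#' @export
setMethod("poolComplexity", "CellCohort", function(x) x@poolComplexity)

#' @rdname accessors
#' @export
setMethod("poolWeights", "BarcodePool", function(x) {
  if (length(x@weights) == 0L) rep(1 / x@complexity, x@complexity) else x@weights
})

#' @rdname accessors
#' @export
setMethod("snapshotGenerations", "Trajectory", function(x)
  as.integer(names(x@snapshots)))

#' @rdname accessors
#' @export
setMethod("snapshot", "Trajectory", function(x, generation) {
  key <- as.character(generation)
  if (!key %in% names(x@snapshots))
    stop("no snapshot recorded at generation ", generation)
  x@snapshots[[key]]
})

#' @rdname accessors
#' @export
setMethod("clusterIds", "LineageAssignment", function(x) x@cluster)

#' Coerce an ObservedCellTable to a data.frame
#'
#' @param x an [ObservedCellTable-class] object.
#' @param ... unused.
#' @return data.frame with columns \code{cell_id}, \code{generation},
#'   \code{barcodes} (semicolon-joined 0-based ids, \code{""} when empty) and
#'   \code{founder_id}.
#' @export
setMethod("as.data.frame", "ObservedCellTable", function(x, ...) {
  data.frame(cell_id = x@cellId, generation = x@generation,
             barcodes = vapply(x@sets, paste, "", collapse = ";"),
             founder_id = x@founderId, stringsAsFactors = FALSE)
})

#' Coerce a LineageAssignment to a data.frame
#'
#' @param x a [LineageAssignment-class] object.
#' @param ... unused.
#' @return data.frame with columns \code{cell_id}, \code{generation},
#'   \code{cluster_id}, \code{strategy}, \code{threshold}.
#' @export
setMethod("as.data.frame", "LineageAssignment", function(x, ...) {
  data.frame(cell_id = x@cellId, generation = x@generation,
             cluster_id = x@cluster, strategy = x@strategy,
             threshold = x@threshold, stringsAsFactors = FALSE)
})

#' Coerce an AccuracyReport to a flat list
#'
#' Suitable for JSON serialisation of one replicate's scores.
#'
#' @param x an [AccuracyReport-class] object.
#' @param ... unused.
#' @export
setMethod("as.list", "AccuracyReport", function(x, ...) {
  c(list(accurate_lineage_ratio = x@accurateLineageRatio,
         accurate_per_initial_cell = x@accuratePerInitialCell,
         labeled_fraction = x@labeledFraction,
         fm_index = x@fmIndex, v_measure = x@vMeasure),
    x@counts)
})
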