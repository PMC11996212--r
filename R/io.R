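## CSV dialects: barcode sets travel as semicolon-joined 0-based ids, an
## empty field meaning an unlabeled (or fully dropped-out) cell.

.joinSets <- function(sets) vapply(sets, paste, "", collapse = ";")

.parseSets <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(p) {
    p <- p[nzchar(p)]
    if (length(p) == 0L) integer(0) else sort.int(as.integer(p))
  })
}

#' Write a founder cohort to CSV
#'
#' Columns \code{cell_id}, \code{founder_id}, \code{barcodes}
#' (semicolon-joined 0-based ids; empty for unlabeled cells).
#'
#' @param cohort a [CellCohort-class].
#' @param path output file.
#' @export
writeCohort <- function(cohort, path) {
  stopifnot(is(cohort, "CellCohort"))
  utils::write.csv(data.frame(cell_id = cohort@founderId,
                              founder_id = cohort@founderId,
                              barcodes = .joinSets(cohort@barcodeSets)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sparse cell-by-barcode incidence matrix
#'
#' Binary sparse matrix with one row per cell and one column per barcode
#' type of the pool (columns named by 0-based type id); suitable for
#' [Matrix::writeMM()] MatrixMarket export.
#'
#' @param cohort a [CellCohort-class].
#' @return a \code{Matrix} sparse matrix of 0/1.
#' @export
cohortMatrix <- function(cohort) {
  stopifnot(is(cohort, "CellCohort"))
  lens <- lengths(cohort@barcodeSets)
  Matrix::sparseMatrix(
    i = rep.int(seq_along(lens), lens),
    j = unlist(cohort@barcodeSets, use.names = FALSE) + 1L,
    x = 1,
    dims = c(length(lens), cohort@poolComplexity),
    dimnames = list(as.character(cohort@founderId),
                    as.character(seq_len(cohort@poolComplexity) - 1L)))
}

#' Write a trajectory to CSV
#'
#' Long format: columns \code{generation}, \code{cell_id},
#' \code{founder_id}, one row per live cell per recorded snapshot.
#'
#' @param trajectory a [Trajectory-class].
#' @param path output file.
#' @export
writeTrajectory <- function(trajectory, path) {
  stopifnot(is(trajectory, "Trajectory"))
  rows <- do.call(rbind, lapply(names(trajectory@snapshots), function(g) {
    s <- trajectory@snapshots[[g]]
    data.frame(generation = as.integer(g), cell_id = s$cell_id,
               founder_id = s$founder_id)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an observed-cell table to CSV
#'
#' The interchange dialect the inference step consumes: columns
#' \code{cell_id}, \code{generation}, \code{barcodes}; with
#' \code{includeTruth = TRUE} a \code{founder_id} column is appended.
#'
#' @param table an [ObservedCellTable-class].
#' @param path output file.
#' @param includeTruth also write the ground-truth founder ids.
#' @export
writeObservedCells <- function(table, path, includeTruth = FALSE) {
  stopifnot(is(table, "ObservedCellTable"))
  df <- data.frame(cell_id = table@cellId, generation = table@generation,
                   barcodes = .joinSets(table@sets))
  if (includeTruth) df$founder_id <- table@founderId
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an observed-cell table from CSV
#'
#' Accepts the dialect of [writeObservedCells()], so externally produced
#' barcode-call exports (cell id, snapshot label, semicolon-joined barcode
#' ids) can be clustered with [inferLineages()]. A missing
#' \code{founder_id} column yields NA truth.
#'
#' @param path CSV file with columns \code{cell_id}, \code{generation},
#'   \code{barcodes} and optionally \code{founder_id}.
#' @return an [ObservedCellTable-class].
#' @export
readObservedCells <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(barcodes = "character"))
  if (!all(c("cell_id", "generation", "barcodes") %in% names(df)))
    stop("expected columns cell_id, generation, barcodes")
  new("ObservedCellTable",
      cellId = as.integer(df$cell_id),
      generation = as.integer(df$generation),
      sets = .parseSets(df$barcodes),
      founderId = if ("founder_id" %in% names(df))
        as.integer(df$founder_id) else rep(NA_integer_, nrow(df)))
}

#' Write a lineage assignment to CSV
#'
#' Columns \code{cell_id}, \code{generation}, \code{cluster_id} (empty for
#' unassigned cells), \code{strategy}, \code{threshold}.
#'
#' @param assignment a [LineageAssignment-class].
#' @param path output file.
#' @export
writeAssignment <- function(assignment, path) {
  stopifnot(is(assignment, "LineageAssignment"))
  utils::write.csv(as.data.frame(assignment), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}
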