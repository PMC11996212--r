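#' Propagate a barcoded cohort through growth and passaging
#'
#' Runs neutral clonal dynamics for \code{generations} rounds, recording
#' nondestructive full-population snapshots at the configured generations.
#' Two engines are available:
#' \describe{
#'   \item{\code{synchronized_doubling}}{every cell produces two daughters
#'     each generation (ids \code{2i}, \code{2i+1}, so trajectories are
#'     bit-reproducible under a seed); at each passaging event the grown
#'     population is uniformly subsampled without replacement back to
#'     \code{targetSize}.}
#'   \item{\code{wright_fisher}}{each generation the next population of
#'     \code{targetSize} cells is drawn by multinomial resampling of
#'     parents.}
#' }
#' Dynamics are neutral: no step ever reads a barcode set, so every cell's
#' set (via its founder) is constant along its lineage. Generation 0 is the
#' initial cohort; the snapshot at generation g reads the population after g
#' complete rounds, when it again holds \code{targetSize} cells under the
#' default passage-every-generation policy.
#'
#' @param cohort a [CellCohort-class] of founder cells.
#' @param generations total generations T (default 15).
#' @param snapshotGenerations sorted generations to record (default
#'   \code{c(0, 5, 10, 15)}, clipped at T).
#' @param passagingPeriod generations between passaging events (default 1 =
#'   passage after every doubling).
#' @param targetSize population size restored at each passage (default: the
#'   cohort size).
#' @param engine \code{"synchronized_doubling"} or \code{"wright_fisher"}.
#' @param snapshotFraction fraction of the population recorded per snapshot
#'   (default 1 = full nondestructive read).
#' @return A [Trajectory-class].
#' @examples
#' set.seed(1)
#' cohort <- integrateUniform(200, barcodePool(1e4), moi = 0.5)
#' traj <- propagate(cohort, generations = 15)
#' length(survivingLineages(traj))   # < 200: passaging loses lineages
#' @export
propagate <- function(cohort, generations = 15L,
                      snapshotGenerations = c(0L, 5L, 10L, 15L),
                      passagingPeriod = 1L, targetSize = NULL,
                      engine = c("synchronized_doubling", "wright_fisher"),
                      snapshotFraction = 1) {
  stopifnot(is(cohort, "CellCohort"))
  if (nCells(cohort) == 0L) stop("cohort must be non-empty")
  engine <- match.arg(engine)
  generations <- as.integer(generations)
  if (is.na(generations) || generations < 0L)
    stop("generations must be a nonnegative integer")
  snapshotGenerations <- sort(unique(as.integer(snapshotGenerations)))
  snapshotGenerations <- snapshotGenerations[snapshotGenerations <= generations &
                                             snapshotGenerations >= 0L]
  if (is.null(targetSize)) targetSize <- nCells(cohort)
  targetSize <- as.integer(targetSize)
  if (is.na(targetSize) || targetSize < 1L) stop("targetSize must be >= 1")
  passagingPeriod <- as.integer(passagingPeriod)
  if (is.na(passagingPeriod) || passagingPeriod < 1L)
    stop("passagingPeriod must be >= 1")
  if (snapshotFraction <= 0 || snapshotFraction > 1)
    stop("snapshotFraction must lie in (0, 1]")

  founderSets <- cohort@barcodeSets
  names(founderSets) <- as.character(cohort@founderId)

  cellId <- cohort@founderId      # initial cell ids = founder ids
  founder <- cohort@founderId
  snaps <- list()
  record <- function(cid, fid) {
    n <- length(cid)
    keep <- if (snapshotFraction < 1)
      sort.int(sample.int(n, max(1L, round(snapshotFraction * n)))) else seq_len(n)
    data.frame(cell_id = cid[keep], founder_id = fid[keep])
  }
  if (0L %in% snapshotGenerations)
    snaps[["0"]] <- record(cellId, founder)

  for (g in seq_len(generations)) {
    if (engine == "synchronized_doubling") {
      n <- length(cellId)
      cellId <- as.integer(rbind(2 * cellId, 2 * cellId + 1L))
      founder <- rep(founder, each = 2L)
      if (g %% passagingPeriod == 0L) {
        keep <- sort.int(sample.int(2L * n, min(targetSize, 2L * n)))
        cellId <- cellId[keep]
        founder <- founder[keep]
      }
    } else {                       # wright_fisher
      parents <- sample.int(length(cellId), targetSize, replace = TRUE)
      founder <- founder[parents]
      cellId <- seq_len(targetSize)
    }
    if (g %in% snapshotGenerations)
      snaps[[as.character(g)]] <- record(cellId, founder)
  }
  new("Trajectory", snapshots = snaps, founderSets = founderSets,
      generations = generations,
      params = list(snapshotGenerations = snapshotGenerations,
                    passagingPeriod = passagingPeriod,
                    targetSize = targetSize, engine = engine,
                    snapshotFraction = snapshotFraction,
                    initialSize = nCells(cohort)))
}

#' Passage a population
#'
#' One passaging event: a uniform subsample without replacement down to
#' \code{targetSize} cells. Lineages absent from the subsample are lost for
#' good — the stochastic bottleneck that prunes lineage diversity over time.
#'
#' @param population data.frame with columns \code{cell_id},
#'   \code{founder_id} (one row per live cell).
#' @param targetSize number of cells retained; must not exceed the
#'   population size.
#' @return The subsampled population, in original row order.
#' @export
passageCells <- function(population, targetSize) {
  stopifnot(is.data.frame(population),
            all(c("cell_id", "founder_id") %in% names(population)))
  n <- nrow(population)
  targetSize <- as.integer(targetSize)
  if (is.na(targetSize) || targetSize < 0L || targetSize > n)
    stop("targetSize must lie in [0, population size]")
  if (targetSize == 0L) {
    warning("passaged to size 0: all lineages lost")
    return(population[integer(0), , drop = FALSE])
  }
  if (targetSize == n) return(population)
  population[sort.int(sample.int(n, targetSize)), , drop = FALSE]
}

#' Lineages surviving propagation
#'
#' Founder ids with at least one live cell in at least one recorded snapshot
#' after generation 0.
#'
#' @param trajectory a [Trajectory-class].
#' @return integer vector of surviving founder ids, sorted.
#' @export
survivingLineages <- function(trajectory) {
  stopifnot(is(trajectory, "Trajectory"))
  gens <- as.integer(names(trajectory@snapshots))
  ids <- unlist(lapply(trajectory@snapshots[gens > 0L],
                       function(s) s$founder_id), use.names = FALSE)
  sort.int(unique(as.integer(ids)))
}
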