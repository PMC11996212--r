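#' Observe a trajectory through barcode dropout
#'
#' Produces the aggregated post-dropout observation table for every recorded
#' snapshot: each integrated barcode of each cell is read independently with
#' probability \code{1 - pDrop}, with fresh noise per cell and per snapshot
#' (reading errors at one time are uncorrelated with those at another).
#' Unlabeled cells and cells whose whole set dropped out are kept with empty
#' sets; the inference step excludes them from clustering.
#'
#' @param trajectory a [Trajectory-class].
#' @param pDrop dropout probability in [0, 1]; typical reported single-cell
#'   RNA-seq values lie between 0.1 and 0.5.
#' @return An [ObservedCellTable-class] covering all snapshots.
#' @examples
#' set.seed(1)
#' cohort <- integrateUniform(100, barcodePool(1000), moi = 1)
#' traj <- propagate(cohort, generations = 5, snapshotGenerations = c(0, 5))
#' obs <- applyDropout(traj, pDrop = 0.2)
#' @export
applyDropout <- function(trajectory, pDrop) {
  stopifnot(is(trajectory, "Trajectory"))
  if (length(pDrop) != 1L || is.na(pDrop) || pDrop < 0 || pDrop > 1)
    stop("pDrop must lie in [0, 1]")
  gens <- as.integer(names(trajectory@snapshots))
  cellId <- integer(0); generation <- integer(0); founderId <- integer(0)
  sets <- list()
  for (k in seq_along(gens)) {
    snap <- trajectory@snapshots[[k]]
    obs <- dropoutSets(trajectory@founderSets[as.character(snap$founder_id)],
                       pDrop)
    cellId <- c(cellId, as.integer(snap$cell_id))
    generation <- c(generation, rep.int(gens[k], nrow(snap)))
    founderId <- c(founderId, as.integer(snap$founder_id))
    sets <- c(sets, obs)
  }
  new("ObservedCellTable", cellId = cellId, generation = generation,
      sets = sets, founderId = founderId)
}

#' Thin barcode sets by dropout
#'
#' Low-level Bernoulli thinning of a list of barcode sets: each element is
#' retained independently with probability \code{1 - pDrop}.
#'
#' @param sets list of integer vectors.
#' @param pDrop dropout probability in [0, 1].
#' @return list of thinned sets, same length and order.
#' @export
dropoutSets <- function(sets, pDrop) {
  if (pDrop < 0 || pDrop > 1) stop("pDrop must lie in [0, 1]")
  if (pDrop == 0) return(unname(sets))
  lens <- lengths(sets)
  n <- length(sets)
  if (sum(lens) == 0L || pDrop == 1) {
    out <- vector("list", n)
    out[] <- list(integer(0))
    return(out)
  }
  all <- unlist(sets, use.names = FALSE)
  keep <- stats::runif(length(all)) >= pDrop
  owner <- rep.int(seq_len(n), lens)
  out <- split(all[keep], factor(owner[keep], levels = seq_len(n)))
  out <- unname(lapply(out, as.integer))
  out
}

#' Observed (post-dropout) set-size pmf
#'
#' Dropout thins the Binomial integration law: the observed set size is
#' Binomial(B, pIn (1 - pDrop)), i.e. the insertion probability is replaced
#' by its dropout-effective value, and the effective MOI is
#' B pIn (1 - pDrop).
#'
#' @param B pool complexity.
#' @param pIn insertion probability.
#' @param pDrop dropout probability.
#' @param L observed set size(s).
#' @return probability (vectorised over \code{L}).
#' @export
observedSetSizePmf <- function(B, pIn, pDrop, L) {
  if (pDrop < 0 || pDrop > 1) stop("pDrop must lie in [0, 1]")
  setSizePmf(B, pIn * (1 - pDrop), L)
}

#' Cells-per-barcode pmf
#'
#' The number of cells in which a given barcode type is observed is
#' Binomial(S, pIn (1 - pDrop)), with mean (S / B) * M_effective — the
#' quantity whose excursions above 1 create barcode sharing across cells.
#'
#' @param S number of cells prepared for integration.
#' @param pIn insertion probability.
#' @param pDrop dropout probability.
#' @param C cell count(s).
#' @return probability (vectorised over \code{C}).
#' @export
cellsPerBarcodePmf <- function(S, pIn, pDrop, C) {
  if (pDrop < 0 || pDrop > 1) stop("pDrop must lie in [0, 1]")
  p <- stats::dbinom(C, size = S, prob = pIn * (1 - pDrop))
  p[C < 0 | C > S] <- 0
  p
}

#' Mean observed barcodes among labeled cells
#'
#' Conditioning the observed-set-size law on the cell being labeled
#' (non-empty observed set) renormalises away the zero class:
#' \deqn{E[L | L > 0] = B q / (1 - (1 - q)^B), \quad q = pIn (1 - pDrop).}
#' In the Poisson limit this is M_eff / (1 - exp(-M_eff)). Call with
#' \code{B} and \code{pIn} for the exact Binomial form, or with \code{moi}
#' alone for the Poisson limit.
#'
#' @param B pool complexity (Binomial form).
#' @param pIn insertion probability (Binomial form).
#' @param pDrop dropout probability (default 0).
#' @param moi effective-exposure shortcut: Poisson-limit mean
#'   \code{moi (1 - pDrop) / (1 - exp(-moi (1 - pDrop)))}.
#' @return expected number of observed barcodes per labeled cell.
#' @examples
#' meanBarcodesInLabeled(moi = 0.43)   # about 1.23
#' @export
meanBarcodesInLabeled <- function(B = NULL, pIn = NULL, pDrop = 0, moi = NULL) {
  if (pDrop < 0 || pDrop > 1) stop("pDrop must lie in [0, 1]")
  if (!is.null(moi)) {
    m <- moi * (1 - pDrop)
    if (m <= 0) stop("effective MOI must be positive for labeled cells to exist")
    return(m / (-expm1(-m)))
  }
  if (is.null(B) || is.null(pIn)) stop("give (B, pIn) or moi")
  q <- pIn * (1 - pDrop)
  if (q <= 0) stop("effective insertion probability must be positive")
  B * q / (1 - (1 - q)^B)
}
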