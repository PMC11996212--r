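#' Probability that a barcode labels at most one cell
#'
#' Under uniform integration the number of cells sharing a given barcode is
#' approximately Poisson with mean (S/B) M, so the probability of no overlap
#' for that barcode is
#' \deqn{P(\mathrm{no\ overlap}) = (1 + (S/B) M)\, e^{-(S/B) M},}
#' an exponentially decaying function of (S/B) M. Evaluated in log space so
#' large exposures do not underflow prematurely.
#'
#' @param S number of cells.
#' @param B pool complexity (> 0).
#' @param M MOI (vectorised).
#' @return probability in (0, 1].
#' @export
pNoOverlap <- function(S, B, M) {
  if (B <= 0) stop("B must be positive")
  if (any(M < 0)) stop("M must be nonnegative")
  x <- (S / B) * M
  exp(log1p(x) - x)
}

#' Probability two equal sets of size L read identically after dropout
#'
#' For two cells carrying the same L integrated barcodes, each barcode is
#' read in both cells (probability (1-p)^2), dropped in both (p^2), or
#' mismatched (2p(1-p)). The sets read identically iff no barcode
#' mismatches, minus the all-dropped-in-both case (two empty reads do not
#' count as an identification):
#' \deqn{(2 p^2 - 2 p + 1)^L - p^{2L}.}
#' At L = 0 this is 0: empty-vs-empty comparisons are excluded by
#' construction.
#'
#' @param pDrop dropout probability.
#' @param L integrated set size (vectorised).
#' @return probability.
#' @export
pIdenticalGivenL <- function(pDrop, L) {
  if (pDrop < 0 || pDrop > 1) stop("pDrop must lie in [0, 1]")
  if (any(L < 0)) stop("L must be nonnegative")
  (2 * pDrop^2 - 2 * pDrop + 1)^L - pDrop^(2 * L)
}

#' Probability of reading two identical non-empty barcode sets
#'
#' Marginalising [pIdenticalGivenL()] over the Poisson set-size law gives
#' the closed form
#' \deqn{e^{-2 p (1-p) M} - e^{-(1 - p^2) M},}
#' which vanishes at M = 0, at pDrop = 1, and as M grows for any
#' pDrop > 0, and is concave in M with an interior maximum — the analytic
#' signature of the minimal-threshold strategy's non-monotone accuracy.
#'
#' @param M MOI (vectorised).
#' @param pDrop dropout probability.
#' @return probability.
#' @export
pIdentical <- function(M, pDrop) {
  if (any(M < 0)) stop("M must be nonnegative")
  if (pDrop < 0 || pDrop > 1) stop("pDrop must lie in [0, 1]")
  exp(-2 * pDrop * (1 - pDrop) * M) - exp(-(1 - pDrop^2) * M)
}

#' Minimal barcode-pool complexity for reliable separation
#'
#' Requiring the probability of any barcode overlap to stay below 1/S gives
#' the design rule B >= S^(3/2) M: the pool complexity that keeps barcode
#' collisions across the whole experiment improbable.
#'
#' @param S number of cells.
#' @param M MOI.
#' @return required complexity S^(3/2) M.
#' @export
minComplexityBound <- function(S, M) {
  if (any(S < 1)) stop("S must be >= 1")
  if (any(M < 0)) stop("M must be nonnegative")
  S^(3 / 2) * M
}

#' MOI maximising the identical-read probability
#'
#' Locates the interior maximiser of [pIdentical()] over M in (0, 50) by
#' bracketed scalar maximisation (tolerance 1e-6). Defined only for
#' dropout strictly between 0 and 1; at the endpoints the curve is monotone
#' or flat and has no interior peak.
#'
#' @param pDrop dropout probability in (0, 1).
#' @return list with \code{moi} (the maximiser) and \code{value} (the peak
#'   probability).
#' @export
pIdenticalPeak <- function(pDrop) {
  if (pDrop <= 0 || pDrop >= 1)
    stop("no interior maximum: pDrop must lie strictly inside (0, 1)")
  opt <- stats::optimize(function(m) pIdentical(m, pDrop),
                         interval = c(0, 50), maximum = TRUE, tol = 1e-6)
  list(moi = opt$maximum, value = opt$objective)
}

#' All closed-form design quantities at one parameter point
#'
#' Convenience calculator bundling the analytic formulas for a candidate
#' experimental design.
#'
#' @param S number of cells.
#' @param B pool complexity.
#' @param M MOI.
#' @param pDrop dropout probability.
#' @return named list: labeled fraction, effective MOI, mean barcodes per
#'   labeled cell, no-overlap probability, identical-read probability, the
#'   complexity bound, and the identical-read peak MOI (NA at the dropout
#'   endpoints).
#' @export
analyticSummary <- function(S, B, M, pDrop) {
  peak <- if (pDrop > 0 && pDrop < 1) pIdenticalPeak(pDrop)$moi else NA_real_
  mEff <- M * (1 - pDrop)
  list(S = S, B = B, moi = M, p_drop = pDrop,
       labeled_fraction = labeledFractionTheory(M),
       effective_moi = mEff,
       mean_barcodes_per_labeled_cell =
         if (mEff > 0) meanBarcodesInLabeled(moi = M, pDrop = pDrop) else NA_real_,
       p_no_overlap = pNoOverlap(S, B, M),
       p_identical_read = pIdentical(M, pDrop),
       min_complexity_bound = minComplexityBound(S, M),
       p_identical_peak_moi = peak)
}
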