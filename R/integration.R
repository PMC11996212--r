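#' Construct a barcode pool
#'
#' Builds the library of \code{complexity} distinct barcode types. By default
#' all types are equally abundant (the uniform pool, stored without
#' materialising weights). Explicit \code{weights} describe an arbitrary
#' library composition; alternatively \code{abundanceSkew > 0} draws skewed
#' weights as normalised log-normal variates with log-sd equal to the skew,
#' emulating the library skewing seen in large real pools.
#'
#' @param complexity number of distinct barcode types B (>= 1).
#' @param weights optional numeric vector of relative abundances, length B;
#'   normalised to sum to 1.
#' @param abundanceSkew nonnegative log-normal sigma for randomly skewed
#'   weights (0 = uniform). Ignored when \code{weights} is given. Uses the
#'   current RNG stream; call \code{set.seed} first for reproducibility.
#' @return A [BarcodePool-class] object.
#' @examples
#' barcodePool(100)
#' set.seed(1); barcodePool(50, abundanceSkew = 1)
#' @export
barcodePool <- function(complexity, weights = NULL, abundanceSkew = 0) {
  B <- as.integer(complexity)
  if (is.na(B) || B < 1L) stop("complexity must be a positive integer")
  if (!is.null(weights)) {
    if (length(weights) != B) stop("weights must have length ", B)
    if (any(weights < 0)) stop("weights must be nonnegative")
    s <- sum(weights)
    if (s <= 0) stop("weights must have positive sum")
    w <- weights / s
  } else if (abundanceSkew > 0) {
    w <- stats::rlnorm(B, meanlog = 0, sdlog = abundanceSkew)
    w <- w / sum(w)
  } else {
    w <- numeric(0)
  }
  new("BarcodePool", complexity = B, weights = w)
}

.isUniformPool <- function(pool) {
  w <- pool@weights
  length(w) == 0L || max(abs(w - 1 / pool@complexity)) < 1e-12
}

## draw a sorted 0-based subset of size k from 0..B-1
.sampleTypes <- function(B, k) {
  useHash <- (B > 1e5 && k < B / 2)
  sort.int(sample.int(B, k, useHash = useHash)) - 1L
}

#' Uniform barcode integration
#'
#' Seeds \code{S} cells from a uniform pool: every one of the B barcode types
#' enters a given cell independently with probability \code{pIn}, so the
#' integrated-set size is Binomial(B, pIn) with mean M = B * pIn (the MOI).
#' Implemented by drawing the set size first and then that many distinct
#' types — identical in law under uniform weights, and O(L) rather than O(B)
#' per cell. Cells that receive no barcode are retained as unlabeled.
#'
#' @param S number of cells to seed.
#' @param pool a uniform [BarcodePool-class].
#' @param pIn per-(cell, type) insertion probability in [0, 1]. Exactly one
#'   of \code{pIn} and \code{moi} must be given; \code{moi} is converted via
#'   \code{pIn = moi / B}.
#' @param moi multiplicity of infection M = B * pIn.
#' @return A [CellCohort-class] of S founder cells with ids \code{1..S}.
#' @examples
#' set.seed(1)
#' cohort <- integrateUniform(1000, barcodePool(1e4), moi = 0.5)
#' mean(lengths(barcodeSets(cohort)))   # close to 0.5
#' @export
integrateUniform <- function(S, pool, pIn = NULL, moi = NULL) {
  stopifnot(is(pool, "BarcodePool"))
  if (!.isUniformPool(pool))
    stop("integrateUniform requires a uniform pool; see integrateBiased")
  B <- pool@complexity
  if (is.null(pIn) && is.null(moi)) stop("give pIn or moi")
  if (!is.null(pIn) && !is.null(moi)) stop("give only one of pIn, moi")
  if (is.null(pIn)) pIn <- moi / B
  if (length(pIn) != 1L || is.na(pIn) || pIn < 0 || pIn > 1)
    stop("pIn must lie in [0, 1]")
  S <- as.integer(S)
  if (is.na(S) || S < 1L) stop("S must be a positive integer")
  L <- stats::rbinom(S, B, pIn)
  sets <- vector("list", S)
  sets[L == 0L] <- list(integer(0))
  for (i in which(L > 0L)) sets[[i]] <- .sampleTypes(B, L[i])
  new("CellCohort", founderId = seq_len(S), barcodeSets = sets,
      poolComplexity = B)
}

#' Integrated-set size probability mass function
#'
#' P(L) = Binomial(B, pIn) mass at L: the distribution of the number of
#' distinct barcode types integrated into one cell under uniform insertion.
#' Out-of-range L returns 0 by convention.
#'
#' @param B pool complexity.
#' @param pIn per-type insertion probability.
#' @param L integer set size(s).
#' @return probability (vectorised over \code{L}).
#' @export
setSizePmf <- function(B, pIn, L) {
  if (pIn < 0 || pIn > 1) stop("pIn must lie in [0, 1]")
  p <- stats::dbinom(L, size = B, prob = pIn)
  p[L < 0 | L > B] <- 0
  p
}

#' Poisson approximation to the set-size distribution
#'
#' In the sparse-labeling regime (pIn << 1, B >> 1) the integrated-set size
#' is approximately Poisson with mean M, the MOI: P(L) = exp(-M) M^L / L!.
#'
#' @param M MOI (nonnegative).
#' @param L integer set size(s).
#' @return probability (vectorised over \code{L}).
#' @export
poissonSetSizePmf <- function(M, L) {
  if (any(M < 0)) stop("M must be nonnegative")
  if (any(L < 0)) stop("L must be nonnegative")
  stats::dpois(L, lambda = M)
}

#' Exact set-size probability under per-type insertion probabilities
#'
#' Exact enumeration of the probability that exactly \code{L} types
#' integrate, for an arbitrary vector of per-(cell, type) insertion
#' probabilities: the sum over all L-subsets of the pool of the product of
#' insertion probabilities inside the subset and complements outside it.
#' Exponential in pool size, so restricted to pools of at most 20 types; it
#' serves as the exact oracle for the sampling routines and reduces to
#' [setSizePmf()] when all probabilities are equal.
#'
#' @param perCellInsertionProbs numeric vector of per-type probabilities.
#' @param L target set size.
#' @return probability.
#' @examples
#' integrationProbabilityExact(c(0.1, 0.2, 0.3), 2)  # 0.092
#' @export
integrationProbabilityExact <- function(perCellInsertionProbs, L) {
  p <- perCellInsertionProbs
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  B <- length(p)
  if (B > 20L) stop("exact enumeration supports pools of at most 20 types")
  if (L < 0 || L > B) return(0)
  if (L == 0) return(prod(1 - p))
  idx <- utils::combn(B, L)
  tot <- 0
  for (k in seq_len(ncol(idx))) {
    inS <- idx[, k]
    tot <- tot + prod(p[inS]) * prod(1 - p[-inS])
  }
  tot
}

#' Biased barcode integration
#'
#' Integration with non-uniform cells and non-uniform barcodes: each cell's
#' exposure is u * M with u drawn from a mean-1 Gamma of shape
#' \code{susceptibilityDispersion}; the cell's number of integration events
#' is Poisson in that exposure; each event picks a barcode type from the
#' pool's abundance weights; the integrated set is the distinct types drawn.
#' The marginal set-size distribution is over-dispersed (variance
#' M + M^2/shape before de-duplication) whenever the shape is finite, and
#' degenerates to the uniform Poisson model as shape tends to infinity with
#' uniform weights.
#'
#' @param S number of cells.
#' @param pool a [BarcodePool-class] (uniform or skewed).
#' @param moi mean exposure M (nonnegative).
#' @param susceptibilityDispersion positive Gamma shape; \code{Inf} means
#'   every cell has susceptibility exactly 1.
#' @return A [CellCohort-class].
#' @export
integrateBiased <- function(S, pool, moi, susceptibilityDispersion = Inf) {
  stopifnot(is(pool, "BarcodePool"))
  if (moi < 0) stop("moi must be nonnegative")
  if (susceptibilityDispersion <= 0) stop("susceptibilityDispersion must be > 0")
  S <- as.integer(S)
  if (is.na(S) || S < 1L) stop("S must be a positive integer")
  B <- pool@complexity
  u <- if (is.finite(susceptibilityDispersion))
    stats::rgamma(S, shape = susceptibilityDispersion,
                  rate = susceptibilityDispersion)
  else rep(1, S)
  nEvents <- stats::rpois(S, u * moi)
  total <- sum(nEvents)
  sets <- vector("list", S)
  sets[nEvents == 0L] <- list(integer(0))
  if (total > 0L) {
    draws <- if (length(pool@weights) == 0L)
      sample.int(B, total, replace = TRUE)
    else
      sample.int(B, total, replace = TRUE, prob = pool@weights)
    byCell <- split(draws, rep.int(seq_len(S), nEvents))
    for (key in names(byCell))
      sets[[as.integer(key)]] <- sort.int(unique(byCell[[key]])) - 1L
  }
  new("CellCohort", founderId = seq_len(S), barcodeSets = sets,
      poolComplexity = B)
}
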