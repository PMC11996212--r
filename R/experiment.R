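#' Build and validate a sweep configuration
#'
#' Describes a full factorial experiment over MOI, pool-complexity ratio
#' B/S, dropout probability and threshold strategy, with a fixed number of
#' replicates per grid point. Every stochastic quantity downstream is
#' derived from \code{seed} and the (grid point, replicate) index, so a
#' config reruns bit-identically.
#'
#' @param S initial number of cells.
#' @param moiGrid MOI values to sweep.
#' @param bOverSGrid pool-complexity-to-cells ratios B/S (B = ratio * S,
#'   rounded).
#' @param pDropGrid dropout probabilities.
#' @param strategies subset of \code{c("any_overlap", "min_d",
#'   "true_count")}.
#' @param replicates replicates per grid point (>= 1).
#' @param generations,propagationSnapshots,passagingPeriod,engine passed to
#'   [propagate()].
#' @param integration \code{"uniform"} or \code{"biased"}.
#' @param susceptibilityDispersion,abundanceSkew biased-integration
#'   parameters (see [integrateBiased()] and [barcodePool()]).
#' @param seed root seed (integer).
#' @return a validated config (list with class \code{"ExperimentConfig"}).
#' @export
experimentConfig <- function(S, moiGrid, bOverSGrid, pDropGrid,
                             strategies = "any_overlap", replicates = 20L,
                             generations = 15L,
                             propagationSnapshots = c(0L, 5L, 10L, 15L),
                             passagingPeriod = 1L,
                             engine = "synchronized_doubling",
                             integration = c("uniform", "biased"),
                             susceptibilityDispersion = Inf,
                             abundanceSkew = 0, seed = 1L) {
  integration <- match.arg(integration)
  if (S < 1) stop("S must be >= 1")
  if (any(moiGrid < 0)) stop("MOI values must be nonnegative")
  if (any(bOverSGrid <= 0)) stop("B/S values must be positive")
  if (any(pDropGrid < 0 | pDropGrid > 1)) stop("pDrop values must lie in [0, 1]")
  if (!all(strategies %in% c("any_overlap", "min_d", "true_count")))
    stop("unknown strategy")
  if (replicates < 1) stop("replicates must be >= 1")
  structure(list(S = as.integer(S), moiGrid = moiGrid,
                 bOverSGrid = bOverSGrid, pDropGrid = pDropGrid,
                 strategies = strategies, replicates = as.integer(replicates),
                 generations = as.integer(generations),
                 propagationSnapshots = as.integer(propagationSnapshots),
                 passagingPeriod = as.integer(passagingPeriod),
                 engine = engine, integration = integration,
                 susceptibilityDispersion = susceptibilityDispersion,
                 abundanceSkew = abundanceSkew, seed = as.integer(seed)),
            class = "ExperimentConfig")
}

## stable per-(grid point, replicate) seed below 2^31
.deriveSeed <- function(root, gridIndex, replicate) {
  as.integer((as.numeric(root) %% 65011 * 33013 +
              gridIndex * 7907 + replicate * 104729) %% 2147483629 + 1)
}

#' Simulate one barcoding experiment end to end
#'
#' One pass through the full pipeline — integration, propagation, dropout,
#' clustering, scoring — at a single parameter point. Used by
#' [runExperiment()] and convenient on its own.
#'
#' @param S cells; \code{B} pool complexity; \code{moi} MOI; \code{pDrop}
#'   dropout probability.
#' @param B pool complexity.
#' @param moi MOI.
#' @param pDrop dropout probability.
#' @param strategy threshold strategy for [inferLineages()].
#' @param generations,propagationSnapshots,passagingPeriod,engine passed to
#'   [propagate()].
#' @param integration \code{"uniform"} or \code{"biased"}.
#' @param susceptibilityDispersion,abundanceSkew biased-integration
#'   parameters.
#' @return list: \code{report} ([AccuracyReport-class] or NULL when no cell
#'   kept a barcode), \code{assignment}, \code{table}, \code{truth},
#'   \code{degenerate} flag.
#' @export
simulateExperiment <- function(S, B, moi, pDrop, strategy = "any_overlap",
                               generations = 15L,
                               propagationSnapshots = c(0L, 5L, 10L, 15L),
                               passagingPeriod = 1L,
                               engine = "synchronized_doubling",
                               integration = "uniform",
                               susceptibilityDispersion = Inf,
                               abundanceSkew = 0) {
  if (integration == "uniform") {
    pool <- barcodePool(B)
    cohort <- integrateUniform(S, pool, moi = moi)
  } else {
    pool <- barcodePool(B, abundanceSkew = abundanceSkew)
    cohort <- integrateBiased(S, pool, moi = moi,
                              susceptibilityDispersion = susceptibilityDispersion)
  }
  traj <- propagate(cohort, generations = generations,
                    snapshotGenerations = propagationSnapshots,
                    passagingPeriod = passagingPeriod, engine = engine)
  tab <- applyDropout(traj, pDrop)
  truth <- truePropagatedLineages(traj, tab)
  if (!any(lengths(tab@sets) > 0L))
    return(list(report = NULL, assignment = NULL, table = tab,
                truth = truth, degenerate = TRUE))
  ## the D* oracle threshold targets the true lineage count *within the
  ## clustered cells* — every founder with a surviving non-empty read,
  ## including those seen only at generation 0
  clusteredLineages <- length(unique(
    tab@founderId[lengths(tab@sets) > 0L]))
  assignment <- inferLineages(tab, strategy,
                              truthCount = if (strategy == "true_count")
                                clusteredLineages else NULL)
  list(report = accuracyReport(assignment, truth, tab, initialCells = S),
       assignment = assignment, table = tab, truth = truth,
       degenerate = FALSE)
}

#' Run a parameter sweep
#'
#' Executes the full factorial grid of an [experimentConfig()], one
#' independently seeded pipeline run per (grid point, replicate), and
#' returns the tidy result table (one row each). Degenerate runs in which
#' every barcode was lost are recorded as zero-score rows flagged
#' \code{degenerate}.
#'
#' @param config an \code{ExperimentConfig}.
#' @param outputDir optional directory; when given, writes
#'   \code{sweep_results.csv} and a \code{manifest.json} echoing the config,
#'   package version and root seed.
#' @param verbose print a progress line per grid point.
#' @return data.frame with parameters, seed and all accuracy fields.
#' @export
runExperiment <- function(config, outputDir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "ExperimentConfig"))
  grid <- expand.grid(moi = config$moiGrid, b_over_s = config$bOverSGrid,
                      p_drop = config$pDropGrid, strategy = config$strategies,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid) * config$replicates)
  k <- 0L
  for (g in seq_len(nrow(grid))) {
    if (verbose)
      message(sprintf("grid %d/%d: MOI=%g B/S=%g pDrop=%g %s", g, nrow(grid),
                      grid$moi[g], grid$b_over_s[g], grid$p_drop[g],
                      grid$strategy[g]))
    B <- max(1L, as.integer(round(grid$b_over_s[g] * config$S)))
    for (r in seq_len(config$replicates)) {
      seed <- .deriveSeed(config$seed, g, r)
      set.seed(seed)
      sim <- simulateExperiment(
        S = config$S, B = B, moi = grid$moi[g], pDrop = grid$p_drop[g],
        strategy = grid$strategy[g], generations = config$generations,
        propagationSnapshots = config$propagationSnapshots,
        passagingPeriod = config$passagingPeriod, engine = config$engine,
        integration = config$integration,
        susceptibilityDispersion = config$susceptibilityDispersion,
        abundanceSkew = config$abundanceSkew)
      rep <- if (sim$degenerate)
        list(accurate_lineage_ratio = 0, accurate_per_initial_cell = 0,
             labeled_fraction = 0, fm_index = NA_real_, v_measure = NA_real_,
             n_true_lineages = sim$truth$nLineages, n_accurate_lineages = 0L,
             n_inferred_clusters = 0L, n_clustered_cells = 0L,
             n_excluded_cells = nCells(sim$table),
             n_initial_cells = config$S)
      else as.list(sim$report)
      k <- k + 1L
      rows[[k]] <- c(list(moi = grid$moi[g], b_over_s = grid$b_over_s[g],
                          B = B, p_drop = grid$p_drop[g],
                          strategy = grid$strategy[g], replicate = r,
                          seed = seed, degenerate = sim$degenerate),
                     rep)
    }
  }
  out <- do.call(rbind, lapply(rows, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(outputDir, "sweep_results.csv"),
                     row.names = FALSE)
    manifest <- list(package = "BarcodeTrace",
                     version = as.character(utils::packageVersion("BarcodeTrace")),
                     seed = config$seed,
                     config = unclass(config))
    jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' Summarise a sweep by grid point
#'
#' Per-(MOI, B/S, pDrop, strategy) means and Monte-Carlo standard errors of
#' the accuracy measures, the form used for trade-off curves.
#'
#' @param result the data.frame returned by [runExperiment()].
#' @param measures numeric columns to summarise.
#' @return data.frame with \code{mean_*}, \code{se_*} and \code{n} columns;
#'   SE is reported as 0 when n = 1.
#' @export
summarizeSweep <- function(result,
                           measures = c("accurate_lineage_ratio",
                                        "accurate_per_initial_cell",
                                        "labeled_fraction", "fm_index",
                                        "v_measure", "n_accurate_lineages")) {
  if (nrow(result) == 0L) stop("empty sweep result")
  measures <- intersect(measures, names(result))
  keyCols <- intersect(c("moi", "b_over_s", "p_drop", "strategy"),
                       names(result))
  key <- interaction(result[keyCols], drop = TRUE, lex.order = TRUE)
  parts <- split(seq_len(nrow(result)), key)
  out <- do.call(rbind, lapply(parts, function(idx) {
    row <- result[idx[1L], keyCols, drop = FALSE]
    row$n <- length(idx)
    for (m in measures) {
      x <- result[[m]][idx]
      x <- x[!is.na(x)]
      row[[paste0("mean_", m)]] <- if (length(x)) mean(x) else NA_real_
      row[[paste0("se_", m)]] <- if (length(x) > 1L)
        stats::sd(x) / sqrt(length(x)) else 0
    }
    row
  }))
  rownames(out) <- NULL
  out
}
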