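# BarcodeTrace

Design and simulation of lentiviral cellular-barcoding lineage-tracing
experiments.

Cellular barcoding marks cells with heritable nucleic-acid tags delivered by
a pooled vector library, so their clonal descendants can be recognised in
later single-cell snapshots. The method has two intrinsic error sources: the
stochastic infection makes barcode-to-cell matching non-injective (a cell
may carry several barcodes, a barcode may label several cells, many cells
get none), and single-cell RNA-seq readout *drops out* a sizeable fraction
of integrated barcodes at each observation. Whether a planned experiment can
actually track the lineages it is meant to track therefore depends on four
design parameters — population size *S*, barcode-pool complexity *B*,
multiplicity of infection *M* (MOI), and dropout probability
*p*<sub>drop</sub> — in non-obvious, partly antagonistic ways.

BarcodeTrace is for experimentalists and modellers planning such
experiments. It simulates the whole pipeline forward and reconstructs
lineages from the corrupted observations:

1. **Integration** — each of the *B* barcode types enters a cell with
   probability *p*<sub>in</sub>, so the per-cell barcode count is
   Binomial(*B*, *p*<sub>in</sub>) ≈ Poisson(*M*), *M* = *B p*<sub>in</sub>;
   the labeled fraction is 1 − e<sup>−*M*</sup>. An over-dispersed biased
   mode (Gamma-mixed susceptibility × skewed library weights) is included.
2. **Propagation** — neutral synchronized doubling with stochastic
   passaging back to *S* cells (Wright–Fisher engine as a variant),
   15 generations with snapshots at 0/5/10/15 by default.
3. **Observation** — every integrated barcode is read independently with
   probability 1 − *p*<sub>drop</sub>, freshly per snapshot; the observed
   count is Binomial(*B*, *p*<sub>in</sub>(1 − *p*<sub>drop</sub>)).
4. **Reconstruction** — observed cells from all snapshots are clustered by
   Jaccard dissimilarity *d*(*X*,*Y*) = 1 − |*X*∩*Y*|/|*X*∪*Y*| under
   single linkage, cut at one of three thresholds: any-overlap
   (*D* = 1⁻), identical-sets-only (minD, *D* = 0), or the oracle *D**
   matched to the true lineage count.
5. **Scoring** — accurately-identified-lineage ratio (exact cluster↔clone
   match), Fowlkes–Mallows index and V-measure against the ground truth,
   plus MOI estimation from labeled fractions.

Closed-form calculators for the uniform model — the no-overlap probability
(1 + (*S*/*B*)*M*) e<sup>−(*S*/*B*)*M*</sup>, the post-dropout
identical-read probability
e<sup>−2*p*(1−*p*)*M*</sup> − e<sup>−(1−*p*²)*M*</sup> and its interior
peak, and the complexity rule *B* ≳ *S*<sup>3/2</sup>*M* — double as design
tools and as analytic oracles for the Monte-Carlo engine.

## A worked example

```r
library(BarcodeTrace)
set.seed(1)

pool   <- barcodePool(1e5)                         # B = 100,000 barcode types
cohort <- integrateUniform(1000, pool, moi = 0.5)  # S = 1,000 cells
cohort
#> CellCohort: 1000 founder cells, 387 labeled; pool complexity 100000
#>   mean barcodes/cell: 0.509

traj <- propagate(cohort, generations = 15)        # snapshots 0/5/10/15
obs  <- applyDropout(traj, pDrop = 0.1)
obs
#> ObservedCellTable: 4000 observations over 4 snapshot(s); 1580 with
#> non-empty barcode sets

truth <- truePropagatedLineages(traj, obs)
fit   <- inferLineages(obs, "any_overlap")
accuracyReport(fit, truth, obs, initialCells = 1000)
#> AccuracyReport
#>   accurate-lineage ratio : 0.9627
#>   accurate / initial cell: 0.155
#>   labeled fraction       : 0.395
#>   Fowlkes-Mallows index  : 0.9916
#>   V-measure              : 0.9984
```

Reading: at MOI 0.5 about 39% of cells are labeled (1 − e<sup>−0.5</sup> =
0.393); after 15 generations of passaging, the any-overlap reconstruction
recovers 96% of the truly propagated lineages exactly — about 155 tracked
lineages per 1,000 prepared cells. The analytic calculator for the same
design (`analyticSummary(1000, 1e5, 0.5, 0.1)`) reports a per-barcode
no-overlap probability of 0.99999 and a minimal recommended complexity of
*S*<sup>3/2</sup>*M* ≈ 1.6 × 10⁴ ≤ *B*, consistent with the high accuracy.

Parameter sweeps (`experimentConfig()` + `runExperiment()` +
`summarizeSweep()`) reproduce the design trade-off curves: accuracy versus
MOI per strategy, saturation versus *B*/*S*, and the non-monotone number of
accurately tracked lineages per prepared cell. A thin CLI with `simulate`,
`infer`, `analytics` and `sweep` subcommands lives at
`inst/cli/barcodetrace.R`; externally produced barcode-call tables in the
simple CSV dialect (`cell_id, generation, barcodes`) can be clustered with
`infer`.

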