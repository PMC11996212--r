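Package: BarcodeTrace
Title: Stochastic Simulation and Design of Cellular Barcoding Lineage-Tracing Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates lentiviral cellular barcoding experiments end to end:
    Poisson-type barcode integration into a cell population at a chosen
    multiplicity of infection (MOI), neutral propagation with periodic
    stochastic passaging, dropout-corrupted single-cell observation, and
    lineage reconstruction by Jaccard-dissimilarity single-linkage clustering
    of observed barcode sets under three threshold strategies. Closed-form
    results for the uniform-integration model (set-size distributions, barcode
    overlap probability, probability of identical post-dropout reads, and the
    library-complexity saturation bound) are provided both as design
    calculators and as analytic oracles for the Monte-Carlo engine, together
    with accuracy metrics (accurate-lineage ratio, Fowlkes-Mallows index,
    V-measure) and a parameter-sweep driver for MOI / complexity / dropout
    trade-off studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
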