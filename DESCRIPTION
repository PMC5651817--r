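Package: glvnet
Title: Microbial Interaction Networks from Longitudinal Abundance Data via
    Stability-Constrained Lotka-Volterra Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers signed, directed interaction networks among microbial taxa
    from longitudinal relative-abundance data under a generalized
    Lotka-Volterra (gLV) model. The data-determined community composition is
    treated as an asymptotically stable equilibrium of the gLV dynamics; the
    interaction matrix is recovered by a repeated Monte-Carlo-sampled compass
    (direct) search that penalizes equilibrium instability and trajectory
    misfit, and the resulting solution ensemble is distilled into a consensus
    signed network. Includes readers for taxon-abundance tables with lineage
    strings, taxonomic aggregation and relative-abundance transforms, a
    synthetic-data generator with known ground-truth networks emulating a
    two-group (control versus vancomycin) weekly mouse-microbiome study
    design, network comparison across conditions, and GraphML/TSV export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    biomformat,
    yaml,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
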