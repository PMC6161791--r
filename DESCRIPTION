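Package: cycleMap
Title: Cell-Cycle Mapping of Single-Cell Transcriptomes by Shortest
    Hamiltonian Path Ordering
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Orders single cells along the cell cycle by estimating the
    shortest Hamiltonian path through cells using distances computed on
    known cell-cycle genes, builds a 0-1 scaled perturbation map with
    contiguous G1/S/G2-M phase segments, classifies genes into cell-cycle
    phases with a Self-Organizing Map anchored by known cycle genes, and
    computes a per-phase cell-cycle index for arbitrary gene panels.
    Includes a microarray-style normalization stack (detection filtering,
    log2 + quantile normalization, a variance-stabilizing transform with
    robust spline normalization, 3-IQR outlier masking, nearest-neighbor
    imputation) and a synthetic single-cell generator with known circular
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    limma,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: SingleCell, CellCycle, Transcriptomics, Normalization, Clustering
RoxygenNote: 7.3.3
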