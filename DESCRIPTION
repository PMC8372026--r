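Package: ProgenitorKit
Title: Quantitative Analysis of Neocortical Progenitor Proliferation and Fate
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative workflows used in studies of
    embryonic neocortical progenitors: estimation of S-phase and total
    cell-cycle length and growth fraction from dual thymidine-analog
    (BrdU/EdU) pulse labeling, with a seeded steady-state population
    simulator for validation; background-corrected fluorescence-intensity
    summaries and laminar bin/zone quantification of tissue sections; a
    compact single-cell RNA-seq stage (QC filtering, log-normalization,
    PCA, graph clustering, Wilcoxon rank-sum differential expression,
    marker-based cell typing); mutual-information regulon inference with
    permutation and bootstrap filtering and Fisher's-exact master-regulator
    analysis; and reconstruction of two-group t statistics from published
    summary data. Synthetic negative-binomial count and regulatory-network
    generators exercise every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: SingleCell, RNASeq, DifferentialExpression, NetworkInference,
    CellBiology, Transcriptomics
RoxygenNote: 7.3.3
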