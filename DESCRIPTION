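Package: dppin
Title: Differential Protein-Protein Interaction Network Inference from
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers condition-specific protein association networks by fitting
    PPI-constrained linear association models to gene expression data, with
    maximum-likelihood (ordinary least squares) coefficient estimation, AIC
    model-order selection along a correlation-ordered forward path, and
    Student's t-test edge pruning.  Condition and control networks are
    contrasted through an elementwise difference matrix; each protein is
    scored by a rewiring statistic (the absolute row sum of coefficient
    differences, a stroke relevance value in the motivating cardioembolic
    stroke study), assessed by a label-permutation null, and ranked into a
    biomarker table with group means and log2 fold changes.  Includes readers
    for expression TSV and GEO series-matrix tables and BioGRID TAB edge
    lists, network export to SIF/GraphML, and a synthetic-data generator with
    ground-truth networks and decoy edges for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
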