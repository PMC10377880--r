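Package: fd4d
Title: Spatio-Temporal Fractal Dimension Analysis of EEG Source Activations
Version: 0.1.0
Authors@R:
    person("fd4d", "maintainers", email = "fd4d@example.org", role = c("aut", "cre"))
Description: Tools to quantify the spatio-temporal complexity of source-space
    EEG recordings with a four-dimensional box-counting fractal dimension
    (4DFD). Per-source magnitude thresholding turns a sources-by-samples
    current matrix into binary activation masks; supra-threshold activations
    within non-overlapping one-second windows form 4D point clouds (three
    spatial axes plus time) whose Minkowski-Bouligand dimension is estimated
    by log-log regression of box counts. Includes a nonparametric group
    statistics battery (Mann-Whitney U, ROC AUC, Spearman correlations with
    Bonferroni correction, PCA data reduction), synthetic generators for
    point clouds of known fractal dimension and for two-group source epochs,
    and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
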