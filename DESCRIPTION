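Package: sparseMVPA
Title: Sparse-Representation Multivoxel Pattern Analysis of Event-Related fMRI
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the within-class reproducibility and
    between-class discriminability of event-related fMRI brain patterns.
    Implements a two-stage voxel selection scheme (correlation screening
    against a simulated BOLD regressor, then sparse-representation selection
    by repeated L1-minimizing linear programs against a category-labeled
    regressor), an angle-based pattern reproducibility index and pattern-norm
    statistics, Talairach-cube region-of-interest analysis, cross-validated
    linear support vector machine decoding of semantic category, and
    within-subject nonparametric group statistics (exact paired Wilcoxon
    signed-rank, paired t, repeated-measures ANOVA with multiple-comparison
    correction). Includes a synthetic data generator that emulates a
    four-condition audiovisual experiment with planted category-informative
    voxels and condition-dependent within-class pattern dispersion, providing
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    e1071
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    RNifti,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
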