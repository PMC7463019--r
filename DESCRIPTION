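Package: refinedmap
Title: Distance-Preserving Feature-to-Image Maps for Convolutional Learning
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Maps unordered high-dimensional feature vectors (molecular
    descriptors, gene expression profiles) to compact 2D images whose pixel
    neighbourhoods preserve feature-space distances, so that standard
    convolutional networks can be trained on tabular data. Locations are
    inferred by Bayesian metric multidimensional scaling on the unit square
    (truncated-normal likelihood, Metropolis-in-Gibbs sampling) and refined
    by a greedy hill-climbing assignment onto a square pixel grid with at
    most one feature per pixel. Includes random and PCA baseline mappers,
    a Gaussian-process synthetic benchmark generator, a self-contained CNN
    engine (sequential regressor, sequential classifier, two-arm hybrid),
    and the evaluation toolkit used for drug-sensitivity regression:
    NRMSE, NMAE, PCC, bias angle, classification metrics, AUROC, bootstrap
    gap statistics, robustness fractions, jackknife-after-bootstrap and
    binomial confidence intervals, McNemar tests, residual-regression bias
    correction, and constrained linear model stacking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    vegan,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
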