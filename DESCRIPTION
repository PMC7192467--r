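Package: smoothNB
Title: Smooth Goodness-of-Fit Tests for Negative Binomial Regression of
    Sequence Count Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a smooth (efficient score) goodness-of-fit test for
    the negative binomial distribution in two-group regression models with
    log library-size offsets, as used for RNA-Seq and microbiome count
    data. The test embeds the negative binomial in an exponentially tilted
    family spanned by polynomials that are orthonormal under the fitted
    model and orthogonal to the nuisance score functions; p-values are
    obtained from the asymptotic chi-square reference or from a full
    parametric bootstrap. The package also estimates the fraction of
    features that are poorly fit via a modified Grenander density estimate
    of the p-value mixture, screens features for zero inflation with a
    likelihood-ratio test against the zero-inflated negative binomial,
    and quantifies the downstream consequences of lack of fit through a
    mock (random relabelling) study comparing the negative binomial Wald
    test with the stratified Prentice rank-sum test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, StatisticalMethod, Regression, RNASeq, Microbiome,
    QualityControl
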