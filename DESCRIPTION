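Package: teprof
Title: Translational Efficiency Analysis from Paired Total and Polysomal
    RNA-seq
Version: 0.1.0
Authors@R:
    person("teprof", "authors", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Differential translation analysis for paired total and
    polysomal RNA-seq count data. Fits per-gene negative binomial
    generalized linear models with a strain-by-RNA-fraction interaction,
    normalizes libraries with median-of-ratios size factors, shrinks
    dispersions toward a parametric mean-dispersion trend with an
    empirical Bayes prior, and tests the interaction coefficient
    (differential translational efficiency) with Wald statistics and
    Benjamini-Hochberg adjustment. Also quantifies sucrose-gradient
    polysome profiles (peak detection, valley-bounded areas under the
    curve, Holm-Sidak replicate comparisons), computes qPCR relative
    expression against the geometric mean of reference genes, and ships
    a negative binomial count simulator with known ground truth for
    power, bias and false discovery rate studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
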