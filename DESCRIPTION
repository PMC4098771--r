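Package: dafs
Title: Data-Adaptive Flagging of Low-Expressed Genes in RNA-Seq Samples
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the lower bound of high expression in a single RNA-seq
    sample without imposing a mixture model on the data. The expression vector
    (raw counts, RPKM or FPKM) is log2-transformed after removing zeros, and a
    profile of scaled Kolmogorov-Smirnov distances between quantile-trimmed
    upper tails and a fitted normal reference is computed over a grid of
    trimming percentiles. A one-dimensional multivariate adaptive regression
    splines (MARS) fit to the profile locates the left-most
    decreasing-to-increasing knot, which defines the optimal quantile cutoff
    separating low-expressed (LE) from high-expressed (HE) genes. A
    two-component Gaussian mixture comparator (EM fit with equal/unequal
    variance structures selected by BIC, and the closed-form density
    intersection cutoff) and a Monte-Carlo simulation harness with
    sensitivity/specificity evaluation are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'ks-profile.R'
    'mars.R'
    'mixture.R'
    'dafs.R'
    'simulation.R'
    'io.R'
    'plots.R'
    'cli.R'
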