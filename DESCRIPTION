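Package: multigt
Title: Global Score Tests for Association with Multiple Covariate Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variance-component (global) score tests for association between a
    response variable, such as one gene's expression, and one or more
    high-dimensional covariate sets, such as copy-number and methylation
    probes in a cis window around the gene.  Provides the single-set
    quadratic-form statistic, its standardization, joint statistics over
    multiple sets with three combination modes, permutation and
    weighted-chi-square (ratio of quadratic forms) null distributions, a
    genomic window builder mapping probes to genes around transcription
    start sites, a simulation engine for linked and empirically correlated
    covariate sets under four association-region effect types, and
    selection/overlap/dilution/ROC summaries for interpreting joint versus
    individual tests genome-wide.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
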