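Package: efpool
Title: Pooling Greenhouse-Gas Emission Factor Estimates
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines multiple, possibly conflicting, estimates of a
    greenhouse-gas emission factor into a single point estimate with valid
    uncertainty. Implements the overall (sample-size weighted) mean, three
    estimators of the population variance - the pooled within-study variance,
    the between-means estimator, and an ANOVA-based estimator equal to the
    total sum of squares over its degrees of freedom - together with their
    scaled chi-square sampling distributions, Student-t and chi-square
    confidence intervals, classical consensus-mean alternatives
    (inverse-variance weighting, Graybill-Deal, Mandel-Paule), a seeded
    Monte Carlo harness for estimator comparison and interval coverage,
    and unit conversion utilities for field-measurement case studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
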