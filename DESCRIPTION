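Package: equianova
Title: Heteroscedastic One-Way ANOVA with Equicorrelated Repeated Measures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tests of equality of group means and simultaneous confidence
    intervals for all pairwise mean differences in the one-way ANOVA model
    with compound-symmetric (equicorrelated) within-subject errors and
    unequal group variances. Implements the generalized F-test, a
    standardization-based test built on fiducial generalized pivotal
    quantities, and a parametric bootstrap test, all operating on per-group
    sufficient statistics; simultaneous interval procedures calibrated by
    the studentized maximum modulus via generalized-pivotal-quantity or
    parametric-bootstrap quantiles; a model simulator; and Monte Carlo
    drivers for Type I error and simultaneous coverage studies.
License: MIT
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr, optparse, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
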