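Package: cctcount
Title: P-Value Combination Tests for Correlated Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements the Cauchy combination test, Fisher's combination
    test, and the minimum-p (MinP) test for aggregating individual p-values
    under a global null hypothesis, together with the simulation machinery
    needed to study their operating characteristics on count data:
    sampling from multivariate Archimedean copulas (Clayton,
    Gumbel-Hougaard, survival Clayton) by frailty constructions, quantile
    transformation to negative binomial marginals, normal-approximation
    Z-tests on sample means, a standardized-skewness diagnostic for the
    normal approximation, and vectorized Monte Carlo drivers for type-I
    error, sensitivity, and sparse-signal power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
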