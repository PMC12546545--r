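Package: samcroon
Title: Structural-After-Measurement Estimation for Multilevel and
    Partially Nested SEMs with Latent Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Factor-score regression ("structural-after-measurement", SAM)
    estimators for two-level structural equation models with within-, cross-
    and between-level latent interactions and for 2/1 partially nested SEMs
    with latent moderated mediation. Implements the uncorrected factor-score
    estimator (SAM-FS) and the Croon method-of-moments corrected estimator
    (SAM-Croon), including cluster-mean reliability adjustments for
    between-level components, the variance-of-product rule for latent
    interaction terms, cluster bootstrap percentile intervals, multivariate
    normal data generators for the supported population models, and a Monte
    Carlo driver that summarises bias, average absolute bias against
    true-latent benchmarks, efficiency and convergence-failure rates.
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
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
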