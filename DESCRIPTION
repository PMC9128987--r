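Package: scrrobust
Title: Robustness of Analytic Strategies for Fear Conditioning and
    Extinction Skin Conductance Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates and bootstraps trial-level skin conductance response
    (SCR) datasets from fear acquisition and extinction paradigms, injects
    trial-wise group-level effects in standard-deviation units, evaluates a
    catalogue of fifteen published analytic strategies as partial eta squared
    effect sizes of their highest-order group interaction, and quantifies
    cross-strategy robustness via bootstrapped Kendall rank-order
    correlations, sample-size trend tests with false-discovery-rate control,
    and effect-size-inflation analyses across a sweep of sample sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
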