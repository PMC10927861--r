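Package: ftlmeta
Title: Random-Effects Meta-Analysis of Controlled Broiler Feeding Trials
Version: 0.1.0
Authors@R:
    person("ftlmeta", "maintainers", email = "maintainers@ftlmeta.org",
           role = c("aut", "cre"))
Description: A tested pipeline for pooling controlled broiler-feeding trials
    of fermented tropical leaf meal supplementation: standardized mean
    differences (Hedges' g) from two-arm summary statistics,
    DerSimonian-Laird random-effects pooling with Cochran's Q, I-squared and
    tau-squared heterogeneity quantification, restricted subgroup analysis
    and mixed-effects meta-regression over study-level moderators,
    Rosenberg's weighted fail-safe number for publication-bias robustness,
    and a synthetic trial-ensemble generator with known true parameters for
    end-to-end validation. Includes a command-line interface for running the
    full analysis from a CSV extraction table or in simulation mode.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
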