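Package: predslice
Title: Heritability and Genetic Correlations from Predictivity in Time Slices
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Closed-form estimation of narrow-sense heritabilities and genetic
    correlations for large genomic-prediction settings, using predictivity (the
    correlation between validation animals' adjusted phenotypes and their
    genomic breeding values) combined with the expected-accuracy formula based
    on the number of independent chromosome segments. Provides the estimators
    and their standard errors, a sliding-window ("time slice") estimation
    procedure over generations, single-trait GBLUP with a VanRaden genomic
    relationship matrix to compute predictivities, estimation of the number of
    independent chromosome segments, and a forward-in-time genomic-selection
    simulator with an engineered composite fitness trait for validating
    parameter recovery under selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
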