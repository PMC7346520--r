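Package: fanp
Title: Fuzzy Analytic Network Process for Multi-Criteria Priority Setting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving decision priorities from multi-expert fuzzy
    pairwise comparison judgments with the fuzzy Analytic Network Process
    (ANP). Triangular fuzzy numbers carry judgment uncertainty through
    reciprocal comparison matrices, geometric-mean panel aggregation,
    Buckley fuzzy geometric-mean or Chang extent-analysis weight derivation,
    Liou-Wang total-integral defuzzification, and Saaty consistency
    diagnostics. Network dependence among criteria clusters is resolved by
    supermatrix assembly, cluster weighting, and limit-power synthesis.
    Includes a synthetic expert-panel generator with known ground truth for
    end-to-end validation, and a bundled worked example from a published
    scarce-drug allocation study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
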