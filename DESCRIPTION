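Package: semsearch
Title: Vector-Space Semantic Analysis of Feature Generation Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing semantic memory search in the feature
    generation task. Scores multi-word feature responses against a target
    word in a word-embedding space (cosine similarity), builds
    response-position and lag trajectory records, and fits Bayesian
    mixed-effects and two-level hierarchical power-law models by MCMC, with
    posterior difference distributions for group comparisons and split
    R-hat convergence checks. Includes a synthetic-data generator with a
    compound-retrieval-cue search simulator so the entire pipeline is
    testable without access to patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
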