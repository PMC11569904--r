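Package: mcdahta
Title: Multi-Criteria Decision Analysis for Prioritizing Health Technologies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Toolkit for building and applying hierarchical multi-criteria
    decision analysis (MCDA) frameworks in health technology assessment.
    Provides a three-level criteria tree (domains, criteria, subcriteria),
    validation and summary of 100-point allocation weight-elicitation
    surveys, two-sample comparison of stakeholder weights, equal-weighted
    pooling of sample means with sum-preserving integer rounding, an
    additive multi-attribute value function over leaf scores, deterministic
    one-way and probabilistic (bootstrap or Dirichlet) sensitivity analysis
    of composite values and rankings, and a seeded synthetic-survey
    generator emulating professional and general-population respondent
    samples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
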