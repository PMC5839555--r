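Package: cannaphen
Title: Computable Phenotyping of Marijuana Use from Clinical Note Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Lexicon-based identification of likely marijuana users and
    non-users from the free text of electronic-medical-record notes, with
    the validation machinery needed to evaluate such a computable
    phenotype against interview self-report: cohort selection on ICD-9
    diagnosis codes and visit windows, whole-word term-mention detection
    with a 12-month lookback, seeded two-arm sampling with post-sampling
    exclusions, concordance tables, predictive values and enrichment
    statistics, exact and chi-square association tests, joint-year
    exposure quantification, and a fully synthetic EHR/interview
    generator (probabilistic or exact-count planting) so the entire
    pipeline is testable without protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
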