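Package: growthrisk
Title: Infant Childhood-Obesity Risk Scoring from Growth-Reference Z-Scores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for scoring an infant's risk of childhood obesity from
    routine anthropometry. Converts weight and length to age- and
    sex-adjusted z-scores against an LMS (lambda-mu-sigma) growth
    reference, computes conditional weight z-score gain (a
    regression-to-the-mean adjusted change score), and evaluates published
    logistic risk equations for three assessment windows in infancy with
    three-tier risk banding. Also provides the equation-development
    pipeline (maximum-likelihood logistic fitting, backward stepwise
    selection with interaction screening), internal bootstrap and external
    validation with ROC and threshold diagnostics, and seeded
    synthetic-cohort generators emulating the development and external
    validation samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
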