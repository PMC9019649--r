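Package: agestereo
Title: Corpus-Based Measurement of Societal Age Stereotypes and
    Medicalization of Aging
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measures societal age stereotype (SAS) scores and a
    medicalization-of-aging score from year-stamped text corpora using
    windowed collocation analysis around a node noun, span-adjusted
    pointwise mutual information filtering, and multi-rater sentiment
    lexicons with Cronbach's alpha reliability. Provides polynomial
    trend tests on the annual series and mediation / first-stage
    moderated mediation under a path-analytic framework with
    percentile-bootstrap confidence intervals, plus synthetic corpus
    and panel generators with planted effects for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
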