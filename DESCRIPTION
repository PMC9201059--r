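Package: mbcea
Title: Markov Cohort Cost-Effectiveness Model for Bevacizumab Combination
    Therapy in Recurrent Pediatric Medulloblastoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cost-effectiveness analysis of bevacizumab added to
    temozolomide plus irinotecan (T+I+B vs T+I) for recurrent pediatric
    medulloblastoma, from a Chinese payer perspective. Implements a
    three-state (event-free survival, progressed disease, death) monthly
    Markov cohort model with partitioned-survival state occupancy,
    parametric survival curves parameterized from reported medians,
    pseudo individual-patient-data reconstruction from digitized
    Kaplan-Meier coordinates with numbers at risk, discounted cost and
    QALY accumulation, incremental cost-effectiveness ratios, one-way
    deterministic sensitivity analysis with tornado ordering and
    threshold search, and Monte-Carlo probabilistic sensitivity analysis
    with cost-effectiveness acceptability curves. A synthetic two-arm
    trial generator provides test data with the statistical structure
    the analysis assumes.
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
    knitr,
    optparse,
    rmarkdown,
    survival,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
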