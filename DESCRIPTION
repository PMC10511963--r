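Package: matchdid
Title: Matched Difference-in-Differences for Late-Life Employment Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Matched difference-in-differences estimation for long-format
    longitudinal cohorts, designed for studying effects of late-life labour
    market entry and exit on bounded integer cognitive scores. Treated
    person-waves are matched exactly on their employment histories over a lag
    window; matched sets are refined by Mahalanobis-distance matching,
    propensity-score matching, propensity-score weighting or covariate
    balancing propensity score (CBPS) weighting; effects at configurable leads
    are estimated by a weighted difference-in-differences contrast with
    weighted block-bootstrap inference. Includes covariate-balance and
    parallel-trend diagnostics and a synthetic biennial ageing-cohort
    generator with confounded selection, attrition and item missingness so
    the full workflow is testable without restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
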