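Package: ffhbn
Title: Bayesian-Network Risk-Scenario Mapping for Fall-from-Height Accidents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds discrete Bayesian networks for construction fall-from-height
    (FFH) accident risk from two empirical sources: questionnaire judgments on
    candidate causal links, fused across respondent panels with Dempster-Shafer
    evidence combination, and a binary report-by-factor incidence matrix used
    for conditional-mutual-information structure refinement and Laplace-smoothed
    parameter estimation. Provides exact bidirectional inference by variable
    elimination, exhaustive enumeration and ranking of outcome risk scenarios,
    and ancestral-sampling simulators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
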