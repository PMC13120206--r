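Package: sedrisk
Title: Probabilistic Heavy-Metal Pollution and Risk Assessment for Lake Sediments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing heavy-metal contamination of lake surface
    sediments and the associated ecological and human health risks. Implements
    the geo-accumulation index, enrichment factor, contamination factor and
    Hakanson-style potential ecological risk indices with their grading
    schemes; a two-pathway (ingestion, dermal) USEPA-style exposure-dose model
    with hazard quotients/indices and carcinogenic risk for adult males,
    adult females and children; moment-based parametric distribution fitting
    with Anderson-Darling family selection; and a seeded Monte Carlo engine
    that propagates concentration and exposure-parameter uncertainty to class
    probabilities, exceedance probabilities, percentile confidence intervals
    and contribution-to-variance sensitivity. Ships a synthetic-data generator
    that emulates a 21-site, nine-metal urban-lake sediment survey.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml
Suggests:
    nortest,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
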