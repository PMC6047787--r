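Package: shrimpselect
Title: Codend Size Selectivity for Brown Shrimp from Paired-Gear Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation and prediction of trawl codend size selectivity for
    brown shrimp (Crangon crangon) from paired-gear experiments. Per-haul
    maximum-likelihood fitting of logistic selection curves with a split
    parameter from test/control length-frequency counts, random-effects
    (Fryer-type) meta-analysis across hauls with known within-haul
    covariances, exhaustive fixed-effect subset enumeration ranked by AICc,
    and a predictive framework producing retention-probability isolines over
    mesh size and exploitation-pattern indicators for a population length
    structure. Includes a synthetic paired-haul experiment generator with
    known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
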