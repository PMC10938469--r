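Package: auxgrad
Title: Auxin Transport Model of Shade-Avoidance Growth in the Arabidopsis Hypocotyl
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compartmental model of auxin production, polar and non-polar
    transport, and degradation on the four-layer, 18-row cellular grid of the
    Arabidopsis thaliana hypocotyl, coupled to auxin-driven epidermal cell
    elongation under shade (low red:far-red) treatments.  Includes light-regime
    forcing (continuous and long-day photoperiods, far-red onset with
    phytochrome decay), a J-score objective against per-cell length profiles,
    two-stage simulated-annealing calibration with a fit/validation split,
    one-at-a-time parameter sensitivity scans, and a synthetic-data generator
    emulating arch-shaped cell-length profiles across genotypes and light
    conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    lhs,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
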