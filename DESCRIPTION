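Package: mhwx
Title: Detection, Tracking and Impact Analysis of Extreme Marine Heatwaves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for the analysis of extreme marine
    heatwaves (MHWs) in gridded daily sea surface temperature: day-of-year
    climatologies and seasonally varying 90th-percentile thresholds,
    per-cell event detection with severity categorization, daily labeling
    of contiguous MHW regions with area-weighted extent metrics, record
    maps and identification of the most extreme events, ENSO (Nino3.4)
    conditioning, lagged composites of atmospheric drivers around event
    peaks, and chlorophyll-a response statistics with exact binomial and
    Monte Carlo significance tests. Includes a stochastic gridded SST
    simulator (seasonal cycle, AR(1) noise with seasonally modulated
    variance, warming trend, ENSO-like loading, implanted events with
    known truth) so that every stage is testable without observational
    archives.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
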