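Package: lakesmoke
Title: Lake Chlorophyll-a Responses to Wildfire Smoke Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links weekly satellite-derived surface chlorophyll-a in lakes
    with overhead wildfire smoke-plume exposure. Classifies smoke events and
    smoke-impacted lakes from daily plume density records, fits per-lake
    seasonal phenology with penalized cubic smoothing splines, and tests
    seasonal residuals for smoke effects: smoke versus no-smoke ANOVA with
    Student's t post hoc comparisons, per-season difference confidence
    intervals, event-aligned before/after composites with detection-limit
    filtering, per-lake response deltas with map binning, and summaries
    stratified by trophic status and elevation. Includes a synthetic lake
    landscape generator with known ground truth (seasonal bloom curves,
    lognormal noise, left-censoring at a method detection limit, stochastic
    smoke schedules, injected ephemeral responses) so the entire pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
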