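Package: squadrank
Title: Team Interdependence, Risk, and Rank in Squad Battle-Royale Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying team behavioral interdependence, collaboration,
    risk taking, and performance in squad-based battle-royale matches from
    positional telemetry. Provides a JSON-Lines telemetry dialect with
    validated readers and writers, an agent-based match simulator with a
    shrinking play area and a planted experience-moderated curvilinear
    performance model, spatial feature engineering (epsilon-graph clustering of
    teammates, normalized pair distances, landing-risk heatmaps), cohort
    assembly with Z-score outlier filtering and K-means experience strata, and
    a proportional-odds cumulative-link estimator for ordinal match rank with
    quadratic, interaction, stratified, and binary top-k robustness fits plus
    maximum-likelihood pseudo-R-squared and variance-inflation diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
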