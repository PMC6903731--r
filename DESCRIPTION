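Package: pengwinter
Title: Winter Migration Analysis for Satellite-Tracked Penguins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing Argos satellite telemetry of migratory
    seabirds during the non-breeding season. Provides quality control of raw
    Argos fixes (location-class and error-ellipse screening, a constant-speed
    filter, minimum-duration retention), maximum-likelihood fitting of a
    continuous-time correlated random walk state-space model with Kalman
    filter/smoother machinery and multiple track imputation, equal-area
    hexagonal habitat-utilization distributions with inter- and intra-colony
    overlap indices, local/east/west migration classification with
    distance and swim-speed summaries, gridded environmental covariate
    extraction (sea-surface temperature, sea-ice concentration, bathymetry,
    surface currents), and a two-part isocline-based index of open-water and
    marginal-ice-zone habitat area. A synthetic-data generator emulating
    duty-cycled Argos sampling, behaviour-specific movement and analytic
    environmental fields makes the whole pipeline testable without external
    data products.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
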