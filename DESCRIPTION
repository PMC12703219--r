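Package: sonpp
Title: Southern Ocean Net Primary Production Trends from Satellites, Floats and Earth System Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare Southern Ocean net primary production (NPP)
    trends across satellite-style ocean-colour algorithms (VGPM, CbPM, AbPM,
    CAFE), BGC-Argo-style float profiles, and CMIP6-style Earth System Model
    output. Implements the six NPP algorithms with shared photophysiology
    utilities, the float processing chain (quality control, monotone Hermite
    regridding, fluorescence quenching correction, backscatter cleaning and
    conversion to phytoplankton carbon), normality-routed robust trend
    estimation (Huber regression or Mann-Kendall/Theil-Sen), area-weighted
    regional integration with moving-window jackknife uncertainty, and Earth
    System Model driver decomposition of NPP changes into phytoplankton
    biomass, iron limitation and light limitation contributions. A synthetic
    data module generates every input class with known ground truth so the
    full analysis runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    pracma,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    geosphere
Config/testthat/edition: 3
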