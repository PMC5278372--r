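Package: hlurm
Title: Historical Land Use Reconstruction with Cellular-Automata Allocation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Backcasts historical land-use maps from later observed maps.
    Implements the four stages of a historical land use reconstruction
    model: quantity control (multi-source area fusion with Analytic
    Hierarchy Process weights, rule-based transition-matrix editing and
    margin-rescaled Markov backcasting), spatial conversion rules
    (categorical-raster cross-tabulation and change-trajectory analysis),
    probability surfaces (multi-criteria evaluation of 0-255 factor layers
    under boolean constraints), and ordered cellular-automata spatial
    allocation. Reconstructions are validated by three-map comparison
    (null successes, hits, misses, false alarms; figure of merit and the
    quantity/allocation error decomposition). A seeded synthetic-landscape
    generator provides autocorrelated categorical rasters, correlated
    factor surfaces and forward-simulated change for testing without any
    external data. Includes the published Zhenlai County (Jilin, China)
    case-study tables as example inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
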