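Package: vigsa
Title: Global Sensitivity Analysis of Vegetation Indices from Coupled
    Leaf-Canopy Radiative Transfer Simulations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the sensitivity and robustness of vegetation indices
    by variance-based global sensitivity analysis (Sobol' first-order and
    total-effect indices via Saltelli's radial estimators over quasi-random
    designs) of coupled leaf-canopy radiative transfer simulations. Includes
    a four-parameter plate-model leaf simulator coupled to a four-stream
    turbid-medium canopy model for homogeneous canopies and to a hybrid
    geometric-optical forest model, sensor band-setting convolution for
    Landsat 8, MODIS, Sentinel-2, Sentinel-3 and EnMAP, and a registry of
    published chlorophyll-, water- and leaf-area-sensitive spectral indices.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    pracma,
    lhs,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
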