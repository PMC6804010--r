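Package: ionsurf
Title: Surface Ionomics of Pretreated Lignocellulose from ToF-SIMS Chemical Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links the spatial distribution of surface-bound ions (notably
    lithium) on pretreated sugarcane bagasse, measured as ToF-SIMS chemical
    images, to enzymatic saccharification yields. Implements the full
    analysis chain: 8-bit chemical-image standardization, IsoData automatic
    thresholding with connected-component particle statistics, surface
    texture metrics (differential entropy, roughness/waviness, periodic-area
    fraction, excavation statistics), mixture discriminant analysis with EM
    and jackknife feature importance, and penalized-spline comparison of
    reducing-sugar release curves. A synthetic-data module generates ion
    maps and saccharification curves with known ground truth so every stage
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    mgcv,
    igraph,
    ape,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
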