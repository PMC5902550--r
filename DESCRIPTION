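Package: fishweirs
Title: Spatial and Circular Statistics for Floodplain Fish-Weir Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative analysis of earthen fish-weir
    landscapes on seasonally flooded savannahs: Monte Carlo randomization
    tests of the spatial association between ponds and linear or zigzag
    earthworks (weirs, causeways, canals) and their V-shaped structures; a
    detection-sensitivity analysis asking how many undetected ponds would
    overturn an observed association; circular statistics (Kuiper uniformity
    test, Watson-Williams test, circular means, berm-arc accumulation) for
    feature orientations against flood-flow direction; morphometric
    comparison of V-shaped structures between fishery systems from raw
    measurements or published summary statistics; and fish-concentration
    factors relating inter-weir capture areas to collecting-structure
    surfaces. Includes a synthetic landscape generator with known ground
    truth for calibration and recovery studies, a GeoJSON/CSV data model,
    and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
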