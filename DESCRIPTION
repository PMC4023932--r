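Package: mimicmaps
Title: Spatial Analysis of Digitised Museum Specimen Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising digitised natural-history collections of
    polymorphic species in space: validation and geocode-error filtering of
    specimen records, an equal-area (Albers, Africa) projection, global Moran's
    I with incremental distance-band selection, Getis-Ord Gi* hot-spot analysis
    of sampling density, circle-count density surfaces with quantile classing,
    convex-hull range inference clipped to occupied environmental classes,
    point-in-polygon overlay of focal morphs against range polygons, and a
    synthetic-data generator that emulates the statistical structure of a
    continental butterfly collection for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
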