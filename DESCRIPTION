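Package: coastband
Title: Transversal Continuity Analysis of Coastal Natural Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies land-cover patches in a coastal zone by their
    adjacency order ("band") from the coastline, extracts transversally
    connected natural landscape mosaics (TCNLM), assigns each mosaic patch
    a Transversal Continuity Depth (TCD), and flags endangered hinge
    patches and restorable artificial barrier patches.  Works on CORINE
    Land Cover style polygon layers (GeoJSON) in a projected coordinate
    system, with a deterministic synthetic-landscape generator for
    testing and a command-line pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
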