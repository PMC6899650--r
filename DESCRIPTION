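Package: sppa
Title: Spatial Point Process Analysis of Fossil Bedding-Plane Communities
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for classifying the assembly processes of sessile
    benthic (palaeo)communities from mapped bedding-plane censuses.
    Implements distance-based summary functions for planar point patterns
    (pair correlation function, Ripley's L, O-ring, nearest-neighbour
    distribution) with translation/border edge correction, homogeneous and
    heterogeneous Poisson null models with Monte-Carlo simulation envelopes
    and Diggle's rank goodness-of-fit test, Thomas cluster process models
    (single, nested double, and inhomogeneous variants) fitted by minimal
    contrast, toroidal-shift tests of bivariate independence, taphonomic
    bias corrections (retrodeformation of tectonic strain, differential
    erosion intensity models selected by AIC), a niche-versus-neutral
    classification of the fitted models, and a ground-truthed synthetic
    community generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
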