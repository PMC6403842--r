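Package: loopex
Title: Chromatin Loop Extrusion Simulations with Knot and Demixing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained bead-spring molecular dynamics of ring chromatin
    fibres undergoing cohesin-mediated loop extrusion. Provides a Langevin
    integrator with selective (phantom, topoisomerase-like) excluded volume and
    spherical confinement, two extrusion mechanisms (an explicit two-ring
    cohesin handcuff walking along the fibre and a simplified migrating-bond
    extruder for large systems), knot identification of closed curves via
    geometric simplification and the Alexander polynomial, Gauss linking
    numbers for catenation, and Voronoi-tessellation interfacial-area metrics
    for chain demixing inside a confining sphere. Includes generators for
    knotted single-domain rings, a three-domain circular construct and a
    topologically equilibrated confined ring melt, plus pipelines that run the
    three corresponding in-silico experiments end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
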