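Package: magsep
Title: Magnetophoretic Flow Separation Modelling for Immunomagnetic Cell Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models flow-through immunomagnetic enrichment of magnetically
    labelled cells (such as circulating tumor cells) in a shallow laminar flow
    channel placed against a permanent-magnet array. Provides analytic 2D
    magnetostatics of rectangular magnets via the equivalent surface-charge
    model, builders for Halbach and alternating arrays, an arctangent
    effective-magnetization law for ferrofluid-labelled cells, overdamped
    force-balance trajectory integration with capture events, magnet-geometry
    optimization by recovery sweeps, recovery-versus-moment curves, and
    population-level recovery prediction from fluorescence-intensity
    histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    broom,
    optparse,
    withr
Config/testthat/edition: 3
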