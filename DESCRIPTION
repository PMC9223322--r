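Package: fibrenet
Title: Spatial Fibre Networks for Mapping Micro-Anatomical Reentry Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates regions of cardiac tissue that are structurally
    susceptible to micro-anatomical reentry. Builds spatial networks from
    voxel fibre-orientation fields via evenly spaced streamline tractography,
    couples nodes with a distance-dependent logistic attachment probability
    that emulates interstitial fibrosis, detects reentrant loops of at least
    one refractory wavelength with a discrete diffusion model backed by an
    exact graph-theoretic criterion, and summarises the result as global and
    local risk maps together with structural metrics (occupied voxel
    fraction, longitudinal connection fraction, spatial cluster counts and
    risk-weighted distributions). Includes seeded synthetic geometries (slabs,
    wedges, ridges, sleeves) emulating thin atrial walls, pectinate-muscle
    ridges and pulmonary-vein sleeves so the whole pipeline runs without
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    RNifti,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
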