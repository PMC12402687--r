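Package: axonmetrics
Title: Probabilistic Axonal Activation Metrics for Brain Stimulation
    Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models recruitment of white-matter fibres by deep brain
    stimulation at three levels of abstraction: electric field magnitude,
    electric field projection onto the fibre tangent, and pathway
    activation modelling with a McNeal-style myelinated-axon cable model
    driven by Frankenhaeuser-Huxley nodal kinetics.  Each metric is
    computed probabilistically (sigmoid conversion for the field metrics;
    repeated simulation over sampled fibre diameters for the axon model)
    and feeds group-level fibre-filtering statistics that contrast
    clinical outcomes between stimulations that do and do not recruit
    each fibre.  Includes an analytic point-source volume conductor,
    import of precomputed field grids, seeded synthetic fibre-atlas and
    cohort generators, and a scripted end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
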