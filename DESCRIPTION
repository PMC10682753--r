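Package: emforge
Title: Building, Optimizing and Generalizing Detailed Single-Neuron Electrical Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for data-driven biophysical single-neuron
    electrical models (e-models): electrophysiological feature extraction from
    voltage recordings with rheobase normalization and tolerance binning,
    multi-objective parameter optimization with an indicator-based
    evolutionary algorithm (IBEA) against Z-scored feature targets, somatic
    and dendritic validation (back-propagating action potential and EPSP
    attenuation with exponential fits), parameter sensitivity analysis,
    currentscape-style ionic current decomposition, and a generalization rule
    that gates an optimized e-model across a bank of morphologies. Ships a
    reduced multi-compartment Hodgkin-Huxley cable simulator (backward-Euler
    tree solver, deterministic and stochastic channel gating), an SWC
    morphology toolkit with axon replacement and clone generation, and
    synthetic-data generators that emulate patch-clamp recording sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
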