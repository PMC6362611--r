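Package: slabs
Title: Slab-Model Reflectometry with Bayesian Co-Refinement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Modelling and inference engine for specular neutron and X-ray
    reflectometry. Computes slab-model reflectivity by the Abeles
    transfer-matrix method with Nevot-Croce interfacial roughness and
    Gaussian instrument-resolution smearing (constant dQ/Q, point-by-point,
    or arbitrary kernel). Interfacial structures are assembled from
    composable components (uniform slabs, free-form splines, and a
    chemically parameterised lipid leaflet expressed through the area per
    molecule), and compared to measured curves through a Bayesian objective:
    box or distribution priors on named parameters, algebraic
    inter-parameter constraints, a Gaussian likelihood, least-squares
    optimisers, affine-invariant ensemble Markov chain Monte Carlo with
    optional parallel tempering, and co-refinement of multiple
    contrast-variation datasets with shared parameters. Includes a synthetic
    dataset generator so analyses and tests run without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    pracma,
    minpack.lm,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
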