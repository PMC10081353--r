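Package: jetmap
Title: Derivative-Preserving Mapping of Neuron Traces Through Nonlinear
    Transformations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps discretely sampled neuron morphologies (SWC traces) through
    nonlinear coordinate transformations while preserving derivative
    information, using the jet-space group action of diffeomorphisms. Knot
    positions are transformed by the map itself, first derivatives by its
    Jacobian, and second derivatives by a Hessian correction; transformed
    curves are reconstructed as first-order or cubic Hermite splines.
    Includes a priori error bounds for zeroth- and first-order mapping,
    discrete Frechet distance for curve comparison, gridded displacement
    field transforms with analytic trilinear Jacobians, and a synthetic
    generator of regular curves and guaranteed-diffeomorphic deformation
    fields for validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
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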