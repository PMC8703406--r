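Package: neurogeo
Title: Sub-Riemannian Geodesics in the Position-Orientation-Curvature Model
    of the Primary Visual Cortex
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Geodesic toolkit for the four-dimensional neurogeometric model
    of the primary visual cortex, M = R^2 x SO(2) x R, whose points encode
    planar position, local orientation and curvature of image contours.
    Provides the rank-2 control system and its bracket-generated frame
    (an Engel-type distribution with growth vector (2,3,4)), the normal
    and abnormal extremal flows obtained from the Pontryagin maximum
    principle with conserved-quantity monitoring, Poincare return-map
    experiments probing Liouville integrability of the reduced flow, a
    multi-start shooting solver for the two-point geodesic boundary-value
    problem, and completion of occluded planar contours via the planar
    projection of geodesics, together with synthetic occluded-contour
    fixtures, boundary-data estimation from sampled curves, CSV/JSON I/O
    and rendering.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
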