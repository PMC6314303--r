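Package: sphpatch
Title: Curved Spherical-Triangle Patches for Boundary-Element Electrostatics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Surface charge method machinery for curved areal elements on
    spheres: geodesic parametrization of great-arc spherical triangles,
    coordinate-free interpolation of vertex charge densities by central
    projection from the inscribed flat triangle, series evaluation of the
    electric field near a patch vertex with accuracy controlled in powers of
    arc length times curvature, exact patch areas and charge moments, moment
    expansions for on-sphere and exterior fields with convergence gating and
    an adaptive-quadrature oracle, and a demonstration dielectric-sphere
    boundary solve validated against the classical Legendre-series solution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
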