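# sphpatch

Curved spherical-triangle surface patches for boundary-element
electrostatics (the surface charge method).

## Why

Implicit-solvent electrostatics solvers represent dielectric polarization
as an induced charge density on the molecular surface and solve for it by
enforcing the interface boundary condition. Discretizing the surface with
flat triangles creates vertices where the surface normal is undefined and
the electric field of the discretized charge layer diverges — an
uncontrollable error source exactly where the boundary condition is
collocated. The spherical pieces of a molecular (solvent-excluded) surface
can instead be covered with *curved* triangles bounded by great arcs, which
lie exactly on the underlying sphere. `sphpatch` provides the complete
machinery for such patches:

- **Geometry** — canonical placement of a patch (`canonicalize()`) and the
  geodesic parametrization of its non-trivial side,
  cot θ = a·cos(φ − φ₀) (`geodesic_params()`, `beta_of_phi()`).
- **Density interpolation** — coordinate-free linear interpolation of the
  three vertex charge densities, carried onto the sphere by central
  projection from the inscribed flat triangle (`sigma_at()`); densities are
  continuous across shared mesh edges by construction.
- **Vertex field** — the normal electric field just above/below a patch
  vertex as a surface jump ±2πσ plus a continuous part, the latter either
  exactly (closed-form polar integral) or as a series in powers of
  β = (arc length × curvature) with selectable order 1/3/5/7
  (`ez_continuous()`, `ez_at_vertex()`). The order-3 error shrinks ~32× per
  halving of the patch size.
- **Patch moments** — exact area (equal to the Girard excess to 1e−12),
  exact direction averages and charge moments
  (`patch_area()`, `direction_average()`, `charge_moments()`).
- **Far field** — moment expansions of the on-sphere radial field and the
  exterior potential/field, gated by an explicit convergence criterion with
  an adaptive-quadrature fallback (`radial_field_on_sphere()`,
  `exterior_potential()`, `exterior_field()`, `expansion_converges()`).
- **Oracle** — deterministic iterated adaptive quadrature of the defining
  integrals, the package's source of truth (`potential_quadrature()` and
  relatives).
- **Demo solver** — induced surface charge on a dielectric sphere with an
  interior point charge, discretized with an icosphere of curved patches
  and validated against the classical Legendre-series solution
  (`assemble_and_solve()`, `legendre_induced_sigma()`).

Units are Gaussian with the sphere radius scaled to 1 (a uniformly charged
shell contributes 2πσ per side to the normal field).

## Worked example

The area of the symmetric patch with one vertex at the pole, both adjacent
arcs β = 0.15 and opening α = π/3, exactly and by the two- and three-term
series:

```r
library(sphpatch)
fr <- canonical_frame(beta2 = 0.15, beta3 = 0.15, alpha = pi/3)
g  <- geodesic_params(fr)
patch_area(fr, g)                                  # 0.009751830
patch_area(fr, g, method = "series", order = 4)    # 0.009749610
patch_area(fr, g, method = "series", order = 6)    # 0.009751868
```

The two-term series is already accurate to 2.2e−6 and the three-term to
3.8e−8 — the series control parameter is the side arc, here 0.15.

A patch with mixed vertex densities, and the field just above its pole
vertex:

```r
tri <- spherical_triangle(rbind(c(0, 0, 1),
                                c(sin(0.1), 0, cos(0.1)),
                                c(0, sin(0.1), cos(0.1))),
                          sigma = c(1, 0.9, 1.1))
ez_at_vertex(list(tri), vertex = 1, side = "above", order = 3)
#> <field evaluation> method = series (order 3)
#>   value: 6.345562697
#>   err_est: 0.00125  side: above
```

The value is the continuous series part (≈ 0.0624) plus the jump 2πσ₁; the
above-minus-below difference is exactly 4πσ₁.

The demonstration boundary solve (unit charge at 0.5 R inside a sphere
with ε_in = 1, ε_out = 80, icosphere level 2):

```r
sol <- assemble_and_solve(dielectric_scene(1, 80, 1, c(0, 0, 0.5), level = 2))
sol$total_induced      # -0.98780   (Gauss sum rule: 1/80 - 1 = -0.98750)
scm_l2_error(sol)      # 0.0034    (relative L2 vs the Legendre series)
```

## Scope

Toroidal surface elements, triangles with a non-great-arc side (the
junction curves of molecular surfaces), and the construction of molecular
surfaces from atom coordinates are out of scope; see the vignette
(`vignettes/curved-patches.Rmd`) for the method description, numerical
conventions and limitations.
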