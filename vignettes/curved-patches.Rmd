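---
title: "Curved spherical-triangle patches for the surface charge method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curved spherical-triangle patches for the surface charge method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sphpatch)
```

## The problem

Boundary-element treatments of implicit-solvent electrostatics represent the
dielectric response of a molecular solute as an induced surface charge
density on the dielectric interface and solve for it by enforcing the
interface boundary condition.  The molecular (solvent-excluded) surface is
made of spherical and toroidal pieces, and the standard discretization into
flat triangles has a well-known defect: at the triangle vertices the
approximate surface has no normal direction and the electric field of the
discretized charge layer diverges.  Curved elements that lie exactly on the
underlying sphere remove this artifact, at the price of making the charge
integrals over each element harder.

`sphpatch` implements that machinery for great-arc spherical triangles (the
spherical pieces of a molecular surface): exact geometry, a coordinate-free
density interpolation, field evaluation near and far from a patch with
accuracy controlled by a single small parameter — the side arc length times
the surface curvature, written `beta` below (radians on the unit sphere) —
and a demonstration boundary solve.  Everything is expressed in Gaussian
units on a unit sphere; a patch on a sphere of radius R scales potentials by
R and charges by R^2, while fields in units of the density are unchanged.

## Geometry: canonical frame and the geodesic side

A patch is fixed by three unit vertex directions.  `canonicalize()` rotates
the chosen vertex to the north pole, the second vertex to azimuth 0 (polar
angle `beta3`) and the third to azimuth `alpha` (polar angle `beta2`), with
`0 < alpha < pi` enforced by relabeling the two non-pole vertices when the
raw winding gives the reflex opening (densities are permuted consistently
and the permutation is reported).  The only non-trivial side, the great arc
opposite the pole, obeys

    cot(theta) = a cos(phi - phi0),

and `geodesic_params()` recovers `a` and `phi0` from the two boundary
conditions in the component form `(a cos phi0, a sin phi0)`, which remains
well-behaved when a side arc equals pi/2.  When both non-pole arcs are pi/2
the opposite side is the equator, `a = 0`, and `phi0` is unidentifiable; it
is set to 0 by convention (the side is `beta(phi) = pi/2` regardless).  The
arc length `beta1` of that side has a two-arctangent closed form that the
package cross-checks against the spherical law of cosines; the identity
`sqrt(1 + a^2) sin(alpha) sin(beta2) sin(beta3) = sin(beta1)` is used to
simplify several closed forms and is verified to 1e-10 in the test suite
over a thousand random triangles before anything relies on it.

## Density interpolation by central projection

Vertex densities are interpolated linearly on the flat triangle through the
three vertices and carried to the spherical patch by central (radial)
projection.  At azimuth `phi`, the meridian half-plane cuts the flat chord
between the two non-pole vertices at fraction `lambda(phi)` and depth
`delta(phi)/R` below the sphere; a surface point at polar angle `theta`
projects to the fraction `t(theta) = sin(theta)/(C sin(theta) + D
cos(theta))` of the way from the pole to the chord, with

    C(phi) = (1 - cos beta) + (delta/R) cos beta   (order beta^2)
    D(phi) = (1 - delta/R) sin beta                (order beta)

evaluated at `beta = beta(phi)`.  The interpolated density is then
`sigma = (1 - t) sigma1 + t[(1 - lambda) sigma2 + lambda sigma3]`.  Two
properties matter in practice and are enforced by tests: on a shared edge
the value depends only on the two shared vertex densities (so densities are
continuous across a mesh), and the flat-triangle centroid receives the mean
of the three vertex values.  All formulas are evaluated in sine/cosine form;
the tangent forms familiar from the derivation have poles at `phi = pi/2`
that the implementation never touches.

One degeneracy deserves note: the order-1 combination `h = zeta23 lambda (1
- lambda) a^2 cos^2(phi - phi0)` (with `zeta23 = 1 - cos beta1` the chord
deficit) divides by `a^2`.  The implementation stores the product `zeta23
lambda (1 - lambda)` and reconstructs `h` only inside series formulas, which
are refused for large patches anyway (they take the quadrature path).

## Field at a patch vertex

The normal field at a point just above or below a vertex separates into a
surface discontinuity `+-2 pi sigma_vertex` and a continuous part, the
regularized integral of `sigma(theta, phi) cos(theta/2)/2` over the patch
(the identity `sin(theta)/sqrt(1 - cos(theta)) = sqrt(2) cos(theta/2)`
removes the apparent pole exactly).  `ez_at_vertex()` sums the continuous
parts of all patches meeting at the vertex and adds the jump; the
above-minus-below difference is `4 pi sigma_vertex` identically, which the
suite verifies to machine precision on 100 random fixtures.  For a single
corner patch in isolation, the physical two-sided limit differs by the
patch's azimuthal fraction of the jump; the `+-2 pi sigma` bookkeeping is a
property of the complete fan of patches surrounding a vertex, which is how
the solver uses it.

The continuous part is evaluated two ways:

* **Exact polar integral** (`ez_theta_integral_exact()`): the t-weighted
  kernel integral has a closed form obtained by the substitutions
  `u = sqrt(1 -+ cos theta)`, which reduce it to rational integrals; it is
  valid while `eta cos(beta) > 1` with `eta^2 = (C^2 + D^2)/C^2`, a
  condition every series-regime patch satisfies, and it agrees with
  adaptive quadrature to ~1e-11 relative.
* **Series in beta** (`ez_continuous()`): the kernel is expanded in powers
  of `1/(a cos(phi - phi0))` (order beta), and each azimuthal integral
  becomes a member of the F/G family below.  `order = r` retains every term
  of total order `beta^r`.

A subtlety in the order counting: if neighbouring vertex densities differ
by O(beta), as they do for a smooth charge distribution sampled on a fine
mesh, some O(beta^3) terms carry an extra power of beta and could be
dropped from the order-3 result.  `ez_continuous()` does **not** assume
this: it keeps all geometric O(beta^3) terms, so the stated order holds for
arbitrary density triples.  The measured error of the order-3 value falls
by a factor ~32 per halving of the patch scale (a beta^5 remainder), and
orders 5 and 7 fall by ~130 and ~520, matching their beta^7 and beta^9
remainders — this scaling test is how every garbled-looking expansion
coefficient in the implementation was confirmed against the quadrature
oracle.

## The F/G integral family and truncation rule

All series results reduce to integrals

    F[nc,ns](l,d,p) = int_0^alpha h^l lambda^d cos^nc(phi) sin^ns(phi)
                      / (a cos(phi - phi0))^p dphi,

of order beta^p.  Substituting `x = tan(phi/2)` makes every integrand
rational; expanding in the order-beta^2 difference `tau' - tau` (two nearby
tangent-like parameters of the substitution) yields the terms
`G[nc,ns](l,d,k,p)`, of order `beta^(p+2k)`, with `F = sum_k G`.  For
`l = d = 0` the `k = 0` term is exact.  The truncation rule for a target
order `r` is `k <= floor((r - p)/2)`: at order 5, `p = 5` integrals need
only `k = 0`, `p = 3` need `k <= 1`, `p = 1` need `k <= 2`.  The G
integrals are evaluated by adaptive Gauss–Kronrod quadrature of the
rational integrand (relative tolerance 1e-12, absolute 1e-15); exact
partial-fraction antiderivatives would be an equivalent optimization behind
the same interface, since the integrands are smooth rational functions on a
closed interval where the denominator `1 - x^2 + 2 tau x` is provably
bounded away from zero.

## Exact areas and charge moments

The patch area has the closed form `A = alpha - atan(tan(alpha - phi0)
cos beta2) - atan(tan(phi0) cos beta3)`; the implementation uses the
equivalent `a`-based form, which is regular for equatorial sides, and
verifies it against the Girard spherical excess (vertex-angle sum minus pi)
to 1e-12 on 500 random triangles.  The area-averaged direction `(t_x, t_y,
t_z)` likewise has exact closed forms built from the side arcs and `beta1`.
Charge moments — total charge `q0`, first moments `m1` and second moments
`m2` of the interpolated density, the coefficients of both far-field
expansions — are computed three ways (`charge_moments(method = ...)`):

* `"exact"`: the polar integral at fixed azimuth is elementary once written
  in the shifted angle `psi = theta + atan2(D, C)`, where the projection
  denominator is a pure sine.  The implementation uses a stable recursion
  whose multiplier is `C/D = O(beta)`, then integrates adaptively over
  azimuth.  Agreement with the 2-D quadrature oracle is ~1e-14 absolute.
* `"series"`: G-combinations carrying the leading term and its
  relative-beta^2 correction; the dropped terms are O(beta^6), confirmed by
  the ~64x-per-halving convergence test.  The sign and coefficients of
  every combination were fixed against the exact polar integrals, since
  several are easy to get wrong by transcription.
* `"quadrature"`: the oracle.

`trace(m2) = q0` holds identically (unit position vectors) and is asserted
on every fixture.

## Far-field evaluation and its convergence gate

For an evaluation direction on the same sphere, outside the closed patch,
the radial field is `(1/2) int sigma / sqrt(2 - 2 cos gamma) dA` with
`gamma` the angular separation — exactly half the on-sphere potential, an
identity the tests assert at 1e-10.  Expanding the kernel about the
patch's average direction turns it into a three-term expression in the
moments.  The expansion is trustworthy when

    1 - dot(rhat_eval, (v1 + v2 + v3)/3) > 2 [1 - min pairwise vertex dot],

(`expansion_converges()`, which also reports the margin).  The analogous
exterior expansion about the average position handles points off the
sphere, with the analytic gradient supplying the field.  `method = "auto"`
uses the expansion only when the criterion passes and the patch is in the
series regime (on-sphere), or when the point is farther than twice the
patch diameter from the expansion centre (exterior); otherwise the
iterated adaptive quadrature oracle is used.  Evaluation directions within
arc 1e-3 of the patch boundary are refused: the kernel is integrably
singular there but quadrature accuracy degrades, and boundary-layer values
at a vertex are `ez_at_vertex()`'s job.

## The quadrature oracle

`potential_quadrature()` and relatives integrate the defining kernels by an
iterated adaptive rule (azimuth outermost, polar tolerance 10x tighter),
deterministic for a fixed `quadrature_spec()` (defaults: relative 1e-10,
absolute 1e-14, 400 subdivisions).  A tolerance failure is flagged in the
result, never silent.  Two structural checks: splitting a patch at the
great-arc edge midpoints leaves quadrature sums unchanged to 1e-9 for a
uniform density (an exact geometric partition); with vertex densities
re-interpolated from the parent at the midpoints, the parent and child
interpolants use different flat-triangle planes and differ in the interior
at O(beta^4 x density gradient) — about 3e-5 relative at arcs of 0.25.
This is a property of the interpolation scheme, not an integration error,
and it is the reason refining a mesh changes interpolated densities at
higher order even with exact vertex values.

## Demonstration boundary solve

`assemble_and_solve()` computes the induced surface charge on a dielectric
sphere (permittivity `eps_in` inside, `eps_out` outside) containing a point
charge.  Representing the potential as the source term `q/(eps_in r)` plus
the single-layer potential of the induced density and enforcing continuity
of the normal displacement gives the collocation system

    sigma_j = f E_c(vertex_j),   f = (eps_in - eps_out) /
                                     (2 pi (eps_in + eps_out)),

with `E_c` the continuous normal field (source plus all patches).  Matrix
elements exercise the full evaluation hierarchy: series vertex fields for
patches containing the collocation vertex (Gauss quadrature of the
regularized kernel when a coarse mesh exceeds the series regime), the
moment expansion where its criterion passes, and fixed 12x12 Gauss
quadrature of the bounded kernel in the remaining near zone.  The mesh is
a subdivided icosahedron whose faces are exact spherical triangles (edge
midpoints re-projected), `20 * 4^level` of them summing to the full 4 pi.

The solution is validated against the classical axially-symmetric series
solution (`legendre_induced_sigma()`, 50 Legendre terms).  For `eps_in = 1`,
`eps_out = 80`, a unit charge at 0.5 R on the axis, the area-weighted
relative L2 error of the vertex densities is about 0.95%, 0.34% and 0.097%
at levels 1, 2 and 3 (80, 320, 1280 faces), decreasing monotonically; the
total induced charge matches the Gauss sum rule `q (1/eps_out - 1/eps_in)`
to a fraction of a percent, and for a central charge the density is uniform
to ~1e-4 relative.  A dense direct solve is used; at level 3 the system has
642 unknowns and assembles in well under a minute on one core.

## Fixtures: what they emulate, what they do not

`generate_fixtures()` produces random valid patches with all three side
arcs in a configurable range (default [0.02, 0.3] radians — the series
regime), uniformly random orientation, and uniform random vertex densities.
These resemble the spherical elements of a finely meshed molecular surface
in size and shape diversity, but not in two respects: real surfaces also
contain toroidal elements and elements bounded by non-great-arc junction
curves (out of scope here), and real induced densities are smooth, so
neighbouring vertex values differ by O(beta) rather than O(1).  Passing
tests on these fixtures therefore demonstrates correctness of the patch
machinery under harsher density variation than a production solve would
encounter, but says nothing about toroidal geometry or surface-singularity
handling.

## Numerical conventions and limitations

* Angles in radians; absolute tolerance 1e-12 on angle comparisons, 1e-10
  on identities that involve cancellation.
* Series mode requires all side arcs <= `beta_max` (default 0.35 rad);
  larger patches are served by quadrature, and `ez_continuous()` refuses
  them explicitly rather than degrade.
* Every closed form in the package is validated in the test suite against
  an independent numerical oracle (adaptive quadrature of the defining
  integral, the Girard excess, finite differences, or the Legendre series);
  convergence-order scaling tests guard the series coefficients.
* Problem sizes in the default test run are chosen to keep the full suite
  within a few minutes on one core: 500-fixture sweeps for the closed-form
  moment checks, 100-200 fixtures for property sweeps, icosphere levels 1-3
  for the boundary solve.
* Out of scope: toroidal patches, triangles with a non-great-arc side,
  construction of molecular surfaces from atom coordinates, evaluation at
  points strictly inside the sphere, and tangential field components at a
  vertex.
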