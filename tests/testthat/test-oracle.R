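test_that("potential quadrature is linear in the vertex densities and zero for zero density", {
  tri <- mk_tri(0.2, 0.15, 0.9)
  pr <- fg(tri)
  pt <- c(1.5, 0.4, 1.2)
  expect_identical(potential_quadrature(pt, pr$fr, pr$g,
                                        sigma = c(0, 0, 0))$value, 0)
  full <- potential_quadrature(pt, pr$fr, pr$g, sigma = c(1, 2, 3))$value
  parts <- vapply(list(c(1, 0, 0), c(0, 2, 0), c(0, 0, 3)), function(s)
    potential_quadrature(pt, pr$fr, pr$g, sigma = s)$value, numeric(1))
  expect_equal(full, sum(parts), tolerance = 1e-12 * abs(full))
})

test_that("a polar fan of patches reproduces the axial cap potential", {
  # N apex-at-pole triangles approximate the cap; compare with the 1-D cap
  # closed form at an axial exterior point, to the polygonal-rim error
  N <- 40; beta <- 0.3; sig <- 1; z <- 2
  ring <- function(j) {
    ph <- 2 * pi * j / N
    c(sin(beta) * cos(ph), sin(beta) * sin(ph), cos(beta))
  }
  tot <- sum(vapply(seq_len(N) - 1, function(j) {
    tri <- spherical_triangle(rbind(c(0, 0, 1), ring(j), ring(j + 1)),
                              sigma = c(sig, sig, sig))
    pr <- fg(tri)
    potential_quadrature(as.numeric(pr$fr$rotation %*% c(0, 0, z)),
                         pr$fr, pr$g)$value
  }, numeric(1)))
  cap <- 2 * pi * sig * integrate(function(th)
    sin(th) / sqrt(z^2 + 1 - 2 * z * cos(th)), 0, beta,
    rel.tol = 1e-12)$value
  expect_equal(tot, cap, tolerance = cap * (2 * pi / N)^2)
})

test_that("field quadrature matches central differences of the potential", {
  tri <- mk_tri(0.18, 0.12, 1.0, sigma = c(1, 0.7, 1.3))
  pr <- fg(tri)
  pt <- c(0.9, 0.5, 1.4)
  ef <- field_quadrature(pt, pr$fr, pr$g)$value
  h <- 1e-5
  fd <- vapply(1:3, function(i) {
    e <- rep(0, 3); e[i] <- h
    -(potential_quadrature(pt + e, pr$fr, pr$g)$value -
        potential_quadrature(pt - e, pr$fr, pr$g)$value) / (2 * h)
  }, numeric(1))
  expect_equal(ef, fd, tolerance = 1e-7)
  expect_equal(field_quadrature(pt, pr$fr, pr$g,
                                sigma = c(0, 0, 0))$value, c(0, 0, 0))
})

test_that("the vertex-limit jump emerges from the field quadrature as eps -> 0", {
  # a single corner patch contributes only its azimuthal fraction of the
  # jump; a complete fan around the vertex restores the full 4 pi sigma
  N <- 6; beta <- 0.25; sig <- 0.6
  ring <- function(j) {
    ph <- 2 * pi * j / N
    c(sin(beta) * cos(ph), sin(beta) * sin(ph), cos(beta))
  }
  fan <- lapply(seq_len(N) - 1, function(j)
    fg(spherical_triangle(rbind(c(0, 0, 1), ring(j), ring(j + 1)),
                          sigma = c(sig, sig, sig))))
  ez_at <- function(eps) sum(vapply(fan, function(pr)
    field_quadrature(as.numeric(pr$fr$rotation %*% c(0, 0, 1 + eps)),
                     pr$fr, pr$g)$value[3], numeric(1)))
  up <- 2 * ez_at(1e-4) - ez_at(2e-4)
  dn <- 2 * ez_at(-1e-4) - ez_at(-2e-4)
  expect_equal(up - dn, 4 * pi * sig, tolerance = 1e-2)
})

test_that("splitting a patch into four leaves quadrature sums unchanged", {
  tri <- mk_tri(0.25, 0.2, 0.9, sigma = c(1, 1, 1))
  V <- tri$vertices
  m12 <- arc_mid(V[1, ], V[2, ]); m23 <- arc_mid(V[2, ], V[3, ])
  m13 <- arc_mid(V[1, ], V[3, ])
  mk <- function(vv, sg) spherical_triangle(vv, sigma = sg)
  pt <- c(2, 0.5, 1.5)
  pot <- function(t3) {
    pr <- fg(t3)
    potential_quadrature(as.numeric(pr$fr$rotation %*% pt), pr$fr, pr$g)$value
  }
  # uniform density: geometric additivity is exact
  subs_u <- list(mk(rbind(V[1, ], m12, m13), c(1, 1, 1)),
                 mk(rbind(V[2, ], m23, m12), c(1, 1, 1)),
                 mk(rbind(V[3, ], m13, m23), c(1, 1, 1)),
                 mk(rbind(m12, m23, m13), c(1, 1, 1)))
  expect_equal(sum(vapply(subs_u, pot, numeric(1))), pot(tri),
               tolerance = 1e-9)

  # re-interpolated varying density: the parent and child projections use
  # different flat-triangle planes, so the interpolants differ in the
  # interior at O(beta^4 x density gradient)
  tri_v <- mk_tri(0.25, 0.2, 0.9, sigma = c(1, 0.8, 1.2))
  pr <- fg(tri_v)
  sig_w <- function(p) {
    pc <- as.numeric(pr$fr$rotation %*% p)
    sigma_at(acos(max(-1, min(1, pc[3]))), atan2(pc[2], pc[1]), pr$fr, pr$g)
  }
  s12 <- sig_w(m12); s23 <- sig_w(m23); s13 <- sig_w(m13)
  subs_v <- list(mk(rbind(V[1, ], m12, m13), c(1, s12, s13)),
                 mk(rbind(V[2, ], m23, m12), c(0.8, s23, s12)),
                 mk(rbind(V[3, ], m13, m23), c(1.2, s13, s23)),
                 mk(rbind(m12, m23, m13), c(s12, s23, s13)))
  parent <- pot(tri_v)
  expect_equal(sum(vapply(subs_v, pot, numeric(1))), parent,
               tolerance = 1e-4)
})

test_that("unreachable tolerances are flagged, never silent", {
  tri <- mk_tri(0.2, 0.15, 0.9, sigma = c(1, 1, 1))
  pr <- fg(tri)
  # a point extremely close to the patch surface strains the inner rule
  near_pt <- c(sin(0.05) * cos(0.2), sin(0.05) * sin(0.2), cos(0.05)) * 1.0000001
  res <- potential_quadrature(near_pt, pr$fr, pr$g,
                              spec = quadrature_spec(rel_tol = 1e-13,
                                                     abs_tol = 1e-16,
                                                     max_subdivisions = 12))
  expect_true(is.finite(res$value))
  expect_true(res$flagged)
})
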