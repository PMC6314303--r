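test_that("cap field reproduces the Gauss-law limits and the on-axis quadrature", {
  # full shell: 4 pi sigma outside, 0 inside
  expect_equal(cap_axial_field(pi, "above", 2), 8 * pi, tolerance = 1e-14)
  expect_equal(cap_axial_field(pi, "below", 2), 0, tolerance = 1e-14)
  # beta = pi/3 cap: 1-D quadrature at small eps/R, Richardson to eps -> 0.
  # The integrand spikes over a width ~ eps near theta = 0; the spike is
  # integrated in the stretched variable theta = eps u
  ez_eps <- function(eps) {
    s <- 1 / (1 + eps)
    f <- function(th)
      sin(th) * (1 - s * cos(th)) / (1 + s^2 - 2 * s * cos(th))^1.5
    spike <- integrate(function(u) f(eps * u) * eps, 0, 1000,
                       rel.tol = 1e-7)$value
    rest <- integrate(f, 1000 * eps, pi / 3, rel.tol = 1e-9)$value
    2 * pi * s^2 * (spike + rest)
  }
  e1 <- ez_eps(1e-5); e2 <- ez_eps(2e-5)
  richardson <- 2 * e1 - e2
  expect_equal(cap_axial_field(pi / 3, "above"), richardson,
               tolerance = 1e-6)
})

test_that("theta-kernel regularization identity is exact on a grid", {
  # away from theta = 0, where the unregularized left side itself loses
  # precision to the 1 - cos(theta) cancellation
  th <- seq(0.05, pi - 1e-6, length.out = 500)
  expect_equal(sin(th) / sqrt(1 - cos(th)), sqrt(2) * cos(th / 2),
               tolerance = 1e-11)
})

test_that("exact theta-integral of the vertex kernel matches quadrature on fixtures", {
  fx <- generate_fixtures(fixture_spec(seed = 41, n = 50,
                                       arc_range = c(0.02, 0.35)))
  for (tri in fx) {
    fr <- canonicalize(tri)
    g <- geodesic_params(fr)
    phi <- runif(1, 1e-3, fr$alpha - 1e-3)
    co <- interp_coefficients(phi, fr, g)
    q <- integrate(function(th) cos(th / 2) / 2 * t_of_theta(th, co$C, co$D),
                   0, co$beta, rel.tol = 1e-12, abs.tol = 1e-16)$value
    expect_equal(ez_theta_integral_exact(phi, fr, g), q,
                 tolerance = 1e-10)
  }
})

test_that("continuous vertex field vanishes for zero density and refuses large patches", {
  fr <- canonical_frame(0.1, 0.1, pi / 3, sigma = c(0, 0, 0))
  g <- geodesic_params(fr)
  expect_identical(ez_continuous(fr, g)$value, 0)
  fr_big <- canonical_frame(0.6, 0.6, 1.0, sigma = c(1, 1, 1))
  expect_error(ez_continuous(fr_big, geodesic_params(fr_big)),
               "too large")
})

test_that("series vertex field agrees with the 2-D quadrature oracle at its stated order", {
  fr <- canonical_frame(0.1, 0.1, pi / 3, sigma = c(1, 1, 1))
  g <- geodesic_params(fr)
  q <- ez_pole_quadrature(fr, g, spec = quadrature_spec(rel_tol = 1e-12))
  e3 <- ez_continuous(fr, g, order = 3)$value
  expect_lt(abs(e3 - q$value) / abs(q$value), 0.1^3)
  # arcs <= 0.15: order 3 within 1 percent; arcs <= 0.05 within 0.1 percent
  for (cfg in list(c(0.15, 1e-2), c(0.05, 1e-3))) {
    fr <- canonical_frame(cfg[1], cfg[1] * 0.8, 0.9,
                          sigma = c(1, 0.9, 1.1))
    g <- geodesic_params(fr)
    q <- ez_pole_quadrature(fr, g, spec = quadrature_spec(rel_tol = 1e-12))
    e3 <- ez_continuous(fr, g, order = 3)$value
    expect_lt(abs(e3 - q$value) / abs(q$value), cfg[2])
  }
})

test_that("series error decreases by at least a factor 8 per halving of the patch scale", {
  sig <- c(1, 0.9, 1.1)
  errs <- vapply(c(0.2, 0.1, 0.05), function(sc) {
    s <- sc / 0.2
    fr <- canonical_frame(0.22 * s, 0.13 * s, 1.0, sigma = sig)
    g <- geodesic_params(fr)
    q <- ez_pole_quadrature(fr, g, spec = quadrature_spec(rel_tol = 1e-12))
    abs(ez_continuous(fr, g, order = 3)$value - q$value)
  }, numeric(1))
  expect_gte(errs[1] / errs[2], 8)
  expect_gte(errs[2] / errs[3], 8)
})

test_that("higher series orders converge at their expected rates", {
  sig <- c(1, 0.8, 1.2)
  err <- function(order, sc) {
    s <- sc / 0.2
    fr <- canonical_frame(0.2 * s, 0.16 * s, 0.9, sigma = sig)
    g <- geodesic_params(fr)
    q <- ez_pole_quadrature(fr, g, spec = quadrature_spec(rel_tol = 1e-13))
    abs(ez_continuous(fr, g, order = order)$value - q$value)
  }
  # order 5: ~beta^7 error -> factor ~128 per halving (allow margin)
  expect_gte(err(5, 0.2) / err(5, 0.1), 64)
  # order 1: ~beta^3 error -> factor ~8
  expect_gte(err(1, 0.2) / err(1, 0.1), 6)
})

test_that("the field jump across the surface is 4 pi sigma_vertex for any patch shape", {
  fx <- generate_fixtures(fixture_spec(seed = 42, n = 100,
                                       arc_range = c(0.03, 0.3)))
  for (tri in fx) {
    v1 <- tri$vertices[1, ]
    up <- ez_at_vertex(list(tri), v1, side = "above")$value
    dn <- ez_at_vertex(list(tri), v1, side = "below")$value
    expect_equal(up - dn, 4 * pi * tri$sigma[1], tolerance = 1e-12)
  }
})

test_that("zero vertex density makes above and below fields coincide", {
  tri <- mk_tri(0.2, 0.15, 0.9, sigma = c(0, 1, -1))
  up <- ez_at_vertex(list(tri), 1L, side = "above")$value
  dn <- ez_at_vertex(list(tri), 1L, side = "below")$value
  expect_identical(up, dn)
})

test_that("a fan of triangles around the pole reproduces the cap field", {
  # N congruent triangles with apex at the pole and base vertices on the
  # circle theta = beta: their union approximates the spherical cap (the
  # rim is polygonal, so agreement is to the rim-sagitta error)
  N <- 24; beta <- 0.25; sig <- 0.8
  ring <- function(j) {
    ph <- 2 * pi * j / N
    c(sin(beta) * cos(ph), sin(beta) * sin(ph), cos(beta))
  }
  patches <- lapply(seq_len(N) - 1, function(j)
    spherical_triangle(rbind(c(0, 0, 1), ring(j), ring(j + 1)),
                       sigma = c(sig, sig, sig)))
  fe <- ez_at_vertex(patches, c(0, 0, 1), side = "above", order = 5)
  cap <- cap_axial_field(beta, "above", sig)
  # continuous parts differ by the polygonal-rim mismatch ~ (2 pi / N)^2
  expect_lt(abs(fe$value - cap),
            2 * pi * sig * sin(beta / 2) * (2 * pi / N)^2)
  # series sum vs quadrature sum: tight agreement
  tot_q <- sum(vapply(patches, function(p) {
    pr <- fg(p)
    ez_pole_quadrature(pr$fr, pr$g)$value
  }, numeric(1))) + 2 * pi * sig
  expect_equal(fe$value, tot_q, tolerance = 1e-5)
})

test_that("inconsistent shared-vertex densities are rejected", {
  t1 <- mk_tri(0.2, 0.15, 0.9, sigma = c(1, 0, 0))
  t2 <- mk_tri(0.2, 0.15, 0.9, sigma = c(2, 0, 0))
  expect_error(ez_at_vertex(list(t1, t2), c(0, 0, 1), side = "above"),
               "[Ii]nconsistent")
})
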