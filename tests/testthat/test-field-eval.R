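test_that("convergence criterion behaves at its limiting cases", {
  tri <- mk_tri(0.02, 0.02, pi / 3)
  ctr <- colMeans(tri$vertices); ctr <- ctr / sqrt(sum(ctr^2))
  far <- expansion_converges(-ctr, tri)
  expect_true(far$ok)
  expect_gt(far$margin, 1.9)
  near <- expansion_converges(ctr, tri)
  expect_false(near$ok)
  # at arc distance ~3 patch diameters: direct inequality evaluation
  diam <- acos(min(tri$vertices %*% t(tri$vertices)))
  d3 <- c(sin(3 * diam), 0, cos(3 * diam))
  ref_lhs <- 1 - sum(d3 * colMeans(tri$vertices))
  ref_rhs <- 2 * (1 - min(tri$vertices %*% t(tri$vertices)))
  expect_identical(expansion_converges(d3, tri)$ok, ref_lhs > ref_rhs)
})

test_that("on-sphere radial field approaches the point-charge closed form for shrinking patches", {
  d <- c(sin(1.1), 0, cos(1.1))
  rel <- vapply(c(0.04, 0.02, 0.01), function(b) {
    tri <- mk_tri(b, b, pi / 3, sigma = c(1, 1, 1))
    pr <- fg(tri)
    mom <- moments_to_world(charge_moments(pr$fr, pr$g), pr$fr)
    rc <- mom$t / sqrt(sum(mom$t^2))
    pred <- mom$q0 / (2 * sqrt(2 - 2 * sum(d * rc)))
    abs(radial_field_on_sphere(d, tri, method = "quadrature")$value / pred - 1)
  }, numeric(1))
  expect_true(all(diff(rel) < 0))
  # deviation shrinks at least linearly in the diameter
  expect_gte(log(rel[1] / rel[3]) / log(4), 1)
  # antipodal point: q_t / 4 within 0.1 percent at arc 0.01
  tri <- mk_tri(0.01, 0.01, pi / 3, sigma = c(1, 1, 1))
  pr <- fg(tri)
  mom <- moments_to_world(charge_moments(pr$fr, pr$g), pr$fr)
  rc <- mom$t / sqrt(sum(mom$t^2))
  fa <- radial_field_on_sphere(-rc, tri, method = "quadrature")$value
  expect_lt(abs(fa / (mom$q0 / 4) - 1), 1e-3)
})

test_that("moment expansion matches quadrature within 1 percent when the margin is comfortable", {
  set.seed(61)
  for (i in 1:15) {
    tri <- mk_tri(runif(1, 0.05, 0.12), runif(1, 0.05, 0.12),
                  runif(1, 0.5, 1.5), sigma = runif(3, 0.5, 1.5),
                  rot = rand_rotation())
    # direction at a random comfortable separation
    repeat {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      cv <- expansion_converges(u, tri)
      if (cv$ok && cv$margin > 0.5) break
    }
    fe <- radial_field_on_sphere(u, tri, method = "expansion")$value
    fq <- radial_field_on_sphere(u, tri, method = "quadrature")$value
    expect_lt(abs(fe - fq) / abs(fq), 0.01)
  }
})

test_that("evaluation inside or near the patch boundary is refused", {
  tri <- mk_tri(0.2, 0.2, 1.0, sigma = c(1, 1, 1))
  inside <- colMeans(tri$vertices); inside <- inside / sqrt(sum(inside^2))
  expect_error(radial_field_on_sphere(inside, tri), "inside|boundary")
  expect_error(radial_field_on_sphere(tri$vertices[1, ], tri),
               "inside|boundary")
})

test_that("on-sphere kernel is half the potential kernel for every fixture", {
  fx <- generate_fixtures(fixture_spec(seed = 62, n = 20))
  for (tri in fx) {
    pr <- fg(tri)
    repeat {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      uc <- as.numeric(pr$fr$rotation %*% u)
      loc <- sphpatch:::patch_arc_location(uc, frame_vertices(pr$fr))
      if (!loc$inside && loc$boundary_distance > 0.1) break
    }
    er <- radial_field_quadrature(uc, pr$fr, pr$g)$value
    pot <- potential_quadrature(uc, pr$fr, pr$g)$value
    expect_equal(er, pot / 2, tolerance = 1e-10 * max(1, abs(pot)))
  }
})

test_that("exterior potential has the monopole far limit and matches quadrature at 3R", {
  tri <- mk_tri(0.1, 0.15, 0.9, sigma = c(1, 0.8, 1.2))
  pr <- fg(tri)
  mom <- moments_to_world(charge_moments(pr$fr, pr$g), pr$fr)
  q0 <- mom$q0
  pfar <- 1000 * c(0.3, -0.5, 0.81) / sqrt(sum(c(0.3, -0.5, 0.81)^2))
  # monopole about the patch's average position
  pred <- q0 / sqrt(sum((pfar - as.numeric(mom$t))^2))
  expect_equal(exterior_potential(pfar, tri)$value, pred, tolerance = 1e-5)
  p3 <- 3 * c(0.3, -0.5, 0.81) / sqrt(sum(c(0.3, -0.5, 0.81)^2))
  pe <- exterior_potential(p3, tri, method = "expansion")$value
  pq <- exterior_potential(p3, tri, method = "quadrature")$value
  expect_lt(abs(pe - pq) / abs(pq), 5e-3)
  expect_error(exterior_potential(c(0.1, 0.2, 0.3), tri), "outside")
})

test_that("exterior potential is equivariant under joint rotation of patch and point", {
  set.seed(63)
  R <- rand_rotation()
  tri <- mk_tri(0.12, 0.1, 0.8, sigma = c(1, 1, 1))
  tri_r <- spherical_triangle(t(R %*% t(tri$vertices)), sigma = tri$sigma)
  p <- c(1.2, -0.7, 2.1)
  v1 <- exterior_potential(p, tri, method = "expansion")$value
  v2 <- exterior_potential(as.numeric(R %*% p), tri_r,
                           method = "expansion")$value
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("exterior field is the negative gradient of the exterior potential", {
  tri <- mk_tri(0.1, 0.15, 0.9, sigma = c(1, 0.8, 1.2))
  p5 <- 5 * c(0.2, 0.4, 0.89) / sqrt(sum(c(0.2, 0.4, 0.89)^2))
  ef <- exterior_field(p5, tri, method = "expansion")$value
  h <- 1e-5
  fd <- vapply(1:3, function(i) {
    e <- rep(0, 3); e[i] <- h
    -(exterior_potential(p5 + e, tri, method = "expansion")$value -
        exterior_potential(p5 - e, tri, method = "expansion")$value) / (2 * h)
  }, numeric(1))
  expect_equal(ef, fd, tolerance = 1e-6)
  # monopole far limit of the field, about the patch's average position
  pr <- fg(tri)
  mom <- moments_to_world(charge_moments(pr$fr, pr$g), pr$fr)
  pfar <- 1000 * c(0, 0, 1)
  dfar <- pfar - as.numeric(mom$t)
  pred <- mom$q0 * dfar / sum(dfar^2)^1.5
  expect_equal(exterior_field(pfar, tri)$value, pred, tolerance = 1e-5)
  # zero density gives a zero vector
  tri0 <- mk_tri(0.1, 0.15, 0.9, sigma = c(0, 0, 0))
  expect_equal(exterior_field(p5, tri0, method = "expansion")$value,
               c(0, 0, 0))
})

test_that("exterior field from expansion agrees with the quadrature oracle", {
  tri <- mk_tri(0.1, 0.15, 0.9, sigma = c(1, 0.8, 1.2))
  p5 <- 5 * c(0.2, 0.4, 0.89) / sqrt(sum(c(0.2, 0.4, 0.89)^2))
  ef <- exterior_field(p5, tri, method = "expansion")$value
  eq <- exterior_field(p5, tri, method = "quadrature")$value
  expect_lt(sqrt(sum((ef - eq)^2)) / sqrt(sum(eq^2)), 1e-4)
})
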