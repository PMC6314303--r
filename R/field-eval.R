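#' Convergence criterion for the moment expansion
#'
#' The on-sphere and exterior moment expansions converge quickly when the
#' evaluation direction is far from the patch compared with the patch size:
#' `1 - rhat_tilde . (v1 + v2 + v3)/3 > 2 [1 - min pairwise vertex dot]`.
#' The margin (left minus right side) quantifies how comfortably the
#' criterion holds.
#'
#' @param direction unit 3-vector of the evaluation direction (same
#'   coordinates as `vertices`).
#' @param vertices 3x3 matrix of unit vertex directions (or a
#'   `sph_triangle`).
#' @return list with `ok` (logical) and `margin`.
#' @export
expansion_converges <- function(direction, vertices) {
  if (inherits(vertices, "sph_triangle")) vertices <- vertices$vertices
  direction <- direction / sqrt(sum(direction^2))
  lhs <- 1 - sum(direction * colMeans(vertices))
  dots <- c(sum(vertices[1, ] * vertices[2, ]),
            sum(vertices[1, ] * vertices[3, ]),
            sum(vertices[2, ] * vertices[3, ]))
  rhs <- 2 * (1 - min(dots))
  list(ok = lhs > rhs, margin = lhs - rhs)
}

# great-circle distance from dir to the closed spherical triangle boundary;
# also reports whether dir is inside
patch_arc_location <- function(dir, verts) {
  dir <- dir / sqrt(sum(dir^2))
  or <- sign(det(verts))
  edges <- list(c(1, 2), c(2, 3), c(3, 1))
  inside <- TRUE
  dmin <- Inf
  for (e in edges) {
    a <- verts[e[1], ]; b <- verts[e[2], ]
    n <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1])
    n <- n / sqrt(sum(n^2)) * or
    s <- sum(dir * n)
    if (s < 0) inside <- FALSE
    # distance to the edge arc: foot-of-perpendicular if it falls on the
    # segment, else nearest endpoint
    proj <- dir - sum(dir * n) * n
    pn <- sqrt(sum(proj^2))
    if (pn > 1e-14) {
      proj <- proj / pn
      tot <- acos(max(-1, min(1, sum(a * b))))
      da <- acos(max(-1, min(1, sum(proj * a))))
      db <- acos(max(-1, min(1, sum(proj * b))))
      d_edge <- if (abs(da + db - tot) < 1e-9) abs(asin(max(-1, min(1, s))))
      else min(acos(max(-1, min(1, sum(dir * a)))),
               acos(max(-1, min(1, sum(dir * b)))))
    } else d_edge <- pi / 2
    dmin <- min(dmin, d_edge)
  }
  list(inside = inside, boundary_distance = dmin)
}

#' Radial field on the sphere outside the patch
#'
#' Radial component of the electric field produced by the charged patch at a
#' point on the same sphere, strictly outside the closed patch:
#' `E_r = (1/2) int int sigma(theta, phi) / sqrt(2 - 2 rhat_tilde . rhat)
#' sin(theta) dtheta dphi`
#' (Gaussian units, unit sphere; identical at any radius R since the kernel
#' scales as 1/R^2 against the R^2 area element).  `method = "expansion"`
#' uses the second-order moment expansion about the area-averaged direction;
#' `"auto"` selects the expansion when the convergence criterion holds with
#' positive margin and the patch arcs are small, else quadrature.
#' Evaluation directions within arc 1e-3 of the patch boundary are refused
#' (the kernel is integrably singular there but quadrature accuracy
#' degrades); boundary-layer evaluation at a vertex is [ez_at_vertex()]'s
#' job.
#'
#' @param direction unit 3-vector, world coordinates.
#' @param tri a `sph_triangle` with densities.
#' @param method "auto", "expansion" or "quadrature".
#' @param beta_max largest side arc admitted to the expansion in auto mode.
#' @return a `field_evaluation`.
#' @export
radial_field_on_sphere <- function(direction, tri,
                                   method = c("auto", "expansion",
                                              "quadrature"),
                                   beta_max = 0.35) {
  method <- match.arg(method)
  stopifnot(inherits(tri, "sph_triangle"))
  direction <- direction / sqrt(sum(direction^2))
  loc <- patch_arc_location(direction, tri$vertices)
  if (loc$inside || loc$boundary_distance < 1e-3)
    stop("evaluation direction inside or within arc 1e-3 of the patch ",
         "boundary; use ez_at_vertex for boundary-layer values")
  conv <- expansion_converges(direction, tri$vertices)
  fr <- canonicalize(tri)
  g <- geodesic_params(fr)
  if (method == "auto") {
    arcs <- c(g$beta1, fr$beta2, fr$beta3)
    method <- if (conv$ok && max(arcs) <= beta_max) "expansion" else
      "quadrature"
  }
  dir_c <- as.numeric(fr$rotation %*% direction)
  if (method == "quadrature") {
    qr <- radial_field_quadrature(dir_c, fr, g)
    return(field_evaluation(qr$value, "quadrature", err_est = qr$abs_error))
  }
  if (!conv$ok)
    stop("moment expansion requested but the convergence criterion fails ",
         "(margin = ", format(conv$margin, digits = 3), ")")
  mom <- charge_moments(fr, g)
  ex <- onsphere_expansion(dir_c, mom)
  field_evaluation(ex$value, "moment_expansion", err_est = ex$err_est)
}

# second-order moment expansion of the on-sphere kernel
# 1/sqrt(1 - c) about c0 = dir . t
onsphere_expansion <- function(dir_c, mom) {
  t <- as.numeric(mom$t)
  c0 <- sum(dir_c * t)
  u1 <- sum(dir_c * (mom$m1 - mom$q0 * t))                  # int sigma u
  M2c <- mom$m2 - tcrossprod(mom$m1, t) - tcrossprod(t, mom$m1) +
    mom$q0 * tcrossprod(t)
  u2 <- as.numeric(dir_c %*% M2c %*% dir_c)                 # int sigma u^2
  om <- 1 - c0
  val <- (mom$q0 + u1 / (2 * om) + 3 * u2 / (8 * om^2)) / (2 * sqrt(2 * om))
  # next-order scale: (5/16) |int sigma u^2| * typical |u| / om^3
  err <- 5 / 16 * abs(u2) * sqrt(max(0, u2 / max(abs(mom$q0), 1e-300))) /
    om^3 / (2 * sqrt(2 * om))
  list(value = val, err_est = err)
}

#' Exterior potential of the charged patch
#'
#' Potential at a point outside the sphere, by the moment expansion about
#' the patch's average position `r_ave = R t` (through second order) or by
#' the quadrature oracle.  `method = "auto"` uses the expansion when the
#' evaluation point is farther than twice the patch diameter from `r_ave`,
#' else quadrature.  The far limit is the monopole `q0 R^2 / |r|`.
#'
#' @param position 3-vector, world coordinates, `|position - center| > R`.
#' @param tri a `sph_triangle` with densities.
#' @param method "auto", "expansion" or "quadrature".
#' @return a `field_evaluation` (value in Gaussian units of density x R).
#' @export
exterior_potential <- function(position, tri,
                               method = c("auto", "expansion", "quadrature")) {
  method <- match.arg(method)
  ctx <- exterior_setup(position, tri)
  if (method == "auto")
    method <- if (ctx$dn > 2 * ctx$diam) "expansion" else "quadrature"
  if (method == "quadrature") {
    qr <- potential_quadrature(ctx$p_c, ctx$fr, ctx$g)
    return(field_evaluation(tri$radius * qr$value, "quadrature",
                            err_est = tri$radius * qr$abs_error))
  }
  d <- ctx$d; dn <- ctx$dn; mom <- ctx$mom
  Q <- ctx$Q
  trQ <- sum(diag(Q))
  val <- mom$q0 / dn + sum(d * (mom$m1 - mom$q0 * ctx$t)) / dn^3 +
    (3 * as.numeric(d %*% Q %*% d) - dn^2 * trQ) / (2 * dn^5)
  err <- abs(trQ) * ctx$diam / dn^3     # octupole scale
  field_evaluation(tri$radius * val, "moment_expansion",
                   err_est = tri$radius * err)
}

#' Exterior electric field of the charged patch
#'
#' Field at a point outside the sphere: minus the gradient of the exterior
#' expansion, term by term (monopole, dipole and quadrupole about `r_ave`),
#' or the quadrature oracle.  World Cartesian components, units of the
#' reference density.
#'
#' @inheritParams exterior_potential
#' @return a `field_evaluation` with a 3-vector value.
#' @export
exterior_field <- function(position, tri,
                           method = c("auto", "expansion", "quadrature")) {
  method <- match.arg(method)
  ctx <- exterior_setup(position, tri)
  Rt <- t(ctx$fr$rotation)
  if (method == "auto")
    method <- if (ctx$dn > 2 * ctx$diam) "expansion" else "quadrature"
  if (method == "quadrature") {
    qr <- field_quadrature(ctx$p_c, ctx$fr, ctx$g)
    return(field_evaluation(as.numeric(Rt %*% qr$value), "quadrature",
                            err_est = sqrt(sum(qr$abs_error^2))))
  }
  d <- ctx$d; dn <- ctx$dn; mom <- ctx$mom
  M1 <- mom$m1 - mom$q0 * ctx$t
  Q <- ctx$Q
  trQ <- sum(diag(Q))
  e_mono <- mom$q0 * d / dn^3
  e_dip <- (3 * sum(d * M1) * d - dn^2 * M1) / dn^5
  Qd <- as.numeric(Q %*% d)
  dQd <- sum(d * Qd)
  e_quad <- -(3 * Qd - trQ * d) / dn^5 + 5 / 2 * (3 * dQd - dn^2 * trQ) *
    d / dn^7
  val_c <- e_mono + e_dip + e_quad
  err <- abs(trQ) * ctx$diam / dn^4
  field_evaluation(as.numeric(Rt %*% val_c), "moment_expansion",
                   err_est = err)
}

# shared setup: canonical point, moments, expansion geometry
exterior_setup <- function(position, tri) {
  stopifnot(inherits(tri, "sph_triangle"))
  p_rel <- (position - tri$center) / tri$radius
  if (sqrt(sum(p_rel^2)) <= 1)
    stop("evaluation point not outside the sphere (|r| <= R)")
  fr <- canonicalize(tri)
  g <- geodesic_params(fr)
  p_c <- as.numeric(fr$rotation %*% p_rel)
  mom <- charge_moments(fr, g)
  t <- as.numeric(mom$t)
  d <- p_c - t
  dn <- sqrt(sum(d^2))
  Q <- mom$m2 - tcrossprod(mom$m1, t) - tcrossprod(t, mom$m1) +
    mom$q0 * tcrossprod(t)
  dots <- c(sum(tri$vertices[1, ] * tri$vertices[2, ]),
            sum(tri$vertices[1, ] * tri$vertices[3, ]),
            sum(tri$vertices[2, ] * tri$vertices[3, ]))
  diam <- acos(max(-1, min(1, min(dots))))
  list(fr = fr, g = g, p_c = p_c, mom = mom, t = t, d = d, dn = dn, Q = Q,
       diam = diam)
}
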