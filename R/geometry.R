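#' Spherical triangle patch
#'
#' Constructs a great-arc-bounded triangular patch on a sphere: three unit
#' direction vectors from the sphere centre to the vertices, an optional set
#' of vertex surface-charge densities, a centre and a radius.  All internal
#' computations run on the unit sphere; `center` and `radius` only matter for
#' evaluation at world coordinates.
#'
#' @param vertices 3x3 numeric matrix, one unit vertex direction per row.
#' @param sigma optional numeric length-3 vector of vertex charge densities
#'   (charge per unit area), one per vertex.
#' @param center sphere centre (length-3 numeric).
#' @param radius sphere radius (positive scalar).
#' @return an object of class `sph_triangle`.
#' @examples
#' tri <- spherical_triangle(rbind(c(0, 0, 1),
#'                                 c(sin(0.2), 0, cos(0.2)),
#'                                 c(0, sin(0.2), cos(0.2))),
#'                           sigma = c(1, 0.9, 1.1))
#' canonicalize(tri)
#' @export
spherical_triangle <- function(vertices, sigma = NULL, center = c(0, 0, 0),
                               radius = 1) {
  vertices <- as.matrix(vertices)
  if (!all(dim(vertices) == c(3L, 3L)) || !is.numeric(vertices))
    stop("`vertices` must be a numeric 3x3 matrix (one vertex per row)")
  nrm <- sqrt(rowSums(vertices^2))
  if (any(abs(nrm - 1) > 1e-12))
    stop("vertex ", which(abs(nrm - 1) > 1e-12)[1],
         " is not a unit vector (|v| - 1 = ",
         format(max(abs(nrm - 1)), digits = 3), ")")
  dots <- c(sum(vertices[1, ] * vertices[2, ]),
            sum(vertices[1, ] * vertices[3, ]),
            sum(vertices[2, ] * vertices[3, ]))
  if (any(dots >= 1 - 1e-14) || any(dots <= -1 + 1e-14))
    stop("coincident or antipodal vertices")
  tp <- det(vertices)
  if (abs(tp) < 1e-14)
    stop("degenerate triangle: vertices lie on one great circle ",
         "(triple product = ", format(tp, digits = 3), ")")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != 3L || !all(is.finite(sigma)))
      stop("`sigma` must be three finite densities")
  }
  if (length(center) != 3L || !is.numeric(center))
    stop("`center` must be a length-3 numeric vector")
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("`radius` must be a positive scalar")
  structure(list(vertices = vertices, sigma = sigma,
                 center = as.numeric(center), radius = as.numeric(radius)),
            class = "sph_triangle")
}

#' @export
print.sph_triangle <- function(x, ...) {
  cat("Spherical triangle patch (R =", format(x$radius), ")\n")
  fr <- canonicalize(x)
  cat(sprintf("  side arcs: beta1 = %.5f, beta2 = %.5f, beta3 = %.5f rad\n",
              geodesic_params(fr)$beta1, fr$beta2, fr$beta3))
  cat(sprintf("  opening alpha = %.5f rad, area = %.6g sr\n",
              fr$alpha, patch_area(fr)))
  if (!is.null(x$sigma))
    cat("  vertex densities:", paste(format(x$sigma), collapse = ", "), "\n")
  invisible(x)
}

#' Canonical placement of a spherical triangle
#'
#' Rotates the patch so the chosen vertex sits at the north pole, the second
#' vertex at azimuth 0 and the third at azimuth `alpha`.  The side arcs are
#' `beta3` (pole to the azimuth-0 vertex, i.e. the arc opposite vertex 3) and
#' `beta2` (pole to the azimuth-`alpha` vertex).  If the raw winding gives
#' `alpha` in (pi, 2*pi), the two non-pole vertices are swapped so that
#' 0 < alpha < pi; the applied vertex permutation is recorded in `$perm` and
#' any vertex densities are permuted consistently.
#'
#' @param tri a `sph_triangle`.
#' @param pole which vertex (1, 2 or 3) becomes the north pole.
#' @return an object of class `sph_frame` with fields `rotation` (proper
#'   orthogonal 3x3 matrix mapping world directions into the canonical frame),
#'   `pole_index`, `perm` (canonical position -> original vertex index),
#'   `relabeled`, `beta2`, `beta3`, `alpha`, `zeta23` and (if present) the
#'   permuted `sigma`.
#' @export
canonicalize <- function(tri, pole = 1L) {
  stopifnot(inherits(tri, "sph_triangle"))
  pole <- as.integer(pole)
  if (!pole %in% 1:3) stop("`pole` must be 1, 2 or 3")
  idx <- c(pole, setdiff(1:3, pole))
  v <- tri$vertices[idx, , drop = FALSE]
  tp <- det(tri$vertices)
  if (abs(tp) < 1e-14) stop("degenerate triangle (triple product ~ 0)")

  # rotation: pole -> z; second vertex into the xz half-plane (azimuth 0)
  e3 <- v[1, ]
  u2 <- v[2, ] - sum(v[2, ] * e3) * e3
  e1 <- u2 / sqrt(sum(u2^2))
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  rot <- rbind(e1, e2, e3)            # maps world -> canonical
  w3 <- as.numeric(rot %*% v[3, ])
  alpha <- atan2(w3[2], w3[1])
  if (alpha < 0) alpha <- alpha + 2 * pi

  relabeled <- FALSE
  if (alpha > pi) {
    # swap the two non-pole vertices and rebuild the frame
    idx <- c(idx[1], idx[3], idx[2])
    v <- tri$vertices[idx, , drop = FALSE]
    u2 <- v[2, ] - sum(v[2, ] * e3) * e3
    e1 <- u2 / sqrt(sum(u2^2))
    e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
            e3[3] * e1[1] - e3[1] * e1[3],
            e3[1] * e1[2] - e3[2] * e1[1])
    rot <- rbind(e1, e2, e3)
    w3 <- as.numeric(rot %*% v[3, ])
    alpha <- atan2(w3[2], w3[1])
    relabeled <- TRUE
  }
  if (!(alpha > 0 && alpha < pi))
    stop("canonical opening angle out of (0, pi); degenerate triangle")

  beta3 <- acos(max(-1, min(1, sum(v[1, ] * v[2, ]))))  # pole -> azimuth-0 vertex
  beta2 <- acos(max(-1, min(1, sum(v[1, ] * v[3, ]))))  # pole -> azimuth-alpha vertex
  zeta23 <- 1 - sum(v[2, ] * v[3, ])

  structure(list(rotation = rot, pole_index = pole, perm = idx,
                 relabeled = relabeled,
                 beta2 = beta2, beta3 = beta3, alpha = alpha, zeta23 = zeta23,
                 sigma = if (!is.null(tri$sigma)) tri$sigma[idx] else NULL,
                 center = tri$center, radius = tri$radius),
            class = "sph_frame")
}

#' Build a canonical frame directly from side arcs and opening
#'
#' Convenience constructor for a patch already in canonical position:
#' pole at (0,0,1), second vertex at polar angle `beta3`, azimuth 0, third
#' vertex at polar angle `beta2`, azimuth `alpha`.
#'
#' @param beta2,beta3 side arcs from the pole (radians, in (0, pi)).
#' @param alpha azimuthal opening (radians, in (0, pi)).
#' @param sigma optional vertex densities in canonical order (pole first).
#' @return a `sph_frame`.
#' @export
canonical_frame <- function(beta2, beta3, alpha, sigma = NULL) {
  stopifnot(beta2 > 0, beta2 < pi, beta3 > 0, beta3 < pi,
            alpha > 0, alpha < pi)
  zeta23 <- 1 - (sin(beta2) * sin(beta3) * cos(alpha) +
                   cos(beta2) * cos(beta3))
  structure(list(rotation = diag(3), pole_index = 1L, perm = 1:3,
                 relabeled = FALSE,
                 beta2 = beta2, beta3 = beta3, alpha = alpha, zeta23 = zeta23,
                 sigma = sigma, center = c(0, 0, 0), radius = 1),
            class = "sph_frame")
}

#' Canonical vertex directions of a frame
#'
#' @param frame a `sph_frame`.
#' @return 3x3 matrix of unit vectors in the canonical frame (pole first).
#' @export
frame_vertices <- function(frame) {
  rbind(c(0, 0, 1),
        c(sin(frame$beta3), 0, cos(frame$beta3)),
        c(sin(frame$beta2) * cos(frame$alpha),
          sin(frame$beta2) * sin(frame$alpha),
          cos(frame$beta2)))
}

#' Geodesic parameters of the side opposite the pole
#'
#' The great arc joining the two non-pole vertices satisfies
#' cot(theta) = a cos(phi - phi0).  The parameters are recovered from the
#' boundary conditions cot(beta3) = a cos(phi0) and
#' cot(beta2) = a cos(alpha - phi0), solved in the numerically robust
#' component form (a cos(phi0), a sin(phi0)); this avoids the tangent poles
#' at beta = pi/2.  When both arcs equal pi/2 the opposite side lies on the
#' equator, a = 0 and phi0 is unidentifiable; it is set to 0 by convention.
#'
#' @param frame a `sph_frame`.
#' @return object of class `sph_geodesic`: `a` (nonnegative), `phi0`
#'   (radians), `beta1` (arc length of the opposite side), plus a copy of
#'   `alpha` for domain checks.
#' @export
geodesic_params <- function(frame) {
  stopifnot(inherits(frame, "sph_frame"))
  u <- cos(frame$beta3) / sin(frame$beta3)            # a cos(phi0)
  w <- (cos(frame$beta2) / sin(frame$beta2) -
          cos(frame$alpha) * u) / sin(frame$alpha)    # a sin(phi0)
  a <- sqrt(u^2 + w^2)
  phi0 <- if (a < 1e-14) 0 else atan2(w, u)
  cb1 <- cos(frame$beta2) * cos(frame$beta3) +
    sin(frame$beta2) * sin(frame$beta3) * cos(frame$alpha)
  beta1 <- acos(max(-1, min(1, cb1)))
  structure(list(a = a, phi0 = phi0, beta1 = beta1, alpha = frame$alpha),
            class = "sph_geodesic")
}

#' Polar angle of the opposite side at azimuth phi
#'
#' Evaluates beta(phi) = arccot(a cos(phi - phi0)) on the great-arc side
#' opposite the pole.
#'
#' @param phi azimuth(s), must lie in `[0, alpha]`.
#' @param g a `sph_geodesic`.
#' @return polar angle(s) in (0, pi/2].
#' @export
beta_of_phi <- function(phi, g) {
  stopifnot(inherits(g, "sph_geodesic"))
  if (any(phi < -1e-12 | phi > g$alpha + 1e-12))
    stop("phi outside [0, alpha]")
  atan2(1, g$a * cos(phi - g$phi0))
}

#' Arc length of the side opposite the pole
#'
#' Two-arctangent closed form of the geodesic arc-length integral; agrees
#' with the spherical law of cosines to machine precision.
#'
#' @param g a `sph_geodesic`.
#' @param alpha azimuthal opening (defaults to the one stored in `g`).
#' @return arc length beta1 (radians).
#' @export
arc_length_opposite <- function(g, alpha = g$alpha) {
  stopifnot(inherits(g, "sph_geodesic"))
  sq <- sqrt(1 + g$a^2)
  atan(tan(alpha - g$phi0) / sq) + atan(tan(g$phi0) / sq)
}
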