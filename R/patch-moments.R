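#' Solid-angle area of the patch
#'
#' Area of the spherical triangle in steradians (unit sphere).  Three
#' routes: the closed form
#' `A = alpha - atan(tan(alpha - phi0) cos(beta2)) - atan(tan(phi0) cos(beta3))`,
#' the Girard spherical excess computed from the vertex vectors (independent
#' check), and the series
#' `F(0,0,2)/2 - 3 F(0,0,4)/8 + 5 F(0,0,6)/16 - ...` whose terms are the
#' binomial expansion of `1 - cos(beta(phi))` (signs alternate).
#'
#' @param frame a `sph_frame`.
#' @param g a `sph_geodesic`; computed from the frame if missing.
#' @param method "closed", "girard" or "series".
#' @param order highest retained beta order for the series (2, 4 or 6).
#' @return area in steradians.
#' @export
patch_area <- function(frame, g = geodesic_params(frame),
                       method = c("closed", "girard", "series"), order = 6) {
  method <- match.arg(method)
  if (method == "closed") {
    # a-based form of the two-arctangent result; equivalent to
    # alpha - atan(tan(alpha - phi0) cos(beta2)) - atan(tan(phi0) cos(beta3))
    # but regular at side arcs of pi/2 (a = 0, equatorial opposite side)
    x1 <- frame$alpha - g$phi0
    return(frame$alpha -
             atan(g$a * sin(x1) / sqrt(1 + g$a^2 * cos(x1)^2)) -
             atan(g$a * sin(g$phi0) / sqrt(1 + g$a^2 * cos(g$phi0)^2)))
  }
  if (method == "girard") {
    v <- frame_vertices(frame)
    ang <- function(a, b, c) {
      u <- b - sum(a * b) * a; w <- c - sum(a * c) * a
      acos(max(-1, min(1, sum(u * w) / sqrt(sum(u * u) * sum(w * w)))))
    }
    return(ang(v[1, ], v[2, ], v[3, ]) + ang(v[2, ], v[3, ], v[1, ]) +
             ang(v[3, ], v[1, ], v[2, ]) - pi)
  }
  stopifnot(order %in% c(2, 4, 6))
  # (1 - cos beta) = x/2 - 3x^2/8 + 5x^3/16 - ..., x = 1/(a cos(phi-phi0))^2
  coefs <- c(1 / 2, -3 / 8, 5 / 16)
  ps <- c(2, 4, 6)
  keep <- ps <= order
  sum(coefs[keep] * vapply(ps[keep], function(p)
    F_direct(0, 0, 0, 0, p, frame, g), numeric(1)))
}

#' Area-averaged direction of the patch
#'
#' The average of the unit position vector over the patch,
#' `r_ave = (t_x, t_y, t_z)`, from the exact closed forms of the three
#' defining integrals (each is a combination of the side arcs and the
#' two-arctangent arc-length form).
#'
#' @param frame a `sph_frame`.
#' @param g a `sph_geodesic`.
#' @return named numeric vector `c(t_x, t_y, t_z)`; its norm is <= 1.
#' @export
direction_average <- function(frame, g = geodesic_params(frame)) {
  A <- patch_area(frame, g)
  sq <- sqrt(1 + g$a^2)
  b1 <- g$beta1
  txA <- 0.5 * (sin(frame$alpha) * frame$beta2 -
                  (g$a * cos(g$phi0) / sq) * b1)
  tyA <- 0.5 * (frame$beta3 - cos(frame$alpha) * frame$beta2 -
                  (g$a * sin(g$phi0) / sq) * b1)
  tzA <- b1 / (2 * sq)
  c(t_x = txA / A, t_y = tyA / A, t_z = tzA / A)
}

# azimuthal integral of fn(phi) * weight over [0, alpha], adaptive with a
# graceful retry at a looser tolerance
phi_integral <- function(fn, frame, rel_tol = 1e-11) {
  f <- Vectorize(fn)
  out <- tryCatch(
    stats::integrate(f, 0, frame$alpha, rel.tol = rel_tol,
                     abs.tol = 1e-15, subdivisions = 400L)$value,
    error = function(e) NULL)
  if (!is.null(out)) return(out)
  stats::integrate(f, 0, frame$alpha, rel.tol = 1e-9, abs.tol = 1e-13,
                   subdivisions = 1000L, stop.on.error = FALSE)$value
}

# exact-path moment: sigma1 * int trig(phi) M(n, m, beta(phi)) dphi
#                  + int trig(phi) B(phi) J(n, m) dphi
moment_exact <- function(n, m, trig, frame, g, sigma) {
  s1_part <- phi_integral(function(phi)
    trig(phi) * sin_cos_moment(n, m, beta_of_phi(phi, g)), frame)
  B_part <- phi_integral(function(phi) {
    co <- interp_coefficients(phi, frame, g)
    B <- (sigma[2] - sigma[1]) + co$lambda * (sigma[3] - sigma[2])
    trig(phi) * B * theta_ratio_integral(n, m, co$C, co$D, co$beta)
  }, frame)
  sigma[1] * s1_part + B_part
}

# series-path G combination for both density-difference channels;
# terms given as rows (nc, ns, l, k, p, coef); returns c(d0, d1)
series_comb2 <- function(terms, frame, g, sub) {
  tot0 <- 0; tot1 <- 0
  for (r in seq_len(nrow(terms))) {
    tr <- terms[r, ]
    tot0 <- tot0 + tr[6] * G_term(tr[1], tr[2], tr[3], 0, tr[4], tr[5],
                                  frame, g, sub)
    tot1 <- tot1 + tr[6] * G_term(tr[1], tr[2], tr[3], 1, tr[4], tr[5],
                                  frame, g, sub)
  }
  c(tot0, tot1)
}

# weight-channel decomposition of the series moments: each of q0, m1, m2 as
# s1 / d0 / d1 channel values, so that
# moment = sigma1 * s1 + (sigma2 - sigma1) * d0 + (sigma3 - sigma2) * d1
series_moment_parts <- function(frame, g, sub = substitution_params(frame, g)) {
  TT <- function(...) matrix(c(...), ncol = 6, byrow = TRUE)
  s1m <- function(n, m, trig) phi_integral(function(phi)
    trig(phi) * sin_cos_moment(n, m, beta_of_phi(phi, g)), frame)
  one <- function(phi) 1
  q0_b <- series_comb2(TT(
    0, 0, 0, 0, 2, 1 / 3,
    0, 0, 0, 1, 2, 1 / 3,
    0, 0, 0, 0, 4, -31 / 120,
    0, 0, 1, 0, 4, 1 / 12), frame, g, sub)
  # sign of the density-difference block fixed against the polar-integral
  # oracle: J(2,0) = (1/(4 a^3 c^3)) [1 + (6 h - 37)/(30 a^2 c^2) + ...]
  m1x_b <- series_comb2(TT(
    1, 0, 0, 0, 3, 1 / 4,
    1, 0, 0, 1, 3, 1 / 4,
    1, 0, 0, 0, 5, -37 / 120,
    1, 0, 1, 0, 5, 1 / 20), frame, g, sub)
  m1y_b <- series_comb2(TT(
    0, 1, 0, 0, 3, 1 / 4,
    0, 1, 0, 1, 3, 1 / 4,
    0, 1, 0, 0, 5, -37 / 120,
    0, 1, 1, 0, 5, 1 / 20), frame, g, sub)
  m1z_b <- series_comb2(TT(
    0, 0, 0, 0, 2, 1 / 3,
    0, 0, 0, 1, 2, 1 / 3,
    0, 0, 0, 0, 4, -43 / 120,
    0, 0, 1, 0, 4, 1 / 12), frame, g, sub)
  mxx_b <- series_comb2(TT(
    2, 0, 0, 0, 4, 1 / 5,
    2, 0, 0, 1, 4, 1 / 5), frame, g, sub)
  myy_b <- series_comb2(TT(
    0, 2, 0, 0, 4, 1 / 5,
    0, 2, 0, 1, 4, 1 / 5), frame, g, sub)
  mxy_b <- series_comb2(TT(
    1, 1, 0, 0, 4, 1 / 5,
    1, 1, 0, 1, 4, 1 / 5), frame, g, sub)
  mxz_b <- series_comb2(TT(
    1, 0, 0, 0, 3, 1 / 4,
    1, 0, 0, 1, 3, 1 / 4,
    1, 0, 0, 0, 5, -47 / 120,
    1, 0, 1, 0, 5, 1 / 20), frame, g, sub)
  myz_b <- series_comb2(TT(
    0, 1, 0, 0, 3, 1 / 4,
    0, 1, 0, 1, 3, 1 / 4,
    0, 1, 0, 0, 5, -47 / 120,
    0, 1, 1, 0, 5, 1 / 20), frame, g, sub)
  mzz_b <- series_comb2(TT(
    0, 0, 0, 0, 2, 1 / 3,
    0, 0, 0, 1, 2, 1 / 3,
    0, 0, 0, 0, 4, -11 / 24,
    0, 0, 1, 0, 4, 1 / 12), frame, g, sub)
  mk2 <- function(xx, yy, zz, xy, xz, yz)
    matrix(c(xx, xy, xz, xy, yy, yz, xz, yz, zz), 3, 3)
  A <- patch_area(frame, g)
  t_ave <- direction_average(frame, g)
  list(
    s1 = list(q0 = A, m1 = A * as.numeric(t_ave),
              m2 = mk2(s1m(3, 0, function(p) cos(p)^2),
                       s1m(3, 0, function(p) sin(p)^2),
                       s1m(1, 2, one),
                       s1m(3, 0, function(p) cos(p) * sin(p)),
                       s1m(2, 1, cos), s1m(2, 1, sin))),
    d0 = list(q0 = q0_b[1], m1 = c(m1x_b[1], m1y_b[1], m1z_b[1]),
              m2 = mk2(mxx_b[1], myy_b[1], mzz_b[1], mxy_b[1],
                       mxz_b[1], myz_b[1])),
    d1 = list(q0 = q0_b[2], m1 = c(m1x_b[2], m1y_b[2], m1z_b[2]),
              m2 = mk2(mxx_b[2], myy_b[2], mzz_b[2], mxy_b[2],
                       mxz_b[2], myz_b[2])),
    A = A, t = t_ave)
}

#' Charge moments of the patch
#'
#' Total charge `q0`, unnormalized first moments `m1 = int sigma rhat dA`
#' and unnormalized second moments `m2 = int sigma rhat rhat^T dA` of the
#' interpolated density over the patch (unit sphere; multiply `q0`, `m1`,
#' `m2` by R^2 for a sphere of radius R).  Since `|rhat| = 1`,
#' `trace(m2) = q0` identically.
#'
#' Three methods:
#' \describe{
#'   \item{exact}{polar integrals in closed form ([theta_ratio_integral()]),
#'     azimuthal integral adaptive; accurate to the azimuthal quadrature
#'     tolerance.}
#'   \item{series}{G-integral combinations carrying the leading term and its
#'     relative-order-beta^2 correction (the paper-order truncation); valid
#'     in the small-arc regime.}
#'   \item{quadrature}{iterated 2-D adaptive quadrature of the defining
#'     integrals (the oracle).}
#' }
#'
#' @param frame a `sph_frame`.
#' @param g a `sph_geodesic`.
#' @param sigma vertex densities (canonical order); defaults to
#'   `frame$sigma`.
#' @param method "exact", "series" or "quadrature".
#' @return object of class `sph_moments`: list with `A`, `t` (direction
#'   average), `q0`, `m1` (3-vector), `m2` (3x3 symmetric), `method`.
#' @export
charge_moments <- function(frame, g = geodesic_params(frame),
                           sigma = frame$sigma,
                           method = c("exact", "series", "quadrature")) {
  method <- match.arg(method)
  if (is.null(sigma)) stop("no vertex densities available")
  A <- patch_area(frame, g)
  t_ave <- direction_average(frame, g)

  if (method == "quadrature") {
    spec <- quadrature_spec(rel_tol = 1e-11)
    mom <- function(fn) patch_quad(function(th, phi)
      sigma_at(th, phi, frame, g, sigma) * sin(th) * fn(th, phi),
      frame, g, spec)$value
    q0 <- mom(function(th, phi) 1)
    m1 <- c(mom(function(th, phi) sin(th) * cos(phi)),
            mom(function(th, phi) sin(th) * sin(phi)),
            mom(function(th, phi) cos(th)))
    m2 <- matrix(0, 3, 3)
    m2[1, 1] <- mom(function(th, phi) (sin(th) * cos(phi))^2)
    m2[2, 2] <- mom(function(th, phi) (sin(th) * sin(phi))^2)
    m2[3, 3] <- mom(function(th, phi) cos(th)^2)
    m2[1, 2] <- m2[2, 1] <- mom(function(th, phi)
      sin(th)^2 * cos(phi) * sin(phi))
    m2[1, 3] <- m2[3, 1] <- mom(function(th, phi) sin(th) * cos(phi) * cos(th))
    m2[2, 3] <- m2[3, 2] <- mom(function(th, phi) sin(th) * sin(phi) * cos(th))
  } else if (method == "exact") {
    one <- function(phi) 1
    q0 <- moment_exact(1, 0, one, frame, g, sigma)
    m1 <- c(moment_exact(2, 0, cos, frame, g, sigma),
            moment_exact(2, 0, sin, frame, g, sigma),
            moment_exact(1, 1, one, frame, g, sigma))
    m2 <- matrix(0, 3, 3)
    m2[1, 1] <- moment_exact(3, 0, function(p) cos(p)^2, frame, g, sigma)
    m2[2, 2] <- moment_exact(3, 0, function(p) sin(p)^2, frame, g, sigma)
    m2[3, 3] <- moment_exact(1, 2, one, frame, g, sigma)
    m2[1, 2] <- m2[2, 1] <- moment_exact(3, 0, function(p) cos(p) * sin(p),
                                         frame, g, sigma)
    m2[1, 3] <- m2[3, 1] <- moment_exact(2, 1, cos, frame, g, sigma)
    m2[2, 3] <- m2[3, 2] <- moment_exact(2, 1, sin, frame, g, sigma)
  } else {
    parts <- series_moment_parts(frame, g)
    w <- c(sigma[1], sigma[2] - sigma[1], sigma[3] - sigma[2])
    q0 <- w[1] * parts$s1$q0 + w[2] * parts$d0$q0 + w[3] * parts$d1$q0
    m1 <- w[1] * parts$s1$m1 + w[2] * parts$d0$m1 + w[3] * parts$d1$m1
    m2 <- w[1] * parts$s1$m2 + w[2] * parts$d0$m2 + w[3] * parts$d1$m2
  }
  structure(list(A = A, t = t_ave, q0 = q0, m1 = m1, m2 = m2,
                 method = method),
            class = "sph_moments")
}

#' @export
print.sph_moments <- function(x, ...) {
  cat("<patch charge moments> (", x$method, ")\n", sep = "")
  cat("  area A =", format(x$A, digits = 10), "sr\n")
  cat("  r_ave  =", paste(format(x$t, digits = 6), collapse = ", "), "\n")
  cat("  q0     =", format(x$q0, digits = 10), "\n")
  cat("  m1     =", paste(format(x$m1, digits = 6), collapse = ", "), "\n")
  cat("  tr(m2) =", format(sum(diag(x$m2)), digits = 10), "\n")
  invisible(x)
}

#' Rotate patch moments to world coordinates
#'
#' Moments are computed in the canonical frame; this applies the inverse
#' frame rotation so `t`, `m1`, `m2` refer to world directions.
#'
#' @param m a `sph_moments`.
#' @param frame the `sph_frame` the moments were computed in.
#' @return a `sph_moments` in world coordinates.
#' @export
moments_to_world <- function(m, frame) {
  Rt <- t(frame$rotation)
  m$t <- setNames(as.numeric(Rt %*% m$t), c("t_x", "t_y", "t_z"))
  m$m1 <- as.numeric(Rt %*% m$m1)
  m$m2 <- Rt %*% m$m2 %*% frame$rotation
  m
}
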