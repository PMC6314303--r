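#' Chord fraction lambda(phi)
#'
#' Fraction of the flat chord between the two non-pole vertices cut by the
#' meridian half-plane at azimuth `phi`, from the central projection of the
#' inscribed flat triangle.  Evaluated in the sine form, which is regular at
#' phi = pi/2.
#'
#' @param phi azimuth(s) in `[0, alpha]`.
#' @param frame a `sph_frame`.
#' @return chord fraction(s) in `[0, 1]`, monotone nondecreasing in `phi`.
#' @export
lambda_of_phi <- function(phi, frame) {
  if (any(phi < -1e-12 | phi > frame$alpha + 1e-12))
    stop("phi outside [0, alpha]")
  sb3 <- sin(frame$beta3)
  num <- sb3 * sin(phi)
  num / (sin(frame$beta2) * sin(frame$alpha - phi) + num)
}

#' Chord depth delta(phi)/R
#'
#' Radial depth of the chord point below the sphere surface, as a fraction of
#' the radius: `1 - sqrt(1 - 2 lambda (1 - lambda) zeta23)` with
#' `zeta23 = 1 - cos(beta1)` the chord deficit of the opposite side.
#'
#' @param phi azimuth(s) in `[0, alpha]`.
#' @param frame a `sph_frame`.
#' @param lambda chord fraction(s); defaults to `lambda_of_phi(phi, frame)`.
#' @return delta/R in `[0, 1)`; 0 at the chord endpoints.
#' @export
delta_of_phi <- function(phi, frame, lambda = lambda_of_phi(phi, frame)) {
  1 - sqrt(1 - 2 * lambda * (1 - lambda) * frame$zeta23)
}

#' Projection and expansion coefficients at azimuth phi
#'
#' All phi-dependent quantities of the central-projection interpolation at a
#' slice of constant azimuth: the chord fraction `lambda`, chord depth
#' `delta_over_R`, boundary polar angle `beta`, the slice coefficients
#' `C = (1 - cos beta) + (delta/R) cos beta` (order beta^2) and
#' `D = (1 - delta/R) sin beta` (order beta), `eta_sq = (C^2 + D^2)/C^2`,
#' and the order-1 combination `h_core = zeta23 lambda (1 - lambda)`, which
#' equals `h_tilde / (a^2 cos^2(phi - phi0))`.  `h_tilde` itself is only
#' reconstructed where series formulas need it (it degenerates when a -> 0;
#' large patches take the quadrature path instead).
#'
#' @param phi single azimuth in `[0, alpha]`.
#' @param frame a `sph_frame`.
#' @param g a `sph_geodesic` for the frame.
#' @return list with components `lambda`, `delta_over_R`, `beta`, `C`, `D`,
#'   `eta_sq`, `h_core`.
#' @export
interp_coefficients <- function(phi, frame, g) {
  lam <- lambda_of_phi(phi, frame)
  dR <- delta_of_phi(phi, frame, lam)
  b <- beta_of_phi(phi, g)
  C <- (1 - cos(b)) + dR * cos(b)
  D <- (1 - dR) * sin(b)
  list(lambda = lam, delta_over_R = dR, beta = b, C = C, D = D,
       eta_sq = (C^2 + D^2) / C^2, h_core = frame$zeta23 * lam * (1 - lam))
}

#' Radial projection fraction t(theta)
#'
#' Fraction of the way from the pole to the chord along the slice at azimuth
#' `phi`, for the surface point at polar angle `theta`:
#' `t = sin(theta) / (C sin(theta) + D cos(theta))`.
#'
#' @param theta polar angle(s) in `[0, beta(phi)]`.
#' @param C,D slice coefficients from [interp_coefficients()].
#' @return t in `[0, 1]`; `t(0) = 0` and `t(beta) = 1`.
#' @export
t_of_theta <- function(theta, C, D) {
  s <- sin(theta)
  s / (C * s + D * cos(theta))
}

#' Interpolated surface charge density on the patch
#'
#' Coordinate-free linear interpolation of the three vertex densities,
#' carried from the inscribed flat triangle onto the spherical triangle by
#' central projection:
#' `sigma(theta, phi) = (1 - t) sigma1 + t [(1 - lambda) sigma2 + lambda sigma3]`.
#'
#' @param theta polar angle(s), `0 <= theta <= beta(phi)`.
#' @param phi single azimuth in `[0, alpha]`.
#' @param frame a `sph_frame`.
#' @param g a `sph_geodesic`.
#' @param sigma vertex densities in canonical order (pole first); defaults to
#'   the densities stored in the frame.
#' @return interpolated density value(s).
#' @export
sigma_at <- function(theta, phi, frame, g, sigma = frame$sigma) {
  if (is.null(sigma)) stop("no vertex densities available")
  co <- interp_coefficients(phi, frame, g)
  if (any(theta < -1e-12 | theta > co$beta + 1e-12))
    stop("theta outside [0, beta(phi)]: point not on the patch")
  tt <- t_of_theta(theta, co$C, co$D)
  sigma[1] + tt * ((1 - co$lambda) * sigma[2] + co$lambda * sigma[3] - sigma[1])
}
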