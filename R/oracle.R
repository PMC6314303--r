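#' Quadrature specification
#'
#' Tolerances and limits for the brute-force adaptive quadrature oracle.
#' The iterated rule integrates theta innermost with a tolerance ten times
#' tighter than the outer azimuthal integral; it is deterministic for a
#' fixed spec.
#'
#' @param rel_tol,abs_tol positive tolerances of the outer integral.
#' @param max_subdivisions subdivision limit per 1-D integral.
#' @param regularize use the identity
#'   `sin(theta)/sqrt(1 - cos(theta)) = sqrt(2) cos(theta/2)` to remove the
#'   apparent pole of the vertex kernel.
#' @return object of class `quadrature_spec`.
#' @export
quadrature_spec <- function(rel_tol = 1e-10, abs_tol = 1e-14,
                            max_subdivisions = 400L, regularize = TRUE) {
  stopifnot(rel_tol > 0, abs_tol > 0, max_subdivisions >= 10)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol,
                 max_subdivisions = as.integer(max_subdivisions),
                 regularize = isTRUE(regularize)),
            class = "quadrature_spec")
}

# one guarded 1-D adaptive integral; flags instead of failing silently
safe_integrate <- function(f, lower, upper, rel_tol, abs_tol, max_sub) {
  out <- tryCatch(
    stats::integrate(f, lower, upper, rel.tol = rel_tol, abs.tol = abs_tol,
                     subdivisions = max_sub),
    error = function(e) NULL)
  if (is.null(out)) {
    out <- stats::integrate(f, lower, upper, rel.tol = sqrt(rel_tol),
                            abs.tol = sqrt(abs_tol), subdivisions = max_sub,
                            stop.on.error = FALSE)
    return(list(value = out$value, flagged = TRUE, abs_error = out$abs.error))
  }
  list(value = out$value, flagged = FALSE, abs_error = out$abs.error)
}

# iterated 2-D quadrature over the canonical patch of fn(theta, phi)
# (fn vectorized in theta for fixed phi)
patch_quad <- function(fn, frame, g, spec) {
  flagged <- FALSE
  inner <- function(phi) {
    b <- beta_of_phi(phi, g)
    r <- safe_integrate(function(th) fn(th, phi), 0, b,
                        spec$rel_tol / 10, spec$abs_tol / 10,
                        spec$max_subdivisions)
    if (r$flagged) flagged <<- TRUE
    r$value
  }
  r <- safe_integrate(Vectorize(inner), 0, frame$alpha,
                      spec$rel_tol, spec$abs_tol, spec$max_subdivisions)
  list(value = r$value, flagged = flagged || r$flagged,
       abs_error = r$abs_error)
}

#' Patch potential by adaptive quadrature
#'
#' Source-of-truth evaluation of the electric potential of the charged patch
#' at an arbitrary admissible point, by iterated adaptive quadrature of the
#' Coulomb kernel over the canonical patch parametrization (unit sphere,
#' Gaussian units; multiply by R for a sphere of radius R).
#'
#' @param point evaluation point, 3-vector in canonical-frame coordinates
#'   (any |point|, but not on the open patch surface).
#' @param frame a `sph_frame`.
#' @param g a `sph_geodesic`.
#' @param sigma vertex densities in canonical order; defaults to
#'   `frame$sigma`.
#' @param spec a `quadrature_spec`.
#' @return list with `value`, `flagged` (TRUE if a tolerance was not met; the
#'   value is then the best estimate, never silently degraded), `abs_error`.
#' @export
potential_quadrature <- function(point, frame, g, sigma = frame$sigma,
                                 spec = quadrature_spec()) {
  stopifnot(length(point) == 3)
  fn <- function(th, phi) {
    r <- rbind(sin(th) * cos(phi), sin(th) * sin(phi), cos(th))
    d <- sqrt((point[1] - r[1, ])^2 + (point[2] - r[2, ])^2 +
                (point[3] - r[3, ])^2)
    sigma_at(th, phi, frame, g, sigma) * sin(th) / d
  }
  patch_quad(fn, frame, g, spec)
}

#' Patch electric field by adaptive quadrature
#'
#' As [potential_quadrature()] but for the field (gradient kernel); returns
#' the Cartesian 3-vector in canonical-frame coordinates.
#'
#' @inheritParams potential_quadrature
#' @return list with `value` (3-vector), `flagged`, `abs_error` (3-vector).
#' @export
field_quadrature <- function(point, frame, g, sigma = frame$sigma,
                             spec = quadrature_spec()) {
  stopifnot(length(point) == 3)
  comp <- function(i) {
    fn <- function(th, phi) {
      r <- rbind(sin(th) * cos(phi), sin(th) * sin(phi), cos(th))
      dx <- point[1] - r[1, ]; dy <- point[2] - r[2, ]; dz <- point[3] - r[3, ]
      d3 <- (dx^2 + dy^2 + dz^2)^1.5
      num <- switch(i, dx, dy, dz)
      sigma_at(th, phi, frame, g, sigma) * sin(th) * num / d3
    }
    patch_quad(fn, frame, g, spec)
  }
  rs <- lapply(1:3, comp)
  list(value = vapply(rs, `[[`, numeric(1), "value"),
       flagged = any(vapply(rs, `[[`, logical(1), "flagged")),
       abs_error = vapply(rs, `[[`, numeric(1), "abs_error"))
}

#' Continuous normal field at the pole vertex, quadrature oracle
#'
#' The continuous part of the normal field component at the patch's pole
#' vertex, using the regularized kernel `cos(theta/2)/2` (exact identity:
#' `sin(theta)/sqrt(1 - cos(theta)) = sqrt(2) cos(theta/2)`), so the
#' integrand is smooth and the quadrature uncontaminated by the apparent
#' pole.
#'
#' @inheritParams potential_quadrature
#' @return list with `value`, `flagged`, `abs_error`.
#' @export
ez_pole_quadrature <- function(frame, g, sigma = frame$sigma,
                               spec = quadrature_spec()) {
  fn <- function(th, phi)
    sigma_at(th, phi, frame, g, sigma) * cos(th / 2) / 2
  patch_quad(fn, frame, g, spec)
}

#' Radial on-sphere field, quadrature oracle
#'
#' `E_r = (1/2) int int sigma / sqrt(2 - 2 rhat_tilde . rhat) sin(theta)
#' dtheta dphi` for an evaluation direction on the same sphere, strictly
#' outside the closed patch (the kernel is then bounded).
#'
#' @param direction unit 3-vector (canonical frame) of the on-sphere
#'   evaluation point.
#' @inheritParams potential_quadrature
#' @return list with `value`, `flagged`, `abs_error`.
#' @export
radial_field_quadrature <- function(direction, frame, g,
                                    sigma = frame$sigma,
                                    spec = quadrature_spec()) {
  direction <- direction / sqrt(sum(direction^2))
  fn <- function(th, phi) {
    cth <- direction[1] * sin(th) * cos(phi) +
      direction[2] * sin(th) * sin(phi) + direction[3] * cos(th)
    sigma_at(th, phi, frame, g, sigma) * sin(th) / (2 * sqrt(2 - 2 * cth))
  }
  patch_quad(fn, frame, g, spec)
}
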