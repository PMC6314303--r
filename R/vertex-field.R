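#' Field evaluation result
#'
#' Light container for a computed field or potential value: the number(s),
#' the method that produced them, the retained series order (if any), an
#' error estimate and which side of the surface the value refers to.
#'
#' @param value numeric scalar or 3-vector (units of a reference density,
#'   Gaussian units, R = 1 scaling).
#' @param method one of "series", "moment_expansion", "quadrature".
#' @param order retained beta order for series results, `NA` otherwise.
#' @param err_est nonnegative error estimate (truncation or quadrature).
#' @param side "above", "below" or "none".
#' @return object of class `field_evaluation`.
#' @export
field_evaluation <- function(value, method, order = NA_integer_,
                             err_est = 0, side = "none") {
  method <- match.arg(method, c("series", "moment_expansion", "quadrature"))
  side <- match.arg(side, c("none", "above", "below"))
  stopifnot(err_est >= 0)
  structure(list(value = value, method = method, order = order,
                 err_est = err_est, side = side),
            class = "field_evaluation")
}

#' @export
print.field_evaluation <- function(x, ...) {
  cat("<field evaluation> method =", x$method,
      if (!is.na(x$order)) paste0("(order ", x$order, ")"), "\n")
  cat("  value:", format(x$value, digits = 10), "\n")
  cat("  err_est:", format(x$err_est, digits = 3), " side:", x$side, "\n")
  invisible(x)
}

#' Axial field of a uniformly charged spherical cap
#'
#' Normal field at a point infinitesimally above or below the pole of a
#' uniformly charged cap `0 <= theta <= beta`:
#' `E_z = 2 pi sigma (sin(beta/2) + s)` in Gaussian units, with `s = +1`
#' above the surface, `-1` below and `0` for the principal-value (continuous)
#' part.  Reproduces the Gauss-law limits: a full sphere (`beta = pi`) gives
#' `4 pi sigma` outside and `0` inside.
#'
#' @param beta cap opening angle in `(0, pi]`.
#' @param side "above", "below" or "none".
#' @param sigma uniform surface charge density.
#' @return field value.
#' @export
cap_axial_field <- function(beta, side = c("above", "below", "none"),
                            sigma = 1) {
  side <- match.arg(side)
  stopifnot(beta > 0, beta <= pi)
  s <- switch(side, above = 1, below = -1, none = 0)
  2 * pi * sigma * (sin(beta / 2) + s)
}

#' Exact t-weighted vertex kernel integral at one azimuth
#'
#' The polar integral
#' `int_0^beta(phi) [sin(theta)/(2 sqrt(2) sqrt(1 - cos(theta)))] t(theta)
#' dtheta` in closed form (see [vertex_kernel_integral()]); multiplied by
#' `B(phi) = (sigma2 - sigma1) + lambda(phi) (sigma3 - sigma2)` and
#' integrated over phi it yields the density-difference part of the
#' continuous vertex field.  Falls back to quadrature (with a warning) when
#' the closed form's validity condition `eta cos(beta) > 1` fails.
#'
#' @param phi azimuth in `[0, alpha]`.
#' @param frame a `sph_frame`.
#' @param g a `sph_geodesic`.
#' @return value of the kernel integral.
#' @export
ez_theta_integral_exact <- function(phi, frame, g) {
  co <- interp_coefficients(phi, frame, g)
  v <- vertex_kernel_integral(co$C, co$D, co$beta)
  if (is.na(v)) {
    warning("eta cos(beta) <= 1 at phi = ", format(phi),
            "; falling back to quadrature for the theta integral")
    v <- stats::integrate(function(th)
      cos(th / 2) / 2 * t_of_theta(th, co$C, co$D),
      0, co$beta, rel.tol = 1e-12, abs.tol = 1e-16)$value
  }
  v
}

# series coefficients of the expansion in powers of 1/(a cos(phi - phi0)):
# sqrt((1 - cos beta)/2) = (1/(2 a c)) (1 - 3/8 x + 31/128 x^2 - 187/1024 x^3),
# x = 1/(a c)^2, for the pole-density part, and the Eq-34-type kernel
# (1/(a c)) [1/4 + (16 h - 19)/192 x + (640 h^2 - 216 h + 507)/7680 x^2 + ...]
# for the density-difference part (h the order-1 interpolation combination).
ez_sigma1_coefs <- c(1 / 2, -3 / 16, 31 / 256, -187 / 2048)      # p = 1,3,5,7
ez_B_coefs <- list(
  # each entry: coefficients of h^l at a given p, l = 0 .. (p-1)/2
  p1 = c(1 / 4),
  p3 = c(-19 / 192, 16 / 192),
  p5 = c(507 / 7680, -216 / 7680, 640 / 7680),
  p7 = c(-87637 / 1720320, 29280 / 1720320, -47488 / 1720320,
         186368 / 1720320))

# weight-channel decomposition of the continuous vertex field:
# value = sigma1 * parts[1] + (sigma2 - sigma1) * parts[2] +
#         (sigma3 - sigma2) * parts[3]
ez_series_parts <- function(frame, g, order,
                            sub = substitution_params(frame, g)) {
  p_list <- seq(1, order, by = 2)
  v_s1 <- 0
  for (i in seq_along(p_list))
    v_s1 <- v_s1 + ez_sigma1_coefs[i] *
      G_term(0, 0, 0, 0, 0, p_list[i], frame, g, sub)
  v_d0 <- 0; v_d1 <- 0
  for (i in seq_along(p_list)) {
    p <- p_list[i]
    coefs <- ez_B_coefs[[i]]
    for (l in seq_along(coefs) - 1L) {
      cf <- coefs[l + 1]
      k_max <- (order - p) %/% 2               # G(l,d,k,p) is O(beta^(p+2k))
      for (k in 0:k_max) {
        v_d0 <- v_d0 + cf * G_term(0, 0, l, 0, k, p, frame, g, sub)
        v_d1 <- v_d1 + cf * G_term(0, 0, l, 1, k, p, frame, g, sub)
      }
    }
  }
  c(v_s1, v_d0, v_d1)
}

#' Continuous normal field at the pole vertex, series evaluation
#'
#' Series evaluation of the continuous part of the normal field at the
#' patch's pole vertex, in powers of (side arc x curvature).  `order = r`
#' retains every term of total order `beta^r`: the secant-expansion terms of
#' the pole-density part and, for the density-difference part, all G terms
#' with `p + 2k <= r`.  The truncation error estimate is the magnitude of
#' the first dropped order.
#'
#' Note the order is counted in powers of the patch size alone; no smallness
#' is assumed for the differences between vertex densities, so the stated
#' order holds for arbitrary density triples (when neighbouring densities
#' differ by O(beta), as for a continuous surface density, the effective
#' accuracy is one order better).
#'
#' @param frame a `sph_frame`.
#' @param g a `sph_geodesic`.
#' @param sigma vertex densities (canonical order); defaults to
#'   `frame$sigma`.
#' @param order retained beta order: 1, 3, 5 or 7.
#' @param beta_max largest side arc admitted to series mode (radians).
#' @return a `field_evaluation` (side = "none": continuous part only).
#' @export
ez_continuous <- function(frame, g, sigma = frame$sigma, order = 3,
                          beta_max = 0.35) {
  if (is.null(sigma)) stop("no vertex densities available")
  if (!order %in% c(1, 3, 5, 7)) stop("order must be 1, 3, 5 or 7")
  arcs <- c(g$beta1, frame$beta2, frame$beta3)
  if (max(arcs) > beta_max)
    stop("patch too large for series mode (max side arc ",
         format(max(arcs), digits = 3), " > beta_max = ", beta_max,
         "); use the quadrature oracle (ez_pole_quadrature)")
  parts <- ez_series_parts(frame, g, order)
  value <- sigma[1] * parts[1] + (sigma[2] - sigma[1]) * parts[2] +
    (sigma[3] - sigma[2]) * parts[3]

  # error estimate: first dropped order ~ beta^(order+2) scale of the leading
  # retained magnitude
  bmax <- max(arcs)
  err <- abs(value) * bmax^2 *
    max(abs(c(1, (sigma[2] - sigma[1]) / max(abs(sigma[1]), 1),
              (sigma[3] - sigma[2]) / max(abs(sigma[1]), 1))))
  field_evaluation(value, "series", order = as.integer(order), err_est = err)
}

#' Normal field just above or below a shared vertex
#'
#' Sums the continuous vertex-field contributions of all patches meeting at
#' a common vertex and adds the surface discontinuity `+2 pi sigma_vertex`
#' (above) or `-2 pi sigma_vertex` (below).  All patches must carry
#' densities that agree at the shared vertex.
#'
#' @param patches list of `sph_triangle` objects sharing the vertex, each
#'   with `sigma` set.
#' @param vertex the shared vertex direction (unit 3-vector) or, for a
#'   single patch, a vertex index 1:3.
#' @param side "above" or "below" the surface.
#' @param order series order passed to [ez_continuous()].
#' @param method "series", "quadrature" or "auto" (series where the arcs
#'   admit it, quadrature otherwise).
#' @param beta_max series admission threshold (radians).
#' @return a `field_evaluation`; `value` is the normal (radial) field
#'   component at the vertex.
#' @export
ez_at_vertex <- function(patches, vertex, side = c("above", "below"),
                         order = 3, method = c("auto", "series", "quadrature"),
                         beta_max = 0.35) {
  side <- match.arg(side)
  method <- match.arg(method)
  if (inherits(patches, "sph_triangle")) patches <- list(patches)
  if (length(vertex) == 1)
    vertex <- patches[[1]]$vertices[as.integer(vertex), ]
  vertex <- vertex / sqrt(sum(vertex^2))

  sig_v <- NULL
  total <- 0; err <- 0
  for (p in patches) {
    dots <- as.numeric(p$vertices %*% vertex)
    iv <- which.max(dots)
    if (dots[iv] < 1 - 1e-10)
      stop("a patch does not contain the shared vertex")
    if (is.null(p$sigma)) stop("patch without vertex densities")
    if (is.null(sig_v)) sig_v <- p$sigma[iv]
    else if (abs(p$sigma[iv] - sig_v) > 1e-10 * max(1, abs(sig_v)))
      stop("inconsistent densities at the shared vertex: ",
           format(sig_v), " vs ", format(p$sigma[iv]))
    fr <- canonicalize(p, iv)
    g <- geodesic_params(fr)
    use_series <- method == "series" ||
      (method == "auto" && max(g$beta1, fr$beta2, fr$beta3) <= beta_max)
    if (use_series) {
      fe <- ez_continuous(fr, g, order = order, beta_max = Inf)
      total <- total + fe$value; err <- err + fe$err_est
    } else {
      qr <- ez_pole_quadrature(fr, g)
      total <- total + qr$value; err <- err + qr$abs_error
    }
  }
  jump <- if (side == "above") 2 * pi * sig_v else -2 * pi * sig_v
  field_evaluation(total + jump,
                   if (method == "quadrature") "quadrature" else "series",
                   order = as.integer(order), err_est = err, side = side)
}
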