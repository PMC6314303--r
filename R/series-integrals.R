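#' Substitution parameters for the rational-integrand form
#'
#' Shorthand quantities used by the half-angle substitution x = tan(phi/2)
#' that turns every azimuthal series integral into a rational integrand:
#' `A = sin(beta3)`, `B1 = sin(beta2) sin(alpha)`, `B2 = -sin(beta2) cos(alpha)`,
#' `mu = B2/B1 = -cot(alpha)`, `tau = tan(phi0)`, `tau_prime = (A + B2)/B1`
#' and `x_max = tan(alpha/2)`.  `tau_prime - tau` is of order beta^2; the
#' denominator factor `f(x) = 1 - x^2 + 2 tau x` stays of order 1 on
#' `[0, x_max]`.
#'
#' @param frame a `sph_frame`.
#' @param g a `sph_geodesic`.
#' @return list of the parameters above (all dimensionless).
#' @export
substitution_params <- function(frame, g) {
  A <- sin(frame$beta3)
  B1 <- sin(frame$beta2) * sin(frame$alpha)
  B2 <- -sin(frame$beta2) * cos(frame$alpha)
  list(A = A, B1 = B1, B2 = B2, mu = B2 / B1, tau = tan(g$phi0),
       tau_prime = (A + B2) / B1, x_max = tan(frame$alpha / 2))
}

dbl_factorial <- function(n) if (n <= 0) 1 else prod(seq(n, 1, by = -2))

#' Odd-power secant integral
#'
#' Closed form of `int_0^alpha sec^(2l+1)(phi - phi0) dphi`, the building
#' block of the leading series terms: a log plus a finite sum, evaluated
#' between `y = -sin(phi0)` and `y = sin(alpha - phi0)`.
#'
#' @param l nonnegative integer.
#' @param phi0,alpha geodesic offset and opening (radians); `cos(phi - phi0)`
#'   must stay positive on `[0, alpha]`.
#' @return value of the integral.
#' @export
sec_odd_integral <- function(l, phi0, alpha) {
  stopifnot(l >= 0, l == round(l))
  if (cos(-phi0) <= 0 || cos(alpha - phi0) <= 0)
    stop("integrand pole inside [0, alpha]: cos(phi - phi0) changes sign")
  antider <- function(y) {
    v <- dbl_factorial(2 * l - 1) / (2^(l + 1) * factorial(l)) *
      log((1 + y) / (1 - y))
    if (l >= 1)
      for (p in 0:(l - 1))
        v <- v + dbl_factorial(2 * l - 1) * factorial(l - p - 1) /
          (2^(p + 1) * factorial(l) * dbl_factorial(2 * l - 1 - 2 * p)) *
          y / (1 - y^2)^(l - p)
    v
  }
  antider(sin(alpha - phi0)) - antider(-sin(phi0))
}

#' Azimuthal series integrals, direct quadrature
#'
#' The F family
#' `F[nc,ns](l,d,p) = int_0^alpha h~^l lambda^d cos^nc(phi) sin^ns(phi)
#'  / (a^p cos^p(phi - phi0)) dphi`
#' with `h~ = zeta23 lambda (1 - lambda) a^2 cos^2(phi - phi0)`, evaluated by
#' adaptive quadrature of the defining integrand.  `F` is of order beta^p
#' under uniform patch scaling.
#'
#' @param nc,ns nonnegative integer powers of cos(phi), sin(phi).
#' @param l,d integers, `l >= 0`, `d` in 0:1.
#' @param p integer power of `a cos(phi - phi0)`.
#' @param frame a `sph_frame`.
#' @param g a `sph_geodesic`.
#' @param rel_tol relative tolerance of the quadrature.
#' @return value of the integral.
#' @export
F_direct <- function(nc, ns, l, d, p, frame, g, rel_tol = 1e-12) {
  zeta <- frame$zeta23
  f <- function(phi) {
    lam <- lambda_of_phi(phi, frame)
    acp <- g$a * cos(phi - g$phi0)
    (zeta * lam * (1 - lam) * acp^2)^l * lam^d *
      cos(phi)^nc * sin(phi)^ns / acp^p
  }
  stats::integrate(f, 0, frame$alpha, rel.tol = rel_tol,
                   abs.tol = 1e-15, subdivisions = 200L)$value
}

#' Single term of the rational-integrand expansion of F
#'
#' The G family: the k-th term of the expansion of `F[nc,ns](l,d,p)` in
#' powers of `tau_prime - tau` (order beta^2 each), written as an integral of
#' a rational function of `x = tan(phi/2)` over `[0, tan(alpha/2)]`.
#' `G[nc,ns](l,d,k,p)` is of order `beta^(p + 2k)`.  For `l = d = 0` the
#' `k = 0` term is exact and all higher terms vanish.
#'
#' @inheritParams F_direct
#' @param k nonnegative expansion index.
#' @param sub substitution parameters, defaults to
#'   `substitution_params(frame, g)`.
#' @return value of the term.
#' @export
G_term <- function(nc, ns, l, d, k, p, frame, g,
                   sub = substitution_params(frame, g), rel_tol = 1e-12) {
  stopifnot(k >= 0, l >= 0, d %in% 0:1)
  if (l == 0 && d == 0 && k > 0) return(0)
  pref <- 2 * frame$zeta23^l * (2 * sub$A / sub$B1)^(l + d + k) *
    (g$a * cos(g$phi0))^(2 * l - p) *
    (-1)^k * choose(2 * l + d + k - 1, k) *
    (1 - cos(frame$beta2) / cos(frame$beta3))^k
  mu <- sub$mu; tau <- sub$tau
  f <- function(x)
    2^ns * x^(l + d + k + ns) * (1 - x^2)^nc * (1 - x^2 + 2 * mu * x)^l /
      ((1 - x^2 + 2 * tau * x)^(p + d + k) *
         (1 + x^2)^(2 * l - p + 1 + nc + ns))
  pref * stats::integrate(f, 0, sub$x_max, rel.tol = rel_tol,
                          abs.tol = 1e-15, subdivisions = 200L)$value
}

#' Truncated series evaluation of F
#'
#' Sums G terms `k = 0 .. floor((target_order - p)/2)`, the truncation that
#' retains every contribution up to `beta^target_order`: a `p = 5` integral
#' needs only `k = 0`, `p = 3` needs `k <= 1`, `p = 1` needs `k <= 2` for
#' order-5 accuracy.  For `l = d = 0` a single term is exact.
#'
#' @inheritParams G_term
#' @param target_order retained beta order (>= p).
#' @return list with `value`, `k_max`, and the individual `terms`.
#' @export
F_series <- function(nc, ns, l, d, p, target_order, frame, g,
                     sub = substitution_params(frame, g)) {
  stopifnot(target_order >= p)
  k_max <- if (l == 0 && d == 0) 0L else as.integer((target_order - p) %/% 2)
  terms <- vapply(0:k_max, function(k)
    G_term(nc, ns, l, d, k, p, frame, g, sub), numeric(1))
  list(value = sum(terms), k_max = k_max, terms = terms)
}
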