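# Exact polar (theta) integrals of the projection-weighted integrands.
#
# Everything here reduces integrals of the form
#   int_0^beta sin^n(theta) cos^m(theta) t(theta) dtheta,
#   t(theta) = sin(theta) / (C sin(theta) + D cos(theta)),
# and the vertex-field kernel integral to finite elementary formulas.  The
# engine rewrites the numerator in the basis P = C sin + D cos,
# P' = C cos - D sin (so sin = (C P - D P')/E^2, cos = (D P + C P')/E^2 with
# E^2 = C^2 + D^2), divides by P, and integrates term by term: P^j P'^k are
# trig polynomials in psi = theta + gamma (gamma = atan2(D, C),
# P = E sin(psi)), while the 1/P remainders give log terms.

# antiderivative of sin^k(psi)
sin_pow_antider <- function(k, psi) {
  if (k == 0) return(psi)
  if (k == 1) return(-cos(psi))
  -cos(psi) * sin(psi)^(k - 1) / k + (k - 1) / k * sin_pow_antider(k - 2, psi)
}

# int_lo^hi sin^p(psi) cos^q(psi) dpsi
sin_cos_int <- function(p, q, lo, hi) {
  if (q %% 2 == 1) {
    v <- (q - 1) %/% 2
    anti <- function(psi) {
      s <- sin(psi)
      sum(vapply(0:v, function(u) choose(v, u) * (-1)^u *
                   s^(p + 2 * u + 1) / (p + 2 * u + 1), numeric(1)))
    }
    return(anti(hi) - anti(lo))
  }
  v <- q %/% 2
  sum(vapply(0:v, function(u) choose(v, u) * (-1)^u *
               (sin_pow_antider(p + 2 * u, hi) -
                  sin_pow_antider(p + 2 * u, lo)), numeric(1)))
}

#' Elementary polar moment of the patch slice
#'
#' `int_0^beta sin^n(theta) cos^m(theta) dtheta` for small nonnegative
#' integer powers; used for the pole-density parts of the charge moments.
#'
#' @param n,m nonnegative integer powers.
#' @param beta upper limit (radians).
#' @return value of the integral.
#' @export
sin_cos_moment <- function(n, m, beta) sin_cos_int(n, m, 0, beta)

# int cos^q(psi)/sin(psi) dpsi over [lo, hi], by the reduction
# c^q/s = c^(q-2)/s - c^(q-2) s
cos_over_sin_int <- function(q, lo, hi) {
  if (q == 0) return(log(tan(hi / 2)) - log(tan(lo / 2)))
  if (q == 1) return(log(sin(hi)) - log(sin(lo)))
  cos_over_sin_int(q - 2, lo, hi) - sin_cos_int(1, q - 2, lo, hi)
}

# anchor: K(i, 0) = int_0^beta sin^i(theta) / P dtheta, P = E sin(theta+gam),
# expanded with sin(theta) = sin(psi)cos(gam) - cos(psi)sin(gam)
K_anchor <- function(i, C, D, beta) {
  E <- sqrt(C^2 + D^2)
  gam <- atan2(D, C)
  lo <- gam; hi <- gam + beta
  if (hi >= pi) stop("theta range leaves the validity domain of the reduction")
  cg <- C / E; sg <- D / E
  total <- 0
  for (k in 0:i) {
    coef <- choose(i, k) * cg^(i - k) * (-sg)^k
    total <- total + coef *
      (if (i - k >= 1) sin_cos_int(i - k - 1, k, lo, hi)
       else cos_over_sin_int(k, lo, hi))
  }
  total / E
}

#' Exact t-weighted polar integral
#'
#' Closed-form value of
#' `int_0^beta sin^n(theta) cos^m(theta) t(theta) dtheta` with
#' `t = sin/(C sin + D cos)`, for `n >= 1`.  Writes the integral as
#' `K(n+1, m) = int sin^(n+1) cos^m / P dtheta` and reduces the cosine power
#' through `K(i, j) = M(i, j-1)/D - (C/D) K(i+1, j-1)` (with `M` the
#' elementary moments), whose multiplier `C/D = O(beta)` keeps the recursion
#' numerically stable; the all-sine anchors are evaluated in the shifted
#' angle `psi = theta + atan2(D, C)`, where `P` is a pure sine.  These are
#' the polar integrals behind the exact (non-series) charge moments.
#'
#' @param n integer >= 1; power of sin(theta) multiplying `t(theta)`.
#' @param m nonnegative integer power of cos(theta).
#' @param C,D slice coefficients (positive in the patch interior).
#' @param beta upper limit, in `(0, pi - atan2(D, C))`.
#' @return value of the integral.
#' @export
theta_ratio_integral <- function(n, m, C, D, beta) {
  stopifnot(n >= 1, m >= 0, C > 0, D > 0)
  K <- function(i, j) {
    if (j == 0) return(K_anchor(i, C, D, beta))
    sin_cos_moment(i, j - 1, beta) / D - (C / D) * K(i + 1, j - 1)
  }
  K(n + 1L, m)
}

#' Exact vertex-kernel polar integral
#'
#' Closed form of the t-weighted kernel integral of the normal field at the
#' pole,
#' `int_0^beta [sin(theta) / (2 sqrt(2) sqrt(1 - cos(theta)))] t(theta) dtheta`,
#' derived by the substitutions `u = sqrt(1 -+ cos(theta))` which reduce both
#' halves to rational integrals.  Valid while `eta cos(beta) > 1` with
#' `eta^2 = (C^2 + D^2)/C^2`; outside that region the function returns `NA`
#' and callers fall back to quadrature.
#'
#' @param C,D slice coefficients.
#' @param beta upper limit (radians).
#' @return value of the integral, or `NA_real_` if the validity condition
#'   fails.
#' @export
vertex_kernel_integral <- function(C, D, beta) {
  E2 <- C^2 + D^2
  E <- sqrt(E2)
  if (C * cos(beta) <= 0 || E * cos(beta) <= C) return(NA_real_)  # eta cos(beta) <= 1
  m1 <- 1 - C / E
  m2 <- 1 + C / E
  u0 <- sqrt(2) * sin(beta / 2)   # sqrt(1 - cos beta) < sqrt(m1)
  u1 <- sqrt(2) * cos(beta / 2)   # sqrt(1 + cos beta) > sqrt(m2)
  s1 <- sqrt(m1); s2 <- sqrt(m2)

  p1 <- C / (sqrt(2) * E2) * u0 +
    D^2 / (2 * sqrt(2) * E^3) *
      (log((s2 + u0) / (s2 - u0)) / (2 * s2) -
         log((s1 + u0) / (s1 - u0)) / (2 * s1))

  A2 <- m2 * (m2 - 1) / (m2 - m1)
  B2 <- m1 * (m1 - 1) / (m2 - m1)
  i_m2 <- (log((sqrt(2) + s2) / (sqrt(2) - s2)) -
             log((u1 + s2) / (u1 - s2))) / (2 * s2)
  i_m1 <- (log((sqrt(2) - s1) / (sqrt(2) + s1)) -
             log((u1 - s1) / (u1 + s1))) / (2 * s1)
  p2 <- -D / (sqrt(2) * E2) * (-(sqrt(2) - u1) + A2 * i_m2 + B2 * i_m1)

  p1 + p2
}
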