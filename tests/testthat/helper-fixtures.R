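# shared builders for the test suite (everything generated in code)

# canonical-position triangle: pole, (beta3, 0), (beta2, alpha)
mk_tri <- function(beta2, beta3, alpha, sigma = NULL, rot = diag(3)) {
  v <- rbind(c(0, 0, 1),
             c(sin(beta3), 0, cos(beta3)),
             c(sin(beta2) * cos(alpha), sin(beta2) * sin(alpha), cos(beta2)))
  v <- t(rot %*% t(v))
  v <- v / sqrt(rowSums(v^2))
  spherical_triangle(v, sigma = sigma)
}

# deterministic random proper rotation
rand_rotation <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 3] <- -R[, 3]
  R
}

# great-arc midpoint
arc_mid <- function(a, b) {
  m <- a + b
  m / sqrt(sum(m^2))
}

# frame + geodesic in one go
fg <- function(tri, pole = 1L) {
  fr <- canonicalize(tri, pole)
  list(fr = fr, g = geodesic_params(fr))
}
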