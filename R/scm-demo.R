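# Demonstration boundary solve: induced surface charge on a single
# dielectric sphere with an interior point charge, discretized with curved
# patches.  The boundary condition is the standard dielectric-interface
# condition: with the potential represented as the source term q/(eps_in r)
# plus the single-layer potential of the induced density sigma, continuity
# of the normal displacement eps E_n across the surface gives
#   sigma = f * E_c,   f = (eps_in - eps_out) / (2 pi (eps_in + eps_out)),
# where E_c is the continuous (principal-value) normal field at the surface
# point: source field plus the field of sigma itself, the +-2 pi sigma jump
# having been absorbed into f.  Collocating at mesh vertices yields the
# dense linear system (I - f K) sigma = f E_src.

# Gauss-Legendre nodes/weights on [0, 1] (Golub-Welsch), cached
gauss_legendre01 <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    k <- seq_len(n - 1)
    b <- k / sqrt(4 * k^2 - 1)
    J <- diag(0, n)
    J[cbind(k, k + 1)] <- b
    J[cbind(k + 1, k)] <- b
    e <- eigen(J, symmetric = TRUE)
    x <- (e$values + 1) / 2
    w <- (e$vectors[1, ])^2
    out <- list(x = x, w = w)   # weights sum to 1 on [0,1]
    cache[[key]] <<- out
    out
  }
})

# basis-decomposed kernel integrals over one canonical patch by tensor
# Gauss-Legendre: returns the three per-slot values of
# int int kernel(rhat) * w_slot(theta, phi) sin(theta) dtheta dphi with
# w_slot the interpolation basis (1 - t, t (1 - lambda), t lambda).
# kernel_fn(X, Y, Z, ...) is vectorized over the node grid.
patch_basis_gauss <- function(frame, g, kernel_fn, n_phi = 12, n_th = 12) {
  gl_p <- gauss_legendre01(n_phi)
  gl_t <- gauss_legendre01(n_th)
  phis <- gl_p$x * frame$alpha
  out <- c(0, 0, 0)
  for (ip in seq_along(phis)) {
    phi <- phis[ip]
    co <- interp_coefficients(phi, frame, g)
    th <- gl_t$x * co$beta
    tt <- t_of_theta(th, co$C, co$D)
    st <- sin(th)
    kv <- kernel_fn(st * cos(phi), st * sin(phi), cos(th))
    wts <- gl_t$w * co$beta * st * kv
    wp <- gl_p$w[ip] * frame$alpha
    out <- out + wp * c(sum(wts * (1 - tt)),
                        sum(wts * tt * (1 - co$lambda)),
                        sum(wts * tt * co$lambda))
  }
  out
}

#' Dielectric-sphere scene
#'
#' A single dielectric sphere (unit radius, centred at the origin) with
#' relative permittivity `eps_in` inside and `eps_out` outside, a point
#' charge inside or outside (off the surface), and an icosphere
#' discretization level.
#'
#' @param eps_in,eps_out relative permittivities (> 0).
#' @param charge point charge value.
#' @param charge_pos charge position (3-vector, `|pos| != 1`).
#' @param level icosphere subdivision level.
#' @return object of class `scm_scene`.
#' @export
dielectric_scene <- function(eps_in, eps_out, charge = 1,
                             charge_pos = c(0, 0, 0.5), level = 3L) {
  stopifnot(eps_in > 0, eps_out > 0)
  r <- sqrt(sum(charge_pos^2))
  if (abs(r - 1) < 1e-6) stop("charge on the surface")
  structure(list(eps_in = eps_in, eps_out = eps_out, charge = charge,
                 charge_pos = as.numeric(charge_pos),
                 level = as.integer(level)),
            class = "scm_scene")
}

#' Solve for the induced surface charge
#'
#' Assembles and solves the collocation system for the vertex values of the
#' induced surface charge density on the sphere.  Patch contributions to the
#' continuous normal field at each collocation vertex are computed by the
#' series vertex field for patches containing the vertex, by the
#' second-order moment expansion where its convergence criterion holds, and
#' by fixed-order Gauss quadrature of the kernel otherwise - exercising the
#' full evaluation hierarchy of the patch machinery.
#'
#' @param scene a `scm_scene`.
#' @param order series order for the vertex field.
#' @param beta_max series admission threshold; larger meshes (levels 0-1)
#'   fall back to Gauss quadrature automatically.
#' @param n_gauss nodes per dimension of the near-field Gauss rule.
#' @return object of class `scm_solution`: `sigma` (vertex densities),
#'   `mesh`, `residual` (max norm of the discrete boundary condition),
#'   `total_induced` (surface integral of sigma), `scene`.
#' @export
assemble_and_solve <- function(scene, order = 3, beta_max = 0.35,
                               n_gauss = 12) {
  stopifnot(inherits(scene, "scm_scene"))
  mesh <- build_icosphere(scene$level)
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  V <- mesh$vertices
  f_fac <- (scene$eps_in - scene$eps_out) /
    (2 * pi * (scene$eps_in + scene$eps_out))
  if (abs(f_fac) < 1e-15) {
    sig <- rep(0, nv)
    return(structure(list(sigma = sig, mesh = mesh, residual = 0,
                          total_induced = 0, scene = scene),
                     class = "scm_solution"))
  }

  K <- matrix(0, nv, nv)
  q0_basis <- matrix(0, nf, 3)    # per-face per-slot total charge
  gid_basis <- matrix(0L, nf, 3)  # global vertex id per canonical slot
  for (k in seq_len(nf)) {
    ids <- mesh$faces[k, ]
    tri <- spherical_triangle(V[ids, ])
    fr <- canonicalize(tri, 1L)
    g <- geodesic_params(fr)
    gids <- ids[fr$perm]          # global vertex id per canonical slot
    arcs_ok <- max(g$beta1, fr$beta2, fr$beta3) <= beta_max

    # per-slot moments (world frame)
    if (arcs_ok) {
      parts <- series_moment_parts(fr, g)
      ch <- list(parts$s1, parts$d0, parts$d1)
      # canonical slots: slot1 = s1 - d0, slot2 = d0 - d1, slot3 = d1
      Wm <- rbind(c(1, -1, 0), c(0, 1, -1), c(0, 0, 1))
      slot_mom <- lapply(1:3, function(s) {
        m <- list(q0 = 0, m1 = c(0, 0, 0), m2 = matrix(0, 3, 3),
                  t = parts$t, A = parts$A)
        for (c_i in 1:3) {
          w <- Wm[s, c_i]
          if (w != 0) {
            m$q0 <- m$q0 + w * ch[[c_i]]$q0
            m$m1 <- m$m1 + w * ch[[c_i]]$m1
            m$m2 <- m$m2 + w * ch[[c_i]]$m2
          }
        }
        m
      })
    } else {
      # large faces (coarse meshes): slot moments by Gauss quadrature
      A <- patch_area(fr, g)
      t_ave <- direction_average(fr, g)
      q0s <- patch_basis_gauss(fr, g, function(X, Y, Z) rep(1, length(X)),
                               n_gauss, n_gauss)
      m1s <- lapply(1:3, function(i)
        patch_basis_gauss(fr, g, function(X, Y, Z) switch(i, X, Y, Z),
                          n_gauss, n_gauss))
      m2s <- list()
      cmb <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
      for (r in 1:6) {
        i <- cmb[r, 1]; j <- cmb[r, 2]
        m2s[[r]] <- patch_basis_gauss(fr, g, function(X, Y, Z) {
          u <- switch(i, X, Y, Z); v <- switch(j, X, Y, Z); u * v
        }, n_gauss, n_gauss)
      }
      slot_mom <- lapply(1:3, function(s) {
        m2 <- matrix(0, 3, 3)
        for (r in 1:6) {
          i <- cmb[r, 1]; j <- cmb[r, 2]
          m2[i, j] <- m2[j, i] <- m2s[[r]][s]
        }
        list(q0 = q0s[s], m1 = c(m1s[[1]][s], m1s[[2]][s], m1s[[3]][s]),
             m2 = m2, t = direction_average(fr, g), A = A)
      })
    }
    slot_world <- lapply(slot_mom, function(m)
      moments_to_world(structure(m, class = "sph_moments"), fr))
    q0_basis[k, ] <- vapply(slot_world, `[[`, numeric(1), "q0")
    gid_basis[k, ] <- gids

    # classify collocation vertices
    dots12 <- c(sum(V[ids[1], ] * V[ids[2], ]),
                sum(V[ids[1], ] * V[ids[3], ]),
                sum(V[ids[2], ] * V[ids[3], ]))
    rhs_crit <- 2 * (1 - min(dots12))
    vc <- colMeans(V[ids, ])
    lhs_crit <- 1 - as.numeric(V %*% vc)
    incident <- ids
    far <- which(lhs_crit > rhs_crit)
    far <- setdiff(far, incident)
    near <- setdiff(seq_len(nv), c(far, incident))

    # far vertices: vectorized on-sphere moment expansion per slot
    if (length(far)) {
      dirs <- V[far, , drop = FALSE]
      for (s in 1:3) {
        m <- slot_world[[s]]
        tv <- as.numeric(m$t)
        c0 <- as.numeric(dirs %*% tv)
        u1 <- as.numeric(dirs %*% (m$m1 - m$q0 * tv))
        M2c <- m$m2 - tcrossprod(m$m1, tv) - tcrossprod(tv, m$m1) +
          m$q0 * tcrossprod(tv)
        u2 <- rowSums((dirs %*% M2c) * dirs)
        om <- 1 - c0
        K[far, gids[s]] <- K[far, gids[s]] +
          (m$q0 + u1 / (2 * om) + 3 * u2 / (8 * om^2)) / (2 * sqrt(2 * om))
      }
    }

    # near (criterion fails, not a face vertex): Gauss quadrature of the
    # bounded kernel, all three slots at once
    if (length(near)) {
      for (j in near) {
        dir_c <- as.numeric(fr$rotation %*% V[j, ])
        kv <- patch_basis_gauss(fr, g, function(X, Y, Z) {
          cth <- dir_c[1] * X + dir_c[2] * Y + dir_c[3] * Z
          1 / (2 * sqrt(pmax(2 - 2 * cth, 1e-30)))
        }, n_gauss, n_gauss)
        K[j, gids] <- K[j, gids] + kv
      }
    }

    # incident vertices: series vertex field (or regularized Gauss when the
    # patch is too large for the series)
    for (s in 1:3) {
      j <- gids[s]
      frv <- canonicalize(tri, fr$perm[s])
      gv <- geodesic_params(frv)
      if (max(gv$beta1, frv$beta2, frv$beta3) <= beta_max) {
        pz <- ez_series_parts(frv, gv, order)
        coef <- c(pz[1] - pz[2], pz[2] - pz[3], pz[3])  # canonical slots of frv
      } else {
        # regularized vertex kernel at the pole: cos(theta/2)/2; the sin(theta)
        # Jacobian applied by patch_basis_gauss is divided back out
        coef <- patch_basis_gauss(frv, gv, function(X, Y, Z)
          sqrt(pmax((1 + Z) / 2, 0)) / (2 * pmax(sqrt(1 - Z^2), 1e-300)),
          n_gauss, n_gauss)
      }
      K[j, ids[frv$perm]] <- K[j, ids[frv$perm]] + coef
    }
  }

  # source normal field at the vertices: E_src = (q/eps_in) rhat.(r - r0)/|r - r0|^3
  dvec <- sweep(V, 2, scene$charge_pos)
  dn3 <- (rowSums(dvec^2))^1.5
  E_src <- scene$charge / scene$eps_in * rowSums(V * dvec) / dn3

  A_sys <- diag(nv) - f_fac * K
  sig <- solve(A_sys, f_fac * E_src)
  residual <- max(abs(sig - f_fac * (as.numeric(K %*% sig) + E_src)))

  total <- sum(sig[gid_basis] * q0_basis)

  structure(list(sigma = sig, mesh = mesh, residual = residual,
                 total_induced = total, scene = scene),
            class = "scm_solution")
}

#' @export
print.scm_solution <- function(x, ...) {
  cat("<scm solution> level", x$mesh$level, ":", length(x$sigma),
      "vertex densities\n")
  cat("  residual:", format(x$residual, digits = 3),
      " total induced charge:", format(x$total_induced, digits = 8), "\n")
  invisible(x)
}

#' Analytic induced surface charge (Legendre series)
#'
#' Classical series solution for a point charge `q` on the z-axis at
#' distance `d < 1` inside a unit dielectric sphere (`eps_in` inside,
#' `eps_out` outside):
#' `sigma(theta) = sum_l (2l+1)(l+1) q d^l (eps_in - eps_out) P_l(cos theta)
#'  / (4 pi eps_in [eps_in l + eps_out (l+1)])`.
#'
#' @param ctheta cos(theta) value(s) at which to evaluate.
#' @param q charge.
#' @param d charge distance from the centre (0 <= d < 1).
#' @param eps_in,eps_out permittivities.
#' @param n_terms number of Legendre terms.
#' @return sigma value(s).
#' @export
legendre_induced_sigma <- function(ctheta, q, d, eps_in, eps_out,
                                   n_terms = 50) {
  stopifnot(d >= 0, d < 1)
  out <- numeric(length(ctheta))
  Plm1 <- rep(1, length(ctheta))       # P_0
  Pl <- ctheta                         # P_1
  for (l in 0:(n_terms - 1)) {
    P <- if (l == 0) Plm1 else if (l == 1) Pl else {
      Pn <- ((2 * l - 1) * ctheta * Pl - (l - 1) * Plm1) / l
      Plm1 <- Pl; Pl <- Pn
      Pn
    }
    out <- out + (2 * l + 1) * (l + 1) * d^l * P /
      (eps_in * l + eps_out * (l + 1))
  }
  q * (eps_in - eps_out) / (4 * pi * eps_in) * out
}

#' Relative L2 error of an SCM solution against the Legendre series
#'
#' Area-weighted relative L2 distance between the computed vertex densities
#' and the analytic solution evaluated at the vertices (charge must lie on
#' the z-axis).
#'
#' @param sol a `scm_solution`.
#' @param n_terms Legendre terms for the reference.
#' @return relative L2 error (scalar).
#' @export
scm_l2_error <- function(sol, n_terms = 50) {
  sc <- sol$scene
  if (max(abs(sc$charge_pos[1:2])) > 1e-12)
    stop("analytic reference assumes the charge on the z-axis")
  ref <- legendre_induced_sigma(sol$mesh$vertices[, 3], sc$charge,
                                abs(sc$charge_pos[3]), sc$eps_in, sc$eps_out,
                                n_terms)
  # vertex weights: one third of incident face areas
  w <- numeric(length(sol$sigma))
  for (k in seq_len(nrow(sol$mesh$faces))) {
    ids <- sol$mesh$faces[k, ]
    fr <- canonicalize(spherical_triangle(sol$mesh$vertices[ids, ]), 1L)
    A <- patch_area(fr)
    w[ids] <- w[ids] + A / 3
  }
  sqrt(sum(w * (sol$sigma - ref)^2) / sum(w * ref^2))
}
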