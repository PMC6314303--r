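#' Geodesic icosphere mesh of spherical triangles
#'
#' Subdivided icosahedron on the unit sphere: every face is a spherical
#' triangle bounded by great arcs (edge midpoints are re-projected onto the
#' sphere at each subdivision), so the mesh faces satisfy the patch
#' invariants exactly and the face areas sum to the full sphere.
#'
#' @param level subdivision level (>= 0); the mesh has `20 * 4^level` faces
#'   and `10 * 4^level + 2` vertices.
#' @return object of class `sph_mesh`: list with `vertices` (n x 3 matrix of
#'   unit vectors), `faces` (m x 3 integer matrix, outward orientation:
#'   positive triple product), `level`.
#' @export
build_icosphere <- function(level = 0L) {
  level <- as.integer(level)
  stopifnot(level >= 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))

  if (level > 0) {
    for (lv in seq_len(level)) {
      nv <- nrow(v)
      edge_mid <- new.env(hash = TRUE)
      vlist <- list(v)
      midpoint <- function(i, j) {
        key <- paste(min(i, j), max(i, j))
        id <- edge_mid[[key]]
        if (!is.null(id)) return(id)
        m <- v[i, ] + v[j, ]
        m <- m / sqrt(sum(m^2))
        vlist[[length(vlist) + 1L]] <<- m
        nv <<- nv + 1L
        edge_mid[[key]] <- nv
        nv
      }
      newf <- matrix(0L, 4 * nrow(f), 3)
      for (k in seq_len(nrow(f))) {
        i1 <- f[k, 1]; i2 <- f[k, 2]; i3 <- f[k, 3]
        a <- midpoint(i1, i2); b <- midpoint(i2, i3); c <- midpoint(i3, i1)
        newf[4 * k - 3, ] <- c(i1, a, c)
        newf[4 * k - 2, ] <- c(i2, b, a)
        newf[4 * k - 1, ] <- c(i3, c, b)
        newf[4 * k, ] <- c(a, b, c)
      }
      v <- do.call(rbind, vlist)
      f <- newf
    }
  }
  # outward orientation
  for (k in seq_len(nrow(f)))
    if (det(v[f[k, ], ]) < 0) f[k, ] <- f[k, c(1, 3, 2)]
  structure(list(vertices = v, faces = f, level = level),
            class = "sph_mesh")
}

#' @export
print.sph_mesh <- function(x, ...) {
  cat("<icosphere mesh> level", x$level, ":", nrow(x$faces), "faces,",
      nrow(x$vertices), "vertices\n")
  invisible(x)
}

#' Extract one mesh face as a patch
#'
#' @param mesh a `sph_mesh`.
#' @param k face index.
#' @param sigma optional per-mesh-vertex density vector; the face's three
#'   values are attached to the patch.
#' @return a `sph_triangle`.
#' @export
mesh_face <- function(mesh, k, sigma = NULL) {
  ids <- mesh$faces[k, ]
  spherical_triangle(mesh$vertices[ids, ],
                     sigma = if (!is.null(sigma)) sigma[ids] else NULL)
}
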