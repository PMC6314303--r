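#' @importFrom jsonlite read_json write_json
#' @importFrom stats setNames
NULL

PATCH_SCHEMA <- "sphpatch-patches/1"

#' Read patches from a JSON descriptor file
#'
#' Reads the package's patch descriptor format: a schema tag, a list of
#' patch records (`center`, `radius`, `vertices` as three unit 3-vectors,
#' optional `sigma`), and an optional `mesh` block (`vertices`, 1-based
#' `faces` index triples, optional per-vertex `sigma`) whose faces are
#' loaded as additional patches.  Every triangle is validated on load;
#' violations are reported with the patch or vertex that caused them.
#'
#' @param path file path.
#' @return list of `sph_triangle` objects.
#' @export
read_patches <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema) || doc$schema != PATCH_SCHEMA)
    stop("not a ", PATCH_SCHEMA, " file: schema = ",
         if (is.null(doc$schema)) "<missing>" else doc$schema)
  out <- list()
  as_mat3 <- function(x, n_col = 3) {
    if (is.matrix(x)) return(x)
    matrix(unlist(x), ncol = n_col, byrow = TRUE)
  }
  if (!is.null(doc$patches) && length(doc$patches)) {
    recs <- doc$patches
    n <- length(recs$radius)
    centers <- as_mat3(recs$center)
    get_vv <- function(i) {
      v <- recs$vertices
      if (is.array(v) && length(dim(v)) == 3) return(matrix(v[i, , ], 3, 3))
      as_mat3(v[[i]])
    }
    get_sig <- function(i) {
      s <- recs$sigma
      if (is.null(s)) return(NULL)
      if (is.matrix(s)) return(s[i, ])
      as.numeric(s[[i]])
    }
    for (i in seq_len(n)) {
      tri <- tryCatch(
        spherical_triangle(get_vv(i), sigma = get_sig(i),
                           center = centers[i, ],
                           radius = recs$radius[i]),
        error = function(e) stop("patch ", i, ": ", conditionMessage(e),
                                 call. = FALSE))
      out[[length(out) + 1L]] <- tri
    }
  }
  if (!is.null(doc$mesh)) {
    mv <- as_mat3(doc$mesh$vertices)
    mf <- as_mat3(doc$mesh$faces)
    storage.mode(mf) <- "integer"
    if (any(mf < 1) || any(mf > nrow(mv)))
      stop("mesh face index out of range")
    ms <- doc$mesh$sigma
    for (k in seq_len(nrow(mf))) {
      tri <- tryCatch(
        spherical_triangle(mv[mf[k, ], ],
                           sigma = if (!is.null(ms)) ms[mf[k, ]]),
        error = function(e) stop("mesh face ", k, ": ", conditionMessage(e),
                                 call. = FALSE))
      out[[length(out) + 1L]] <- tri
    }
  }
  if (!length(out)) stop("no patches in file")
  out
}

#' Write patches to a JSON descriptor file
#'
#' Inverse of [read_patches()] for explicit patch lists; values are written
#' at full precision so a write/read round trip is loss-free.
#'
#' @param patches list of `sph_triangle` objects (or a single one).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_patches <- function(patches, path) {
  if (inherits(patches, "sph_triangle")) patches <- list(patches)
  recs <- list(
    center = do.call(rbind, lapply(patches, `[[`, "center")),
    radius = vapply(patches, `[[`, numeric(1), "radius"),
    vertices = lapply(patches, function(p)
      lapply(seq_len(3), function(i) p$vertices[i, ])))
  if (all(vapply(patches, function(p) !is.null(p$sigma), logical(1))))
    recs$sigma <- lapply(patches, `[[`, "sigma")
  jsonlite::write_json(list(schema = PATCH_SCHEMA, patches = recs), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a results report
#'
#' Serializes a named list of results (numbers, vectors, nested lists) to
#' JSON at full precision.
#'
#' @param results named list.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Fixture generation specification
#'
#' @param seed integer RNG seed.
#' @param n number of patches.
#' @param arc_range range (radians) that all three side arcs must fall in;
#'   `0 < min <= max < 0.5` keeps fixtures in the series regime.
#' @param sigma_range range of the vertex densities.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n = 10L, arc_range = c(0.02, 0.3),
                         sigma_range = c(-1, 1)) {
  stopifnot(arc_range[1] > 0, arc_range[1] <= arc_range[2],
            arc_range[2] < 0.5, n >= 1)
  structure(list(seed = as.integer(seed), n = as.integer(n),
                 arc_range = arc_range, sigma_range = sigma_range),
            class = "fixture_spec")
}

#' Generate random valid patches
#'
#' Seeded generator of random spherical-triangle patches with all three
#' side arcs inside `arc_range` (rejection sampling on the opposite side),
#' random orientation (uniform rotation) and uniform random vertex
#' densities.  Deterministic given the seed; the caller's RNG state is left
#' untouched.
#'
#' @param spec a `fixture_spec` (or an integer seed, with the remaining
#'   parameters at their defaults).
#' @param n,arc_range,sigma_range overrides when `spec` is a seed.
#' @return list of `sph_triangle` objects.
#' @export
generate_fixtures <- function(spec = fixture_spec(), n = NULL,
                              arc_range = NULL, sigma_range = NULL) {
  if (!inherits(spec, "fixture_spec"))
    spec <- fixture_spec(seed = spec,
                         n = if (is.null(n)) 10L else n,
                         arc_range = if (is.null(arc_range)) c(0.02, 0.3)
                         else arc_range,
                         sigma_range = if (is.null(sigma_range)) c(-1, 1)
                         else sigma_range)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  ar <- spec$arc_range
  out <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    repeat {
      b2 <- stats::runif(1, ar[1], ar[2])
      b3 <- stats::runif(1, ar[1], ar[2])
      alpha <- stats::runif(1, 0.2, pi - 0.2)
      cb1 <- cos(b2) * cos(b3) + sin(b2) * sin(b3) * cos(alpha)
      b1 <- acos(max(-1, min(1, cb1)))
      if (b1 >= ar[1] && b1 <= ar[2]) break
    }
    # uniform random rotation from a QR-orthonormalized Gaussian matrix
    M <- matrix(stats::rnorm(9), 3, 3)
    qr_ <- qr(M)
    R <- qr.Q(qr_)
    R <- R %*% diag(sign(diag(qr.R(qr_))))
    if (det(R) < 0) R[, 3] <- -R[, 3]
    v <- rbind(c(0, 0, 1),
               c(sin(b3), 0, cos(b3)),
               c(sin(b2) * cos(alpha), sin(b2) * sin(alpha), cos(b2)))
    v <- t(R %*% t(v))
    v <- v / sqrt(rowSums(v^2))
    out[[i]] <- spherical_triangle(
      v, sigma = stats::runif(3, spec$sigma_range[1], spec$sigma_range[2]))
  }
  out
}
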