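#' Two-hemisphere triangle-mesh container
#'
#' A light S3 container for a cortical surface: vertex coordinates in mm,
#' triangular faces, a per-vertex hemisphere label, and (optionally) the
#' per-vertex spherical parameterisation \eqn{(\theta, \phi)} used by the
#' harmonic decomposition.  All surfaces in one harmonic family share the
#' vertex count, ordering and topology, so per-vertex quantities are
#' comparable across surfaces.
#'
#' @param vertices Numeric `N x 3` matrix of coordinates (mm).
#' @param faces Integer `M x 3` matrix of 1-based vertex indices.
#' @param hemisphere Character or factor of length `N` with values
#'   `"left"`/`"right"`.
#' @param theta,phi Optional per-vertex spherical angles, one chart per
#'   hemisphere; `theta` in `[0, pi]`, `phi` in `[0, 2*pi]`.
#'
#' @return An object of class `cortical_mesh`.
#' @export
cortical_mesh <- function(vertices, faces, hemisphere,
                          theta = NULL, phi = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must have 3 columns", call. = FALSE)
  if (ncol(faces) != 3L) stop("`faces` must have 3 columns", call. = FALSE)
  n <- nrow(vertices)
  if (min(faces) < 1L || max(faces) > n) {
    stop("`faces` index vertices outside 1..N", call. = FALSE)
  }
  hemisphere <- as.character(hemisphere)
  if (length(hemisphere) != n || !all(hemisphere %in% c("left", "right"))) {
    stop("`hemisphere` must label every vertex as \"left\" or \"right\"",
         call. = FALSE)
  }
  if (!is.null(theta)) {
    stopifnot(length(theta) == n, length(phi) == n)
    eps <- 1e-9
    if (any(theta < -eps | theta > pi + eps)) {
      stop("`theta` must lie in [0, pi]", call. = FALSE)
    }
    if (any(phi < -eps | phi > 2 * pi + eps)) {
      stop("`phi` must lie in [0, 2*pi]", call. = FALSE)
    }
  }
  structure(
    list(vertices = vertices, faces = faces, hemisphere = hemisphere,
         theta = theta, phi = phi),
    class = "cortical_mesh"
  )
}

#' @export
print.cortical_mesh <- function(x, ...) {
  cat("<cortical_mesh> ", nrow(x$vertices), " vertices, ",
      nrow(x$faces), " faces (",
      sum(x$hemisphere == "left"), " left / ",
      sum(x$hemisphere == "right"), " right)",
      if (!is.null(x$theta)) ", parameterised" else "", "\n", sep = "")
  invisible(x)
}

#' Per-vertex spherical parameterisation as a tibble
#'
#' @param mesh A [cortical_mesh()] carrying `theta`/`phi`.
#' @return A tibble with columns `vertex`, `hemisphere`, `theta`, `phi`.
#' @export
mesh_parameterisation <- function(mesh) {
  stopifnot(inherits(mesh, "cortical_mesh"))
  if (is.null(mesh$theta)) {
    stop("mesh carries no spherical parameterisation", call. = FALSE)
  }
  tibble::tibble(
    vertex = seq_len(nrow(mesh$vertices)),
    hemisphere = mesh$hemisphere,
    theta = mesh$theta,
    phi = mesh$phi
  )
}

#' Outward per-vertex surface normals
#'
#' Area-weighted average of the incident face normals, renormalised to unit
#' length.  Face winding determines orientation; meshes produced by
#' [generate_synthetic_cortex()] are wound outward.  Degenerate (zero-area)
#' faces are skipped from the average with a warning.
#'
#' @param mesh A [cortical_mesh()].
#' @return An `N x 3` matrix of unit vectors.
#' @export
surface_normals <- function(mesh) {
  stopifnot(inherits(mesh, "cortical_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2L], ] - v[f[, 1L], ]
  e2 <- v[f[, 3L], ] - v[f[, 1L], ]
  fn <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )  # cross product; norm = 2 * face area, so summation is area-weighted
  area2 <- sqrt(rowSums(fn^2))
  degen <- area2 <= .Machine$double.eps * 100
  if (any(degen)) {
    warning(sum(degen), " degenerate face(s) skipped in normal averaging")
    fn[degen, ] <- 0
  }
  out <- matrix(0, nrow(v), 3L)
  for (k in 1:3) {
    for (d in 1:3) {
      acc <- tapply(fn[, d], f[, k], sum)
      idx <- as.integer(names(acc))
      out[idx, d] <- out[idx, d] + acc
    }
  }
  nrm <- sqrt(rowSums(out^2))
  if (any(nrm == 0)) stop("isolated or fully degenerate vertex in mesh", call. = FALSE)
  out / nrm
}

#' Euler characteristic of one hemisphere's sub-mesh
#'
#' `V - E + F`; a closed 2-manifold sphere-topology hemisphere gives 2.
#'
#' @param mesh A [cortical_mesh()].
#' @param hemi `"left"` or `"right"`.
#' @return Integer Euler characteristic.
#' @export
mesh_euler_characteristic <- function(mesh, hemi = c("left", "right")) {
  hemi <- match.arg(hemi)
  keep <- which(mesh$hemisphere == hemi)
  f <- mesh$faces
  in_h <- matrix(f %in% keep, nrow(f), 3L)
  f <- f[rowSums(in_h) == 3L, , drop = FALSE]
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  edges <- unique(t(apply(edges, 1L, sort)))
  length(keep) - nrow(edges) + nrow(f)
}

# Edge list (i, j, length) of a mesh, one row per undirected edge.
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  len <- sqrt(rowSums((mesh$vertices[e[, 1], ] - mesh$vertices[e[, 2], ])^2))
  cbind(e, len)
}
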