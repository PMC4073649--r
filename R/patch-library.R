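#' Library of cortical patch covariance components
#'
#' Samples `n_patches` centre vertices without replacement and builds, for
#' each, a Gaussian spatial profile in mesh geodesic distance with the given
#' full width at half maximum, truncated at 3 standard deviations (so every
#' patch is a single connected piece of cortex).  Each covariance component
#' is the rank-1 outer product of its profile; the library as a whole is the
#' sparse candidate set the MSP inversion optimises over.
#'
#' @param mesh A [cortical_mesh()].
#' @param n_patches Library size (<= number of vertices).
#' @param fwhm Patch full width at half maximum (mm, geodesic). A warning is
#'   issued if this is below the mean edge length (the patch degenerates to
#'   a point).
#' @param seed Integer seed for the centre draw.
#' @param centres Optional explicit centre vertex indices (overrides the
#'   seeded draw); used e.g. to plant patches at known locations.
#'
#' @return An object of class `patch_library`: `profiles` (sparse
#'   `N_d x n_patches` [Matrix::Matrix()], columns peak-normalised to 1),
#'   `centres`, `fwhm`, `sigma_mm`, and the mesh edge statistics.
#' @export
build_patch_library <- function(mesh, n_patches, fwhm = 10, seed = 1,
                                centres = NULL) {
  stopifnot(inherits(mesh, "cortical_mesh"))
  nd <- nrow(mesh$vertices)
  if (is.null(centres)) {
    if (n_patches > nd) stop("`n_patches` exceeds the vertex count", call. = FALSE)
    centres <- with_seed(seed, sample.int(nd, n_patches))
  } else {
    centres <- as.integer(centres)
    n_patches <- length(centres)
  }
  ed <- mesh_edges(mesh)
  mean_edge <- mean(ed[, 3])
  if (fwhm < mean_edge) {
    warning("fwhm (", signif(fwhm, 3), " mm) is below the mean edge length (",
            signif(mean_edge, 3), " mm): patches degenerate to single vertices")
  }
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  g <- igraph::graph_from_edgelist(cbind(ed[, 1], ed[, 2]), directed = FALSE)
  if (igraph::vcount(g) < nd) {
    g <- igraph::add_vertices(g, nd - igraph::vcount(g))
  }
  dmat <- igraph::distances(g, v = centres, weights = ed[, 3])
  cut <- 3 * sigma
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  for (k in seq_len(n_patches)) {
    idx <- which(dmat[k, ] <= cut)
    trip_i <- c(trip_i, idx)
    trip_j <- c(trip_j, rep(k, length(idx)))
    trip_x <- c(trip_x, exp(-dmat[k, idx]^2 / (2 * sigma^2)))
  }
  profiles <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                                   dims = c(nd, n_patches))
  structure(
    list(profiles = profiles, centres = centres, fwhm = fwhm,
         sigma_mm = sigma, mean_edge_mm = mean_edge, n_vertices = nd),
    class = "patch_library"
  )
}

#' @export
print.patch_library <- function(x, ...) {
  cat("<patch_library> ", length(x$centres), " patches, FWHM ",
      x$fwhm, " mm on ", x$n_vertices, " vertices\n", sep = "")
  invisible(x)
}

#' Assemble a prior source covariance from weighted components
#'
#' The optimised prior is the weighted sum \eqn{Q = \sum_i h_i C_i}.  For
#' the minimum-norm model the single component is the identity, so
#' `Q = h * I`; for MSP each component is a rank-1 patch outer product.
#'
#' @param h Non-negative component weights.
#' @param components A `patch_library`, or a list of `N_d x N_d` symmetric
#'   PSD matrices, or the string `"identity"` with `n_d` given.
#' @param n_d Source count (only for `components = "identity"`).
#' @return Dense `N_d x N_d` prior covariance matrix.
#' @export
assemble_Q <- function(h, components, n_d = NULL) {
  if (any(h < 0)) stop("component weights must be non-negative", call. = FALSE)
  if (inherits(components, "patch_library")) {
    P <- components$profiles
    stopifnot(length(h) == ncol(P))
    return(as.matrix(P %*% (h * Matrix::t(P))))
  }
  if (identical(components, "identity")) {
    stopifnot(length(h) == 1L, !is.null(n_d))
    return(diag(h, n_d))
  }
  stopifnot(is.list(components), length(h) == length(components))
  Q <- matrix(0, nrow(components[[1]]), ncol(components[[1]]))
  for (i in seq_along(components)) Q <- Q + h[i] * as.matrix(components[[i]])
  Q
}
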