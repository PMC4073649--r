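#' Weighted-Fourier-series decomposition of a parameterised surface
#'
#' Expresses each coordinate function of a two-hemisphere surface as a linear
#' combination of real spherical harmonics up to degree `Lmax`,
#' \deqn{x(\omega) = \sum_{l=0}^{L} \sum_{m=-l}^{l} e^{-l(l+1)\sigma}
#'   f_{lm} S_{lm}(\omega),}
#' where \eqn{\omega = (\theta, \phi)} is the per-vertex spherical
#' parameterisation.  The coefficients \eqn{f_{lm}} are obtained per
#' hemisphere and per coordinate by least squares (ridge-stabilised normal
#' equations; the ridge is `ridge` times the mean diagonal of the Gram
#' matrix, guarding near-singular parameterisations).  Hemispheres are fitted
#' independently, each on its own spherical chart.
#'
#' @param mesh A [cortical_mesh()] carrying its parameterisation, or a mesh
#'   plus a separate `param` tibble as returned by [mesh_parameterisation()].
#' @param Lmax Maximum harmonic degree of the decomposition.
#' @param sigma Smoothing bandwidth stored with the fit and used as the
#'   default in [reconstruct_surface()]; `0` (pure truncation) by default so
#'   that reduced-order surfaces isolate the effect of harmonic order.
#' @param ridge Relative ridge (default `1e-10`).
#' @param param Optional parameterisation tibble overriding the mesh's own.
#'
#' @return An object of class `wfs_fit`: per-hemisphere coefficient matrices
#'   (`(Lmax+1)^2 x 3`, columns x/y/z), the template mesh, `Lmax`, `sigma`,
#'   and per-hemisphere RMS residuals (mm).
#' @seealso [reconstruct_surface()], [harmonic_family()], [spatial_distortion()]
#' @export
fit_wfs <- function(mesh, Lmax, sigma = 0, ridge = 1e-10, param = NULL) {
  stopifnot(inherits(mesh, "cortical_mesh"))
  if (!is.null(param)) {
    mesh$theta <- param$theta[order(param$vertex)]
    mesh$phi <- param$phi[order(param$vertex)]
  }
  if (is.null(mesh$theta)) {
    stop("mesh has no spherical parameterisation; supply `param`", call. = FALSE)
  }
  Lmax <- as.integer(Lmax)
  ncoef <- (Lmax + 1L)^2
  hemis <- c("left", "right")
  coeffs <- list()
  resid_rms <- c(left = NA_real_, right = NA_real_)
  for (h in hemis) {
    idx <- which(mesh$hemisphere == h)
    if (length(idx) == 0L) next
    if (ncoef > length(idx)) {
      stop("(Lmax+1)^2 exceeds the number of vertices in the ", h,
           " hemisphere", call. = FALSE)
    }
    B <- sh_basis(mesh$theta[idx], mesh$phi[idx], Lmax)
    G <- crossprod(B)
    lam <- ridge * mean(diag(G))
    diag(G) <- diag(G) + lam
    # conditioning guard: a degenerate parameterisation collapses the Gram
    rc <- rcond(G)
    if (!is.finite(rc) || rc < .Machine$double.eps) {
      stop("degenerate spherical parameterisation: normal equations are ",
           "numerically singular for the ", h, " hemisphere", call. = FALSE)
    }
    cf <- solve(G, crossprod(B, mesh$vertices[idx, , drop = FALSE]))
    colnames(cf) <- c("x", "y", "z")
    coeffs[[h]] <- cf
    resid_rms[h] <- sqrt(mean((mesh$vertices[idx, ] - B %*% cf)^2))
  }
  structure(
    list(coeffs = coeffs, Lmax = Lmax, sigma = sigma,
         template = mesh, resid_rms = resid_rms,
         degrees = attr(sh_basis(0, 0, Lmax), "degrees")),
    class = "wfs_fit"
  )
}

#' @export
print.wfs_fit <- function(x, ...) {
  cat("<wfs_fit> Lmax = ", x$Lmax, ", sigma = ", x$sigma,
      ", residual RMS (mm): left = ", signif(x$resid_rms["left"], 3),
      ", right = ", signif(x$resid_rms["right"], 3), "\n", sep = "")
  invisible(x)
}

#' Rebuild a surface from its harmonic decomposition at order L
#'
#' Evaluates the weighted series truncated at degree `L`, with degree weights
#' `exp(-l*(l+1)*sigma)`.  Faces, hemisphere labels and parameterisation are
#' copied from the decomposition's template, so the result is vertex-wise
#' comparable with every other member of the family.
#'
#' @param fit A [fit_wfs()] object.
#' @param L Truncation degree, `0 <= L <= fit$Lmax`.
#' @param sigma Smoothing bandwidth; defaults to the value stored in `fit`.
#' @return A [cortical_mesh()].
#' @export
reconstruct_surface <- function(fit, L, sigma = fit$sigma) {
  stopifnot(inherits(fit, "wfs_fit"))
  if (L > fit$Lmax || L < 0) {
    stop("`L` must lie in 0..Lmax of the decomposition", call. = FALSE)
  }
  mesh <- fit$template
  keep <- fit$degrees <= L
  w <- wfs_weights(fit$degrees[keep], sigma)
  out <- mesh$vertices
  for (h in names(fit$coeffs)) {
    idx <- which(mesh$hemisphere == h)
    B <- sh_basis(mesh$theta[idx], mesh$phi[idx], as.integer(L))
    out[idx, ] <- B %*% (w * fit$coeffs[[h]][keep, , drop = FALSE])
  }
  cortical_mesh(out, mesh$faces, mesh$hemisphere, mesh$theta, mesh$phi)
}

#' Per-vertex spatial displacement between two corresponding surfaces
#'
#' Euclidean distance (mm) between corresponding vertices of a reduced-order
#' surface and the reference (most complete) surface.
#'
#' @param mesh_L,mesh_ref Two [cortical_mesh()] objects with identical vertex
#'   count and correspondence.
#' @return Numeric vector of length `N` (mm), non-negative.
#' @export
per_vertex_distortion <- function(mesh_L, mesh_ref) {
  stopifnot(inherits(mesh_L, "cortical_mesh"), inherits(mesh_ref, "cortical_mesh"))
  if (nrow(mesh_L$vertices) != nrow(mesh_ref$vertices)) {
    stop("meshes have different vertex counts", call. = FALSE)
  }
  sqrt(rowSums((mesh_L$vertices - mesh_ref$vertices)^2))
}

#' Spatial distortion: an upper-percentile summary of vertex displacement
#'
#' The stated percentile (default 95th) of the per-vertex displacements,
#' using the linear-interpolation quantile convention
#' (`stats::quantile(type = 7)`).
#'
#' @param d Non-empty numeric vector of per-vertex distortions (mm), or a
#'   [cortical_mesh()] (in which case `ref` must be given).
#' @param percentile Quantile level in percent (default 95).
#' @param ref Reference mesh when `d` is a mesh.
#' @return Scalar distortion (mm).
#' @export
spatial_distortion <- function(d, percentile = 95, ref = NULL) {
  if (inherits(d, "cortical_mesh")) {
    if (is.null(ref)) stop("supply `ref` when `d` is a mesh", call. = FALSE)
    d <- per_vertex_distortion(d, ref)
  }
  if (length(d) == 0L) stop("empty distortion vector", call. = FALSE)
  unname(stats::quantile(d, percentile / 100, type = 7, names = FALSE))
}

#' Nested family of harmonic surfaces with distortion summaries
#'
#' Rebuilds the surface at every requested order and summarises each member's
#' spatial distortion against the most complete reconstruction
#' (`L = fit$Lmax`), which serves as the reference anatomy.
#'
#' @param fit A [fit_wfs()] object.
#' @param L_values Harmonic orders to rebuild (default `1:fit$Lmax`).
#' @param percentile Distortion percentile (default 95).
#' @return A list with `meshes` (named list of [cortical_mesh()], including
#'   the reference under its own order) and `distortion`, a tibble with
#'   columns `L` and `distortion_mm`.
#' @export
harmonic_family <- function(fit, L_values = seq_len(fit$Lmax), percentile = 95) {
  stopifnot(inherits(fit, "wfs_fit"))
  L_values <- sort(unique(as.integer(L_values)))
  ref <- reconstruct_surface(fit, fit$Lmax)
  meshes <- lapply(L_values, function(L) reconstruct_surface(fit, L))
  names(meshes) <- paste0("L", L_values)
  dist <- vapply(meshes, function(m) {
    spatial_distortion(per_vertex_distortion(m, ref), percentile)
  }, numeric(1))
  if (!fit$Lmax %in% L_values) {
    meshes[[paste0("L", fit$Lmax)]] <- ref
  }
  list(
    meshes = meshes,
    reference = ref,
    distortion = tibble::tibble(L = L_values, distortion_mm = unname(dist))
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a harmonic surface decomposition
#'
#' @param x A `wfs_fit`.
#' @param ... Unused.
#' @return A tibble with one row per (hemisphere, degree, order, coordinate)
#'   coefficient.
#' @export
tidy.wfs_fit <- function(x, ...) {
  degs <- x$degrees
  ords <- attr(sh_basis(0, 0, x$Lmax), "orders")
  purrr::map_dfr(names(x$coeffs), function(h) {
    cf <- x$coeffs[[h]]
    tibble::tibble(
      hemisphere = h,
      l = rep(degs, 3L),
      m = rep(ords, 3L),
      coordinate = rep(c("x", "y", "z"), each = length(degs)),
      value = c(cf)
    )
  })
}

#' @rdname tidy.wfs_fit
#' @export
glance.wfs_fit <- function(x, ...) {
  tibble::tibble(
    Lmax = x$Lmax, sigma = x$sigma,
    n_coefficients = 3L * 2L * (x$Lmax + 1L)^2,
    resid_rms_left = x$resid_rms[["left"]],
    resid_rms_right = x$resid_rms[["right"]]
  )
}
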