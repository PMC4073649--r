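#' Read and write surfaces as Wavefront OBJ
#'
#' Vertices are written in mm; the hemisphere label is carried as `g left` /
#' `g right` group lines, and the per-vertex parameterisation (when present)
#' as `vt theta phi` texture lines in vertex order.
#'
#' @param mesh A [cortical_mesh()].
#' @param path File path.
#' @return `write_mesh_obj` returns `path` invisibly; `read_mesh_obj`
#'   returns a [cortical_mesh()].
#' @export
write_mesh_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "cortical_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# cortical surface (mm)", con)
  for (h in c("left", "right")) {
    idx <- which(mesh$hemisphere == h)
    if (!length(idx)) next
    writeLines(paste("g", h), con)
    writeLines(sprintf("v %.9g %.9g %.9g",
                       mesh$vertices[idx, 1], mesh$vertices[idx, 2],
                       mesh$vertices[idx, 3]), con)
  }
  if (!is.null(mesh$theta)) {
    ord <- order(match(mesh$hemisphere, c("left", "right")))
    writeLines(sprintf("vt %.9g %.9g", mesh$theta[ord], mesh$phi[ord]), con)
  }
  # faces refer to vertices in (left, right) write order
  ord <- order(match(mesh$hemisphere, c("left", "right")))
  remap <- integer(length(ord)); remap[ord] <- seq_along(ord)
  f <- matrix(remap[mesh$faces], ncol = 3L)
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}

#' @rdname write_mesh_obj
#' @export
read_mesh_obj <- function(path) {
  lines <- readLines(path)
  tok <- strsplit(trimws(lines), "\\s+")
  keys <- vapply(tok, function(x) if (length(x)) x[[1]] else "", "")
  hemi_cur <- "left"
  hemis <- character(0)
  verts <- list()
  for (i in seq_along(tok)) {
    if (keys[i] == "g") {
      hemi_cur <- tok[[i]][2]
    } else if (keys[i] == "v") {
      verts[[length(verts) + 1L]] <- as.numeric(tok[[i]][2:4])
      hemis <- c(hemis, hemi_cur)
    }
  }
  v <- do.call(rbind, verts)
  vt <- tok[keys == "vt"]
  theta <- phi <- NULL
  if (length(vt) == nrow(v)) {
    ang <- do.call(rbind, lapply(vt, function(x) as.numeric(x[2:3])))
    # guard against rounding at the chart boundary in the text encoding
    theta <- pmin(pi, pmax(0, ang[, 1]))
    phi <- ang[, 2] %% (2 * pi)
  }
  f <- do.call(rbind, lapply(tok[keys == "f"], function(x) {
    as.integer(vapply(strsplit(x[2:4], "/"), `[[`, "", 1L))
  }))
  cortical_mesh(v, f, hemis, theta, phi)
}

#' Write / read a sensor array as delimited text
#'
#' Columns `name, x, y, z, ox, oy, oz` (positions in mm, unit orientations),
#' tab-separated with a header.
#'
#' @param sensors A sensor array tibble.
#' @param path File path.
#' @export
write_sensor_array <- function(sensors, path) {
  utils::write.table(as.data.frame(sensors), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sensor_array
#' @export
read_sensor_array <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- tibble::as_tibble(df)
  o <- as.matrix(out[, c("ox", "oy", "oz")])
  nrm <- sqrt(rowSums(o^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    stop("sensor orientations are not unit vectors", call. = FALSE)
  }
  class(out) <- c("sensor_array", class(out))
  out
}

#' Serialise harmonic coefficients to JSON
#'
#' Layout: `hemisphere -> coordinate -> flat (l, m) array` in lexicographic
#' `(l, m)` order with `m = -l..l`, plus `Lmax` and `sigma` metadata, so the
#' decomposition can be interchanged with other tools.
#'
#' @param fit A [fit_wfs()] object.
#' @param path File path.
#' @export
write_wfs_json <- function(fit, path) {
  stopifnot(inherits(fit, "wfs_fit"))
  obj <- list(
    Lmax = fit$Lmax, sigma = fit$sigma,
    ordering = "(l, m) lexicographic, m = -l..l",
    convention = "real orthonormal spherical harmonics, Condon-Shortley phase",
    coefficients = lapply(fit$coeffs, function(cf) {
      list(x = cf[, "x"], y = cf[, "y"], z = cf[, "z"])
    })
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_wfs_json
#' @param template A [cortical_mesh()] providing faces, hemisphere labels
#'   and parameterisation for surfaces rebuilt from the file.
#' @export
read_wfs_json <- function(path, template) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coeffs <- lapply(obj$coefficients, function(cf) {
    m <- cbind(x = cf$x, y = cf$y, z = cf$z)
    m
  })
  structure(
    list(coeffs = coeffs, Lmax = obj$Lmax, sigma = obj$sigma,
         template = template,
         resid_rms = c(left = NA_real_, right = NA_real_),
         degrees = attr(sh_basis(0, 0, obj$Lmax), "degrees")),
    class = "wfs_fit"
  )
}

#' Write a model-comparison table as CSV
#'
#' @param table A [model_comparison_table()].
#' @param path File path.
#' @export
write_comparison_csv <- function(table, path) {
  df <- as.data.frame(table)
  df$hdh <- attr(table, "hdh")
  df$threshold <- attr(table, "threshold")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
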