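#' MEG lead field for a homogeneous spherical conductor
#'
#' Computes the `N_c x N_d` gain matrix `K` mapping unit current dipoles at
#' the mesh vertices (oriented along the outward surface normals, the
#' direction of pyramidal-cell current flow) to the field component measured
#' by each sensor, using the closed-form solution for a current dipole in a
#' homogeneous conducting sphere.  The solution is exact, needs no skull
#' mesh, and inherits the sphere model's key property that radially oriented
#' dipoles are magnetically silent.
#'
#' Physical constants (and the point-magnetometer pickup) are folded into a
#' single gain scale: by default `K` is rescaled so its RMS entry is 1,
#' making signal-to-noise handling unit-free.
#'
#' @param mesh A [cortical_mesh()] of source locations.
#' @param sensors A [generate_sensor_array()] table (or any tibble with
#'   `x,y,z,ox,oy,oz` columns).
#' @param centre Conductor sphere centre (mm).
#' @param normals Per-vertex unit dipole orientations; defaults to
#'   [surface_normals()] of the mesh.
#' @param normalise Rescale `K` to unit RMS entry (default `TRUE`).
#'
#' @return An object of class `leadfield`: list with `K` (`N_c x N_d`),
#'   `centre`, `scale` (the applied gain scale), and `silent` (indices of
#'   flagged zero columns, i.e. sources at the sphere centre).
#' @export
compute_leadfield <- function(mesh, sensors, centre = c(0, 0, 0),
                              normals = surface_normals(mesh),
                              normalise = TRUE) {
  stopifnot(inherits(mesh, "cortical_mesh"))
  rq <- sweep(mesh$vertices, 2L, centre)      # sources, relative to centre
  rs <- sweep(sensor_positions(sensors), 2L, centre)
  or <- sensor_orientations(sensors)
  src_rad <- sqrt(rowSums(rq^2))
  if (max(src_rad) >= min(sqrt(rowSums(rs^2)))) {
    stop("sensors must lie strictly outside the bounding sphere of the sources",
         call. = FALSE)
  }
  at_centre <- which(src_rad < 1e-6)
  if (length(at_centre)) {
    warning(length(at_centre),
            " source(s) at the sphere centre: lead-field columns set to zero")
  }
  q <- normals
  # q x r_Q per source (constant across sensors)
  qxr <- cbind(
    q[, 2] * rq[, 3] - q[, 3] * rq[, 2],
    q[, 3] * rq[, 1] - q[, 1] * rq[, 3],
    q[, 1] * rq[, 2] - q[, 2] * rq[, 1]
  )
  nc <- nrow(rs)
  nd <- nrow(rq)
  K <- matrix(0, nc, nd)
  for (s in seq_len(nc)) {
    r <- rs[s, ]
    rn <- sqrt(sum(r^2))
    avec <- matrix(r, nd, 3L, byrow = TRUE) - rq
    a <- sqrt(rowSums(avec^2))
    adotr <- drop(avec %*% r)
    rqdotr <- drop(rq %*% r)
    Fv <- a * (rn * a + rn^2 - rqdotr)
    c1 <- a^2 / rn + adotr / a + 2 * a + 2 * rn
    c2 <- a + 2 * rn + adotr / a
    gradF <- cbind(
      c1 * r[1] - c2 * rq[, 1],
      c1 * r[2] - c2 * rq[, 2],
      c1 * r[3] - c2 * rq[, 3]
    )
    qxr_dot_r <- qxr %*% r
    B <- (Fv * qxr - drop(qxr_dot_r) * gradF) / Fv^2
    K[s, ] <- B %*% or[s, ]
  }
  if (length(at_centre)) K[, at_centre] <- 0
  scale <- 1
  if (normalise) {
    rms <- sqrt(mean(K^2))
    if (rms > 0) {
      scale <- 1 / rms
      K <- K * scale
    }
  }
  structure(
    list(K = K, centre = centre, scale = scale, silent = at_centre),
    class = "leadfield"
  )
}

#' @export
print.leadfield <- function(x, ...) {
  cat("<leadfield> ", nrow(x$K), " channels x ", ncol(x$K), " sources\n", sep = "")
  invisible(x)
}

# Accept a leadfield object or plain matrix.
leadfield_matrix <- function(K) {
  if (inherits(K, "leadfield")) K$K else as.matrix(K)
}

#' Reduce problem dimensionality via spatial and temporal eigenmodes
#'
#' Projects channels onto the leading left singular vectors of the lead
#' field (spatial modes) and samples onto the leading right singular vectors
#' of the projected data (temporal modes).  When several anatomical models
#' are compared, their log evidences are only commensurable if every model
#' is projected through the *same* spatial projector; pass the reference
#' model's projector via `U` (as [run_experiment()] does) to guarantee this.
#'
#' @param K Lead field (matrix or `leadfield`).
#' @param Y Sensor data, channels x samples.
#' @param n_spatial,n_temporal Numbers of spatial / temporal modes to keep;
#'   requests beyond the available rank are clipped with a warning.
#' @param U Optional pre-computed spatial projector (rows orthonormal) to
#'   reuse across models.
#'
#' @return An object of class `reduced_problem`: `U` (`n_spatial x N_c`),
#'   `V` (`N_t x n_temporal`), `K` (reduced lead field), `Y` (reduced data),
#'   and the original sample count `n_samples_full`.
#' @export
reduce_dimensionality <- function(K, Y, n_spatial = 60, n_temporal = 16,
                                  U = NULL) {
  Km <- leadfield_matrix(K)
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) == nrow(Km))
  if (is.null(U)) {
    sv <- svd(Km)
    rk <- sum(sv$d > sv$d[1] * max(dim(Km)) * .Machine$double.eps)
    if (n_spatial > rk) {
      warning("n_spatial clipped from ", n_spatial, " to rank ", rk)
      n_spatial <- rk
    }
    U <- t(sv$u[, seq_len(n_spatial), drop = FALSE])
  } else {
    U <- as.matrix(U)
    stopifnot(ncol(U) == nrow(Km))
  }
  Yu <- U %*% Y
  svy <- svd(Yu)
  rky <- sum(svy$d > max(svy$d[1], .Machine$double.eps) * max(dim(Yu)) * .Machine$double.eps)
  rky <- max(rky, 1L)
  if (n_temporal > rky) {
    warning("n_temporal clipped from ", n_temporal, " to rank ", rky)
    n_temporal <- rky
  }
  V <- svy$v[, seq_len(n_temporal), drop = FALSE]
  structure(
    list(U = U, V = V, K = U %*% Km, Y = Yu %*% V,
         n_samples_full = ncol(Y)),
    class = "reduced_problem"
  )
}

#' Permute channel lead fields (negative geometric control)
#'
#' Applies a seeded uniform random permutation to the *rows* (channels) of
#' the lead field, destroying the geometric relationship between sensors and
#' anatomy while preserving the multiset of lead-field patterns.  The sensor
#' data are left untouched; inverting real data through a permuted lead
#' field should make all anatomical models indistinguishable.
#'
#' @param K Lead field (matrix or `leadfield`).
#' @param seed Integer seed.
#' @return Same type as `K`, rows permuted; the permutation is stored in
#'   attribute `permutation`.
#' @export
permute_leadfields <- function(K, seed = 1) {
  Km <- leadfield_matrix(K)
  perm <- with_seed(seed, sample.int(nrow(Km)))
  out <- Km[perm, , drop = FALSE]
  if (inherits(K, "leadfield")) {
    K$K <- out
    attr(K, "permutation") <- perm
    K
  } else {
    attr(out, "permutation") <- perm
    out
  }
}
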