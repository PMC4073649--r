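#' @keywords internal
# Evaluate code with a temporary RNG state seeded at `seed`, restoring the
# caller's stream afterwards so package randomness never perturbs a script's.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Unit icosphere with vertices at the two poles.  Returns vertices (unit
# sphere), faces (outward winding).  Levels 0..4 give 12/42/162/642/2562
# vertices.
icosphere <- function(subdivisions = 3L) {
  stopifnot(subdivisions >= 0, subdivisions == round(subdivisions))
  z <- 1 / sqrt(5)
  r <- 2 / sqrt(5)
  ang_u <- (0:4) * 2 * pi / 5
  ang_l <- ang_u + pi / 5
  v <- rbind(
    c(0, 0, 1),
    cbind(r * cos(ang_u), r * sin(ang_u), z),
    cbind(r * cos(ang_l), r * sin(ang_l), -z),
    c(0, 0, -1)
  )
  up <- 2:6; lo <- 7:11
  f <- NULL
  for (i in 0:4) {
    j <- (i + 1) %% 5
    f <- rbind(
      f,
      c(1, up[i + 1], up[j + 1]),                 # top cap
      c(up[i + 1], lo[i + 1], up[j + 1]),         # upper band
      c(up[j + 1], lo[i + 1], lo[j + 1]),         # lower band
      c(12, lo[j + 1], lo[i + 1])                 # bottom cap
    )
  }
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    edge_key <- new.env(hash = TRUE, parent = emptyenv())
    verts <- v
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      idx <- edge_key[[key]]
      if (!is.null(idx)) return(idx)
      m <- verts[a, ] + verts[b, ]
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      idx <- nrow(verts)
      edge_key[[key]] <- idx
      idx
    }
    nf <- matrix(0L, 4L * nrow(f), 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[4L * i - 3L, ] <- c(a, ab, ca)
      nf[4L * i - 2L, ] <- c(b, bc, ab)
      nf[4L * i - 1L, ] <- c(cc, ca, bc)
      nf[4L * i, ] <- c(ab, bc, ca)
    }
    v <- verts
    f <- nf
  }
  list(vertices = v, faces = f)
}

# Smallest icosphere subdivision level whose vertex count reaches n.
icosphere_level_for <- function(n_vertices) {
  counts <- c(12L, 42L, 162L, 642L, 2562L, 10242L)
  lev <- which(counts >= n_vertices)[1] - 1L
  if (is.na(lev)) stop("requested vertex count too large", call. = FALSE)
  lev
}

#' Generate a band-limited synthetic two-hemisphere cortex
#'
#' Builds a cortex-like surface with *known* harmonic content: each
#' hemisphere is an icosphere whose three coordinate functions are perturbed
#' by random band-limited spherical-harmonic fields, so the surface is
#' exactly band-limited at `L_content` by construction (coordinate
#' perturbations, rather than radial ones, keep the coordinate functions
#' band-limited; a radial perturbation would couple with the degree-1
#' direction field and leak into degree `L_content + 1`).  Degree-`l`
#' coefficients are drawn i.i.d. normal with standard deviation
#' `amplitudes[l] / sqrt(2*l + 1)`, so `amplitudes[l]` sets the total RMS
#' contribution of degree `l` in mm.  Hemispheres are two disjoint closed
#' surfaces offset laterally by `offset` mm, each carrying its own spherical
#' chart (the generating angles), and the construction is fully determined
#' by `seed`.
#'
#' @param n_vertices Vertices per hemisphere; rounded up to the nearest
#'   icosphere granularity (12, 42, 162, 642, 2562, ...).
#' @param base_radius Hemisphere base radius \eqn{r_0} (mm).
#' @param amplitudes Per-degree RMS perturbation amplitudes \eqn{a_l} (mm)
#'   for degrees `1..L_content`; the default `12 / (1:12)` gives a smooth
#'   red spectrum with ~7 mm RMS total displacement on a 50 mm sphere.
#' @param offset Lateral (±x) hemisphere centre offset (mm).
#' @param seed Integer seed; identical seeds give bit-identical meshes.
#'
#' @return A [cortical_mesh()] with parameterisation attached, plus
#'   attributes `generator` (the exact generating coefficients, per
#'   hemisphere) and `spec` (the arguments).
#' @export
generate_synthetic_cortex <- function(n_vertices = 642,
                                      base_radius = 50,
                                      amplitudes = 12 / (1:12),
                                      offset = 25,
                                      seed = 1) {
  L_content <- length(amplitudes)
  lev <- icosphere_level_for(n_vertices)
  ico <- icosphere(lev)
  u <- ico$vertices
  n <- nrow(u)
  theta <- acos(pmin(1, pmax(-1, u[, 3])))
  phi <- atan2(u[, 2], u[, 1]) %% (2 * pi)
  B <- if (L_content > 0) sh_basis(theta, phi, L_content) else NULL
  degs <- if (L_content > 0) attr(B, "degrees") else integer(0)
  pert_cols <- which(degs >= 1L)

  gen <- with_seed(seed, {
    lapply(c(left = "left", right = "right"), function(h) {
      if (L_content == 0L) return(matrix(0, 0, 3))
      sds <- amplitudes[degs[pert_cols]] / sqrt(2 * degs[pert_cols] + 1)
      cf <- matrix(stats::rnorm(length(pert_cols) * 3), length(pert_cols), 3)
      cf * sds
    })
  })

  build_hemi <- function(h, centre_x) {
    x <- base_radius * u
    if (L_content > 0L) {
      disp <- B[, pert_cols, drop = FALSE] %*% gen[[h]]
      if (max(sqrt(rowSums(disp^2))) >= base_radius) {
        stop("star-shape violation: perturbation reaches the base radius",
             call. = FALSE)
      }
      x <- x + disp
    }
    x[, 1] <- x[, 1] + centre_x
    x
  }
  vl <- build_hemi("left", -offset)
  vr <- build_hemi("right", offset)
  mesh <- cortical_mesh(
    vertices = rbind(vl, vr),
    faces = rbind(ico$faces, ico$faces + n),
    hemisphere = rep(c("left", "right"), each = n),
    theta = rep(theta, 2L), phi = rep(phi, 2L)
  )
  attr(mesh, "generator") <- gen
  attr(mesh, "spec") <- list(
    n_vertices = n, base_radius = base_radius, amplitudes = amplitudes,
    L_content = L_content, offset = offset, seed = seed,
    pert_degrees = degs[pert_cols]
  )
  mesh
}

#' Helmet-like MEG sensor array on a spherical cap
#'
#' Quasi-uniform (Fibonacci spiral) layout of radially oriented point
#' magnetometers on a spherical cap of radius `helmet_radius` covering the
#' top `cap_fraction` of the sphere's area.
#'
#' @param n_channels Number of sensors (>= 2).
#' @param helmet_radius Helmet radius (mm); must exceed the outermost source
#'   radius of the anatomy it is used with.
#' @param cap_fraction Fraction of the full sphere's area covered by the cap
#'   (default 0.55, a whole-head helmet reaching below the ears).
#' @param centre Helmet centre (mm).
#' @return A `sensor_array`: a tibble with columns `name`, `x`, `y`, `z`
#'   (positions, mm) and `ox`, `oy`, `oz` (unit orientations).
#' @export
generate_sensor_array <- function(n_channels = 128,
                                  helmet_radius = 120,
                                  cap_fraction = 0.55,
                                  centre = c(0, 0, 0)) {
  if (n_channels < 2) stop("`n_channels` must be at least 2", call. = FALSE)
  stopifnot(cap_fraction > 0, cap_fraction <= 1)
  i <- seq_len(n_channels) - 0.5
  z <- 1 - 2 * cap_fraction * i / n_channels
  golden <- pi * (3 - sqrt(5))
  az <- (seq_len(n_channels) - 1L) * golden
  rho <- sqrt(pmax(0, 1 - z^2))
  o <- cbind(ox = rho * cos(az), oy = rho * sin(az), oz = z)
  pos <- sweep(helmet_radius * o, 2L, centre, "+")
  out <- tibble::tibble(
    name = sprintf("MEG%03d", seq_len(n_channels)),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    ox = o[, 1], oy = o[, 2], oz = o[, 3]
  )
  class(out) <- c("sensor_array", class(out))
  attr(out, "helmet_radius") <- helmet_radius
  attr(out, "centre") <- centre
  out
}

# positions / orientations as plain matrices
sensor_positions <- function(sensors) {
  as.matrix(sensors[, c("x", "y", "z")])
}
sensor_orientations <- function(sensors) {
  as.matrix(sensors[, c("ox", "oy", "oz")])
}
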