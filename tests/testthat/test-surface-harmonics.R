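test_that("basis has the expected layout and is orthonormal under quadrature", {
  B <- sh_basis(c(0.3, 1.2, 2.8), c(0.1, 3.0, 5.9), L = 2)
  expect_equal(ncol(B), 9L)
  expect_equal(unname(B[, 1]), rep(1 / sqrt(4 * pi), 3))
  expect_equal(attr(B, "degrees"), c(0, 1, 1, 1, 2, 2, 2, 2, 2))
  expect_equal(attr(B, "orders"), c(0, -1, 0, 1, -2, -1, 0, 1, 2))

  skip_if_not_installed("pracma")
  gl <- pracma::gaussLegendre(80, -1, 1)
  nphi <- 160
  phig <- (seq_len(nphi) - 0.5) * 2 * pi / nphi
  theta <- rep(acos(gl$x), times = nphi)
  phi <- rep(phig, each = length(gl$x))
  w <- rep(gl$w, times = nphi) * (2 * pi / nphi)
  for (L in c(3L, 8L)) {
    Bq <- sh_basis(theta, phi, L)
    G <- t(Bq * w) %*% Bq
    expect_lt(max(abs(G - diag(ncol(G)))), 1e-6)
  }

  expect_error(sh_basis(-0.2, 1, 2), "theta")
  expect_error(sh_basis(1, 7, 2), "phi")
  expect_error(sh_basis(1, 1, -1), "non-negative")
})

test_that("a sphere has only degree-0 radial content and coefficients round-trip", {
  sph <- generate_synthetic_cortex(n_vertices = 162, amplitudes = numeric(0),
                                   base_radius = 80, offset = 0, seed = 1)
  fit <- fit_wfs(sph, Lmax = 6)
  # a sphere's coordinates are pure degree-0 (radius) x degree-1 (direction):
  # nothing beyond l = 1 survives
  for (h in c("left", "right")) {
    expect_lt(max(abs(fit$coeffs[[h]][fit$degrees > 1, ])), 1e-8)
  }

  # generate-then-fit round trip: coefficients beyond the generator's band
  # vanish and those inside it (degrees >= 2, unconfounded by the base
  # sphere) match the generating values
  ctx <- small_cortex(seed = 42)
  gen <- attr(ctx, "generator")
  spec <- attr(ctx, "spec")
  fit <- fit_wfs(ctx, Lmax = 10)
  for (h in c("left", "right")) {
    cf <- fit$coeffs[[h]]
    expect_lt(max(abs(cf[fit$degrees > spec$L_content, ])), 1e-8)
    inside <- which(fit$degrees >= 2 & fit$degrees <= spec$L_content)
    gen_rows <- which(spec$pert_degrees >= 2)
    expect_lt(max(abs(cf[inside, ] - gen[[h]][gen_rows, ])), 1e-6)
  }
})

test_that("fitting agrees with an independent dense least-squares solve", {
  set.seed(7)
  n <- 80
  theta <- runif(n, 0.15, pi - 0.15)
  phi <- runif(n, 0, 2 * pi)
  verts <- matrix(rnorm(2 * n * 3, sd = 5), 2 * n, 3) + 50
  mesh <- cortical_mesh(verts,
                        faces = cbind(1, 2, 3),  # topology irrelevant to the fit
                        hemisphere = rep(c("left", "right"), each = n),
                        theta = rep(theta, 2), phi = rep(phi, 2))
  L <- 5
  fit <- fit_wfs(mesh, Lmax = L)
  B <- sh_basis(theta, phi, L)
  for (h in c("left", "right")) {
    idx <- which(mesh$hemisphere == h)
    oracle <- qr.solve(B, verts[idx, ])
    expect_lt(max(abs(fit$coeffs[[h]] - oracle)), 1e-5)
  }
})

test_that("reconstruction truncates exactly and the residual is the dropped terms", {
  ctx <- small_cortex(seed = 3)
  fit <- fit_wfs(ctx, Lmax = 8)
  expect_equal(wfs_weights(0, 0.7), 1)           # l = 0 weight is 1 for any sigma
  expect_equal(wfs_weights(0:3, 0), rep(1, 4))

  full <- reconstruct_surface(fit, 8)
  expect_lt(max(per_vertex_distortion(full, ctx)), 1e-8)

  L <- 4
  recL <- reconstruct_surface(fit, L)
  # dropped-term oracle: evaluate the l > L terms directly
  for (h in c("left", "right")) {
    idx <- which(ctx$hemisphere == h)
    B <- sh_basis(ctx$theta[idx], ctx$phi[idx], fit$Lmax)
    drop_cols <- which(fit$degrees > L)
    resid_direct <- B[, drop_cols, drop = FALSE] %*%
      fit$coeffs[[h]][drop_cols, , drop = FALSE]
    expect_lt(max(abs((full$vertices[idx, ] - recL$vertices[idx, ]) -
                        resid_direct)), 1e-8)
  }
  expect_error(reconstruct_surface(fit, 9), "Lmax")
})

test_that("per-vertex distortion is the Euclidean displacement", {
  ctx <- small_cortex(seed = 5)
  expect_equal(per_vertex_distortion(ctx, ctx),
               rep(0, nrow(ctx$vertices)))
  shifted <- ctx
  shifted$vertices[, 1] <- shifted$vertices[, 1] + 3
  expect_equal(per_vertex_distortion(shifted, ctx),
               rep(3, nrow(ctx$vertices)))
  set.seed(9)
  pert <- ctx
  delta <- matrix(rnorm(length(ctx$vertices)), ncol = 3)
  pert$vertices <- pert$vertices + delta
  expect_equal(per_vertex_distortion(pert, ctx), sqrt(rowSums(delta^2)))
  small <- cortical_mesh(ctx$vertices[1:12, ], cbind(1, 2, 3),
                         rep("left", 12))
  expect_error(per_vertex_distortion(small, ctx), "vertex counts")
})

test_that("spatial distortion is a linear-interpolated percentile", {
  expect_equal(spatial_distortion(rep(2, 40)), 2)
  expect_equal(spatial_distortion(rep(0, 10)), 0)
  d <- as.numeric(1:100)
  # independent linear-interpolation oracle
  p <- 0.95
  hidx <- (length(d) - 1) * p + 1
  lo <- floor(hidx)
  oracle <- d[lo] + (hidx - lo) * (d[lo + 1] - d[lo])
  expect_equal(spatial_distortion(d), oracle)
  expect_error(spatial_distortion(numeric(0)), "empty")
})

test_that("distortion shrinks monotonically with harmonic order for band-limited cortices", {
  ctx <- small_cortex(seed = 11)
  fit <- fit_wfs(ctx, Lmax = 8)
  fam <- harmonic_family(fit, 1:8)
  expect_true(all(diff(fam$distortion$distortion_mm) <= 1e-9))
  expect_equal(fam$distortion$distortion_mm[8], 0, tolerance = 1e-8)
})
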