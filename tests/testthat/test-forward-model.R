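# scalar, loop-based transcription of the spherical-conductor dipole field
sphere_dipole_oracle <- function(r_sensor, n_sensor, r_dip, q_dip) {
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  a_vec <- r_sensor - r_dip
  a <- sqrt(sum(a_vec^2))
  r <- sqrt(sum(r_sensor^2))
  Fs <- a * (r * a + r^2 - sum(r_dip * r_sensor))
  gradF <- (a^2 / r + sum(a_vec * r_sensor) / a + 2 * a + 2 * r) * r_sensor -
    (a + 2 * r + sum(a_vec * r_sensor) / a) * r_dip
  qxr <- cross3(q_dip, r_dip)
  B <- (Fs * qxr - sum(qxr * r_sensor) * gradF) / Fs^2
  sum(B * n_sensor)
}

test_that("radial dipoles are magnetically silent; tangential ones are not", {
  ctx <- small_cortex(seed = 1)
  sens <- generate_sensor_array(64)
  v <- ctx$vertices
  radial <- v / sqrt(rowSums(v^2))
  tang <- cbind(-radial[, 2], radial[, 1], 0)
  tang <- tang / sqrt(rowSums(tang^2))
  K_rad <- compute_leadfield(ctx, sens, normals = radial, normalise = FALSE)$K
  K_tan <- compute_leadfield(ctx, sens, normals = tang, normalise = FALSE)$K
  expect_lt(max(abs(K_rad)), 1e-10 * max(abs(K_tan)))
})

test_that("lead field is linear and matches the scalar oracle", {
  ctx <- small_cortex(seed = 2)
  sens <- generate_sensor_array(32)
  lf <- compute_leadfield(ctx, sens, normalise = FALSE)
  set.seed(3)
  J1 <- matrix(rnorm(ncol(lf$K) * 4), ncol = 4)
  J2 <- matrix(rnorm(ncol(lf$K) * 4), ncol = 4)
  expect_lt(max(abs(lf$K %*% (2.5 * J1 - 0.7 * J2) -
                      (2.5 * lf$K %*% J1 - 0.7 * lf$K %*% J2))), 1e-10)

  nm <- surface_normals(ctx)
  pos <- as.matrix(sens[, c("x", "y", "z")])
  ori <- as.matrix(sens[, c("ox", "oy", "oz")])
  for (src in c(1L, 57L, 200L)) {
    for (ch in c(1L, 17L, 32L)) {
      expect_equal(
        lf$K[ch, src],
        sphere_dipole_oracle(pos[ch, ], ori[ch, ], ctx$vertices[src, ],
                             nm[src, ]),
        tolerance = 1e-10
      )
    }
  }
})

test_that("a source at the conductor centre is flagged as a zero column", {
  ctx <- small_cortex(seed = 4)
  ctx$vertices[7, ] <- c(0, 0, 0)
  sens <- generate_sensor_array(16)
  nm <- surface_normals(small_cortex(seed = 4))
  expect_warning(lf <- compute_leadfield(ctx, sens, normals = nm),
                 "sphere centre")
  expect_equal(unname(lf$K[, 7]), rep(0, 16))
})

test_that("sensors inside the source compartment are rejected", {
  ctx <- small_cortex(seed = 5)
  sens <- generate_sensor_array(16, helmet_radius = 10)
  expect_error(compute_leadfield(ctx, sens), "outside")
})

test_that("dimensionality reduction projects losslessly at full rank", {
  set.seed(10)
  nc <- 12; nd <- 40; nt <- 9
  K <- matrix(rnorm(nc * nd), nc, nd)
  Y <- matrix(rnorm(nc * nt), nc, nt)
  red <- reduce_dimensionality(K, Y, n_spatial = nc, n_temporal = nt)
  expect_lt(max(abs(tcrossprod(red$U) - diag(nc))), 1e-10)
  expect_lt(max(abs(crossprod(red$V) - diag(nt))), 1e-10)

  Q <- diag(nd)
  full <- free_energy(Y, K, list(Q), h = 0.4, h0 = 1.1, hyperpriors = "flat")
  reduced <- free_energy(red$Y, red$K, list(Q), h = 0.4, h0 = 1.1,
                         hyperpriors = "flat")
  expect_equal(reduced$F, full$F, tolerance = 1e-6)

  # reduced data never carry more energy than the original
  red2 <- reduce_dimensionality(K, Y, n_spatial = 6, n_temporal = 4)
  expect_lte(sum(red2$Y^2), sum(Y^2) + 1e-10)

  expect_warning(reduce_dimensionality(K, Y, n_spatial = 20, n_temporal = nt),
                 "clipped")
  expect_warning(reduce_dimensionality(K, Y, n_spatial = 6, n_temporal = 30),
                 "clipped")
})

test_that("lead-field permutation preserves rows and is seeded and uniform", {
  set.seed(1)
  K <- matrix(rnorm(6 * 10), 6, 10)
  P1 <- permute_leadfields(K, seed = 42)
  P2 <- permute_leadfields(K, seed = 42)
  expect_identical(P1, P2)
  expect_equal(sort(sqrt(rowSums(P1^2))), sort(sqrt(rowSums(K^2))))

  # chi-square uniformity over the 4! permutations of a 4-channel toy case
  K4 <- diag(4) * (1:4)
  perms <- vapply(seq_len(1e4), function(s) {
    paste(attr(permute_leadfields(K4, seed = s), "permutation"),
          collapse = "")
  }, "")
  counts <- table(perms)
  expect_equal(length(counts), 24L)
  p <- stats::chisq.test(as.numeric(counts))$p.value
  expect_gt(p, 0.01)
})
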