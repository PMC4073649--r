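test_that("patch profiles are connected, correctly sized, and degenerate gracefully", {
  ctx <- patch_cortex(seed = 1)
  lib <- build_patch_library(ctx, n_patches = 32, fwhm = 10, seed = 2)
  P <- lib$profiles
  for (k in seq_len(ncol(P))) {
    supp <- which(P[, k] > 0)
    expect_true(bfs_connected(ctx, supp))
    expect_equal(max(P[, k]), 1)  # peak-normalised at the centre
  }

  # measured FWHM along geodesics matches the requested width within an edge
  ed <- megharmonics:::mesh_edges(ctx)
  ctr <- lib$centres[1]
  d <- dijkstra_oracle(ed, nrow(ctx$vertices), ctr)
  above_half <- which(P[, 1] >= 0.5)
  measured <- 2 * max(d[above_half])
  expect_lt(abs(measured - lib$fwhm), 2 * lib$mean_edge_mm)

  expect_warning(build_patch_library(ctx, 4, fwhm = 0.5, seed = 1),
                 "mean edge length")
  tiny <- suppressWarnings(build_patch_library(ctx, 4, fwhm = 1e-6, seed = 1))
  for (k in 1:4) {
    col <- tiny$profiles[, k]
    expect_equal(sum(col > 0), 1L)       # single-vertex indicator
    expect_equal(which(col > 0), tiny$centres[k])
  }
})

test_that("assemble_Q forms the weighted component sum", {
  ctx <- small_cortex(seed = 3)
  lib <- suppressWarnings(build_patch_library(ctx, 6, fwhm = 12, seed = 4))
  nd <- nrow(ctx$vertices)
  expect_equal(assemble_Q(rep(0, 6), lib), matrix(0, nd, nd))
  C1 <- as.matrix(tcrossprod(lib$profiles[, 1]))
  expect_equal(assemble_Q(c(2, rep(0, 5)), lib), 2 * C1)

  set.seed(5)
  h <- runif(6)
  oracle <- matrix(0, nd, nd)
  for (i in 1:6) oracle <- oracle + h[i] * as.matrix(tcrossprod(lib$profiles[, i]))
  expect_equal(assemble_Q(h, lib), oracle, tolerance = 1e-12)

  expect_equal(assemble_Q(0.3, "identity", n_d = 5), diag(0.3, 5))
  expect_error(assemble_Q(c(-1, rep(0, 5)), lib), "non-negative")
})

test_that("posterior mean sources follow the closed form and shrink with noise", {
  expect_equal(estimate_sources(matrix(c(2, 0)), diag(2), diag(2), diag(2)),
               matrix(c(1, 0)))
  expect_equal(estimate_sources(matrix(c(2, 0)), diag(2),
                                matrix(0, 2, 2), diag(2)),
               matrix(0, 2, 1))

  set.seed(6)
  K <- matrix(rnorm(6 * 10), 6, 10)
  Y <- matrix(rnorm(6 * 4), 6, 4)
  A <- matrix(rnorm(100), 10, 10)
  Q <- crossprod(A) / 10
  noise <- diag(6) * 0.8
  oracle <- Q %*% t(K) %*% solve(noise + K %*% Q %*% t(K)) %*% Y
  expect_equal(estimate_sources(Y, K, Q, noise), oracle, tolerance = 1e-8)

  # ridge monotonicity: posterior norm non-increasing in the noise scale
  norms <- vapply(c(0.1, 0.5, 1, 5, 20), function(h0) {
    sqrt(sum(estimate_sources(Y, K, Q, h0)^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("free energy equals the exact Gaussian log evidence for fixed weights", {
  for (seed in 1:3) {
    inst <- random_instance(seed, nc = 12, nd = 20, nt = 6)
    fe <- free_energy(inst$Y, inst$K, list(inst$Q), h = 0.6, h0 = 1.2,
                      hyperpriors = "flat")
    Sig <- 1.2 * diag(12) + 0.6 * inst$K %*% inst$Q %*% t(inst$K)
    expect_equal(fe$F, gaussian_log_evidence(inst$Y, Sig), tolerance = 1e-6)
    expect_equal(fe$complexity, 0)
  }

  # a zero-weight component changes nothing
  inst <- random_instance(9, nc = 10, nd = 15, nt = 5)
  Q2 <- diag(15)
  f1 <- free_energy(inst$Y, inst$K, list(inst$Q), h = 0.5, h0 = 1,
                    hyperpriors = "lognormal")
  f2 <- free_energy(inst$Y, inst$K, list(inst$Q, Q2), h = c(0.5, 0), h0 = 1,
                    hyperpriors = "lognormal")
  expect_equal(f1$F, f2$F, tolerance = 1e-9)

  # two identical epochs double the data-dependent accuracy term
  fa <- free_energy(inst$Y, inst$K, list(inst$Q), h = 0.5, h0 = 1,
                    hyperpriors = "flat")
  fb <- free_energy(cbind(inst$Y, inst$Y), inst$K, list(inst$Q),
                    h = 0.5, h0 = 1, hyperpriors = "flat")
  expect_equal(fb$data_term, 2 * fa$data_term, tolerance = 1e-6)
})

test_that("minimum-norm hyperparameters maximise the exact evidence (grid oracle)", {
  set.seed(2)
  nc <- 10; nd <- 15; nt <- 8
  K <- matrix(rnorm(nc * nd), nc, nd)
  J <- matrix(rnorm(nd * nt, sd = 0.3), nd, nt)
  Y <- K %*% J + matrix(rnorm(nc * nt), nc, nt)
  opt <- optimize_hyperparameters(Y, K, "identity", method = "full",
                                  hyperpriors = "flat")
  expect_true(all(diff(opt$trace) >= -1e-9))

  grid <- seq(-6, 4, by = 0.05)
  KKt <- tcrossprod(K)
  S <- tcrossprod(Y) / nt
  best <- -Inf; arg <- c(NA, NA)
  for (lh in grid) for (l0 in grid) {
    Sig <- exp(l0) * diag(nc) + exp(lh) * KKt
    val <- -0.5 * nt * (nc * log(2 * pi) +
                          as.numeric(determinant(Sig)$modulus) +
                          sum(solve(Sig) * S))
    if (val > best) { best <- val; arg <- c(lh, l0) }
  }
  expect_lt(abs(log(opt$h[1]) - arg[1]), 0.05 + 1e-9)
  expect_lt(abs(log(opt$h0) - arg[2]), 0.05 + 1e-9)
  expect_gte(opt$F, best - 1e-6)
})

test_that("greedy search finds planted patches and reports the best restart", {
  ctx <- patch_cortex(seed = 3)
  sens <- generate_sensor_array(64)
  lf <- compute_leadfield(ctx, sens)
  lib <- build_patch_library(ctx, 64, fwhm = 10, seed = 7)
  set.seed(11)
  planted <- c(5, 40)
  P <- as.matrix(lib$profiles[, planted])
  Ys <- lf$K %*% (P %*% matrix(rnorm(2 * 120), 2, 120))
  Ys <- Ys / sqrt(mean(Ys^2)) * sqrt(100)  # 20 dB vs unit noise
  Y <- Ys + matrix(rnorm(64 * 120), 64, 120)
  red <- reduce_dimensionality(lf$K, Y, 60, 16)
  g <- optimize_hyperparameters(red$Y, red$K, lib, method = "greedy", seed = 1)
  expect_true(all(diff(g$trace) >= -1e-9))
  # every planted centre lies in the support of an accepted component
  supp <- which(Matrix::rowSums(lib$profiles[, g$active, drop = FALSE]) > 0)
  expect_true(all(lib$centres[planted] %in% supp))

  res <- invert(Y, lf, method = "MSP", mesh = ctx, library = lib,
                n_restarts = 3, seed = 5, reduced = red)
  expect_equal(res$F, max(res$restart_F))

  r1 <- invert(Y, lf, method = "MNM", n_restarts = 1, reduced = red)
  r5 <- invert(Y, lf, method = "MNM", n_restarts = 5, reduced = red)
  expect_equal(r1$F, r5$F)
  expect_equal(r1$J_hat, r5$J_hat)
  expect_true(r1$explained_variance >= 0 && r1$explained_variance <= 1)
})

test_that("prior assumptions matched to the data win the evidence comparison", {
  ctx <- patch_cortex(seed = 4)
  sens <- generate_sensor_array(96)
  lf <- compute_leadfield(ctx, sens)
  lib <- build_patch_library(ctx, 96, fwhm = 10, seed = 9)
  nd <- ncol(lf$K)
  wins_patch <- 0L; wins_diffuse <- 0L
  n_runs <- 3L
  for (s in seq_len(n_runs)) {
    set.seed(100 + s)
    # few-patch data (MSP-like)
    P <- as.matrix(lib$profiles[, sample(ncol(lib$profiles), 3)])
    Yp <- lf$K %*% (P %*% matrix(rnorm(3 * 100), 3, 100))
    Yp <- Yp / sqrt(mean(Yp^2)) + matrix(rnorm(96 * 100), 96, 100)
    red <- reduce_dimensionality(lf$K, Yp, 60, 16)
    msp <- invert(Yp, lf, method = "MSP", library = lib, reduced = red, seed = s)
    mnm <- invert(Yp, lf, method = "MNM", reduced = red)
    wins_patch <- wins_patch + (msp$F > mnm$F)
    # many weak uncorrelated sources (minimum-norm-like)
    Jd <- matrix(rnorm(nd * 100, sd = 1), nd, 100)
    Yd <- lf$K %*% Jd
    Yd <- Yd / sqrt(mean(Yd^2)) + matrix(rnorm(96 * 100), 96, 100)
    redd <- reduce_dimensionality(lf$K, Yd, 60, 16)
    mspd <- invert(Yd, lf, method = "MSP", library = lib, reduced = redd, seed = s)
    mnmd <- invert(Yd, lf, method = "MNM", reduced = redd)
    wins_diffuse <- wins_diffuse + (mnmd$F > mspd$F)
  }
  expect_gte(wins_patch, 2L)
  expect_gte(wins_diffuse, 2L)
})
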