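# Shared fixtures, all generated in code.

# Small two-hemisphere cortex (162 vertices per hemisphere, band-limited at 6).
small_cortex <- function(seed = 1, n = 162, amplitudes = 6 / (1:6)) {
  generate_synthetic_cortex(n_vertices = n, amplitudes = amplitudes,
                            seed = seed)
}

# Mid-size cortex matching the patch geometry the inversion tests need
# (edge length well below the 10 mm patch width).
patch_cortex <- function(seed = 1) {
  generate_synthetic_cortex(n_vertices = 642, seed = seed)
}

# Random dense linear-Gaussian instance for the evidence oracles.
random_instance <- function(seed, nc = 30, nd = 50, nt = 10) {
  set.seed(seed)
  K <- matrix(rnorm(nc * nd), nc, nd)
  Y <- matrix(rnorm(nc * nt), nc, nt)
  A <- matrix(rnorm(nd * nd), nd, nd)
  Q <- crossprod(A) / nd
  list(K = K, Y = Y, Q = Q)
}

# Independent closed-form Gaussian log marginal likelihood, summed over
# columns of Y (each an independent sample with covariance Sig).
gaussian_log_evidence <- function(Y, Sig) {
  nc <- nrow(Y)
  ld <- as.numeric(determinant(Sig, logarithm = TRUE)$modulus)
  qf <- sum(vapply(seq_len(ncol(Y)), function(j) {
    y <- Y[, j]
    sum(y * solve(Sig, y))
  }, numeric(1)))
  -0.5 * (ncol(Y) * (nc * log(2 * pi) + ld) + qf)
}

# Plain Dijkstra shortest paths from one vertex, independent of igraph.
dijkstra_oracle <- function(edges, n, from) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]; w <- edges[r, 3]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  dist <- rep(Inf, n)
  dist[from] <- 0
  done <- rep(FALSE, n)
  for (iter in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      v <- nb[r, 1]
      nd <- dist[u] + nb[r, 2]
      if (nd < dist[v]) dist[v] <- nd
    }
  }
  dist
}

# Breadth-first-search connectivity of a vertex subset on a mesh.
bfs_connected <- function(mesh, subset) {
  if (length(subset) <= 1L) return(TRUE)
  ed <- megharmonics:::mesh_edges(mesh)
  keep <- ed[, 1] %in% subset & ed[, 2] %in% subset
  ed <- ed[keep, , drop = FALSE]
  adj <- split(c(ed[, 2], ed[, 1]), c(ed[, 1], ed[, 2]))
  seen <- setNames(rep(FALSE, length(subset)), subset)
  queue <- subset[1]
  seen[as.character(subset[1])] <- TRUE
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[as.character(u)]]) {
      key <- as.character(v)
      if (!is.na(seen[key]) && !seen[key]) {
        seen[key] <- TRUE
        queue <- c(queue, v)
      }
    }
  }
  all(seen)
}
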