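# Parametric-empirical-Bayes machinery.
#
# All evidence computations happen in (possibly reduced) sensor space, where
# the model covariance is a weighted sum of components
#   Sigma(h) = h0 * I  +  sum_i h_i * K C_i K',
# with C_i the source-space covariance components (identity for the minimum
# norm model, rank-1 patch outer products for MSP).  Internally a component
# is one of: identity, rank-1 (vector a with A = a a'), or dense.

comp_identity <- function(n, label = "h0") {
  list(kind = "identity", n = n, label = label)
}
comp_rank1 <- function(a, label) {
  list(kind = "rank1", a = as.numeric(a), label = label)
}
comp_dense <- function(M, label) {
  M <- as.matrix(M)
  list(kind = "dense", M = (M + t(M)) / 2, label = label)
}

comp_matrix <- function(cmp, nc) {
  switch(cmp$kind,
    identity = diag(nc),
    rank1 = tcrossprod(cmp$a),
    dense = cmp$M
  )
}

comp_trace <- function(cmp, nc) {
  switch(cmp$kind,
    identity = nc,
    rank1 = sum(cmp$a^2),
    dense = sum(diag(cmp$M))
  )
}

sigma_assemble <- function(comps, h, nc) {
  Sig <- matrix(0, nc, nc)
  for (i in seq_along(comps)) {
    cmp <- comps[[i]]
    Sig <- Sig + switch(cmp$kind,
      identity = diag(h[i], nc),
      rank1 = h[i] * tcrossprod(cmp$a),
      dense = h[i] * cmp$M
    )
  }
  Sig
}

# Map user-level source components to sensor space through the lead field.
# `components` may be a patch_library, "identity" (minimum norm), a list of
# dense source matrices, or an already-internal list of comp_* entries.
sensor_components <- function(components, K) {
  if (is.list(components) && length(components) &&
      is.list(components[[1]]) && !is.null(components[[1]]$kind)) {
    return(components)
  }
  if (inherits(components, "patch_library")) {
    A <- as.matrix(K %*% components$profiles)
    return(lapply(seq_len(ncol(A)), function(i) {
      comp_rank1(A[, i], label = paste0("patch_", components$centres[i]))
    }))
  }
  if (identical(components, "identity")) {
    return(list(comp_dense(tcrossprod(K), label = "mnm")))
  }
  stopifnot(is.list(components))
  lapply(seq_along(components), function(i) {
    comp_dense(K %*% as.matrix(components[[i]]) %*% t(K),
               label = paste0("component_", i))
  })
}

# Log-likelihood and derivative ingredients at weights h.
# S: sensor sample covariance (Y Y' / N); N: sample count.
evidence_core <- function(comps, h, S, N) {
  nc <- nrow(S)
  Sig <- sigma_assemble(comps, h, nc)
  ch <- tryCatch(chol(Sig), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  logdet <- 2 * sum(log(diag(ch)))
  W <- chol2inv(ch)
  trWS <- sum(W * S)
  logL <- -0.5 * N * (nc * log(2 * pi) + logdet + trWS)
  list(Sig = Sig, W = W, logdet = logdet, trWS = trWS, logL = logL, nc = nc)
}

# Gradient (in h) and Fisher information of logL.
evidence_derivs <- function(comps, h, core, S, N) {
  W <- core$W
  nc <- core$nc
  WSW <- W %*% S %*% W
  k <- length(comps)
  g <- numeric(k)
  img <- vector("list", k)  # W-image of each component for the Fisher terms
  for (i in seq_len(k)) {
    cmp <- comps[[i]]
    if (cmp$kind == "rank1") {
      Wa <- W %*% cmp$a
      g[i] <- 0.5 * N * (sum(cmp$a * (WSW %*% cmp$a)) - sum(cmp$a * Wa))
      img[[i]] <- list(kind = "rank1", a = cmp$a, Wa = drop(Wa))
    } else if (cmp$kind == "identity") {
      g[i] <- 0.5 * N * (sum(diag(WSW)) - sum(diag(W)))
      img[[i]] <- list(kind = "identity")
    } else {
      g[i] <- 0.5 * N * (sum(WSW * cmp$M) - sum(W * cmp$M))
      img[[i]] <- list(kind = "dense", M = cmp$M, WM = W %*% cmp$M)
    }
  }
  FI <- matrix(0, k, k)
  WW <- NULL
  for (i in seq_len(k)) {
    for (j in i:k) {
      a <- img[[i]]; b <- img[[j]]
      v <- if (a$kind == "rank1" && b$kind == "rank1") {
        sum(b$a * a$Wa)^2
      } else if (a$kind == "rank1" && b$kind == "identity") {
        sum(a$Wa^2)
      } else if (a$kind == "identity" && b$kind == "rank1") {
        sum(b$Wa^2)
      } else if (a$kind == "identity" && b$kind == "identity") {
        sum(W * W)
      } else if (a$kind == "rank1" && b$kind == "dense") {
        sum(a$Wa * (b$M %*% a$Wa))
      } else if (a$kind == "dense" && b$kind == "rank1") {
        sum(b$Wa * (a$M %*% b$Wa))
      } else if (a$kind == "identity" && b$kind == "dense") {
        if (is.null(WW)) WW <- W %*% W
        sum(WW * b$M)
      } else if (a$kind == "dense" && b$kind == "identity") {
        if (is.null(WW)) WW <- W %*% W
        sum(WW * a$M)
      } else {
        sum((a$WM %*% W) * b$M)
      }
      FI[i, j] <- FI[j, i] <- 0.5 * N * v
    }
  }
  list(g = g, FI = FI)
}

# Variational-Laplace free energy at log-weights lambda.
# hp: NULL for flat hyperpriors (F = exact Gaussian log evidence), or
# list(eta, prec) for independent normal priors on each log-weight.
free_energy_at <- function(comps, lambda, S, N, hp = NULL) {
  h <- exp(lambda)
  core <- evidence_core(comps, h, S, N)
  if (is.null(core)) return(NULL)
  if (is.null(hp)) {
    return(list(F = core$logL, accuracy = core$logL, complexity = 0,
                data_term = -0.5 * N * core$trWS, core = core, h = h))
  }
  de <- evidence_derivs(comps, h, core, S, N)
  Ilam <- de$FI * tcrossprod(h)
  quad <- sum(hp$prec * (lambda - hp$eta)^2)
  M <- diag(length(lambda)) + sweep(Ilam, 1L, hp$prec, "/")
  vol <- as.numeric(determinant(M, logarithm = TRUE)$modulus)
  complexity <- 0.5 * quad + 0.5 * vol
  list(F = core$logL - complexity, accuracy = core$logL,
       complexity = complexity, data_term = -0.5 * N * core$trWS,
       core = core, derivs = de, Ilam = Ilam, h = h)
}

# ReML / EM-style ascent on log-weights, Fisher-scored with step halving so
# the free energy trace is non-decreasing.  Returns best-so-far on
# non-convergence, flagged.
reml_fit <- function(comps, S, N, lambda_init, hp = NULL,
                     max_iter = 128, tol = 1e-4) {
  k <- length(comps)
  lambda <- pmin(30, pmax(-30, lambda_init))
  cur <- free_energy_at(comps, lambda, S, N, hp)
  if (is.null(cur)) stop("initial covariance model is not positive definite",
                         call. = FALSE)
  trace <- cur$F
  converged <- FALSE
  prec <- if (is.null(hp)) rep(0, k) else hp$prec
  eta <- if (is.null(hp)) rep(0, k) else hp$eta
  for (iter in seq_len(max_iter)) {
    de <- if (!is.null(cur$derivs)) cur$derivs else {
      evidence_derivs(comps, cur$h, cur$core, S, N)
    }
    glam <- de$g * cur$h - prec * (lambda - eta)
    Ilam <- de$FI * tcrossprod(cur$h)
    H <- Ilam + diag(prec + 1e-8, k)
    step <- tryCatch(solve(H, glam), error = function(e) glam / (diag(H) + 1))
    sn <- sqrt(sum(step^2))
    if (sn > 8) step <- step * (8 / sn)  # trust region on log scale
    improved <- FALSE
    for (half in 0:11) {
      cand_l <- pmin(30, pmax(-30, lambda + step / 2^half))
      cand <- free_energy_at(comps, cand_l, S, N, hp)
      if (!is.null(cand) && cand$F > cur$F) {
        dF <- cand$F - cur$F
        lambda <- cand_l
        cur <- cand
        trace <- c(trace, cur$F)
        improved <- TRUE
        break
      }
    }
    if (!improved) { converged <- TRUE; break }
    if (dF < tol) { converged <- TRUE; break }
  }
  list(lambda = lambda, h = exp(lambda), F = cur$F,
       accuracy = cur$accuracy, complexity = cur$complexity,
       trace = trace, converged = converged, eval = cur)
}

default_hyperpriors <- function(k, mean = -8, precision = 1 / 256) {
  list(eta = rep(mean, k), prec = rep(precision, k))
}

# Crude initial log-weights: split half the data power between noise and the
# source components (equally by trace).
init_lambda <- function(comps, S) {
  nc <- nrow(S)
  tp <- mean(diag(S))
  k <- length(comps)
  vapply(seq_len(k), function(i) {
    tr <- comp_trace(comps[[i]], nc) / nc
    log(max(0.5 * tp / (max(k - 1, 1) * max(tr, 1e-12)), 1e-12))
  }, numeric(1))
}

#' Variational free energy of a fixed covariance model
#'
#' Evaluates the (negative variational) free energy — the lower bound on the
#' log model evidence `log p(Y)` — of the linear Gaussian model
#' `Y = K J + e` with prior source covariance `sum_i h_i C_i` and sensor
#' noise `h0 * I`, at *fixed* hyperparameters.  With flat hyperpriors this
#' equals the exact Gaussian log marginal likelihood of `Y` under model
#' covariance `h0 I + K Q K'`; with log-normal hyperpriors a
#' Laplace-approximation complexity penalty (hyperprior energy plus
#' posterior-volume term) is subtracted.  The return value splits into an
#' accuracy and a complexity part, `F = accuracy - complexity`.
#'
#' @param Y Sensor data (channels x samples).
#' @param K Lead field (matrix or `leadfield`).
#' @param components Source covariance components: a [build_patch_library()]
#'   object, `"identity"`, or a list of dense `N_d x N_d` matrices.
#' @param h Non-negative component weights (zero-weight components are
#'   dropped: they contribute nothing to the model covariance and carry no
#'   hyperparameter).
#' @param h0 Sensor-noise scale (> 0).
#' @param hyperpriors `"flat"` or `"lognormal"`.
#' @param hyperprior_mean,hyperprior_precision Log-normal hyperprior
#'   parameters per log-weight (defaults -8 and 1/256).
#'
#' @return List with `F`, `accuracy`, `complexity` and `data_term` (the
#'   data-dependent part of the accuracy, `-N/2 * tr(Sigma^-1 S)`).
#' @export
free_energy <- function(Y, K, components, h, h0,
                        hyperpriors = c("flat", "lognormal"),
                        hyperprior_mean = -8, hyperprior_precision = 1 / 256) {
  hyperpriors <- match.arg(hyperpriors)
  Km <- leadfield_matrix(K)
  Y <- as.matrix(Y)
  stopifnot(h0 > 0, all(h >= 0))
  src <- sensor_components(components, Km)
  stopifnot(length(h) == length(src))
  keep <- which(h > 0)
  comps <- c(list(comp_identity(nrow(Y))), src[keep])
  hh <- c(h0, h[keep])
  N <- ncol(Y)
  S <- tcrossprod(Y) / N
  hp <- if (hyperpriors == "lognormal") {
    default_hyperpriors(length(comps), hyperprior_mean, hyperprior_precision)
  }
  out <- free_energy_at(comps, log(hh), S, N, hp)
  if (is.null(out)) stop("assembled model covariance is not positive definite",
                         call. = FALSE)
  out[c("F", "accuracy", "complexity", "data_term")]
}

#' Posterior mean source estimate for a known prior covariance
#'
#' The conditional expectation of the sources given the data under the
#' linear Gaussian model: `J_hat = Q K' (Sigma_e + K Q K')^-1 Y`.
#'
#' @param Y Sensor data (channels x samples).
#' @param K Lead field (matrix or `leadfield`).
#' @param Q Prior source covariance (`N_d x N_d`).
#' @param noise Sensor noise covariance `Sigma_e` (`N_c x N_c`, positive
#'   definite), or a scalar meaning that multiple of the identity.
#' @return `N_d x N_t` posterior mean current matrix.
#' @export
estimate_sources <- function(Y, K, Q, noise) {
  Km <- leadfield_matrix(K)
  Y <- as.matrix(Y)
  nc <- nrow(Km)
  if (length(noise) == 1L) noise <- diag(as.numeric(noise), nc)
  Sy <- noise + Km %*% Q %*% t(Km)
  if (rcond(Sy) < .Machine$double.eps * 10) {
    stop("model covariance (Sigma_e + K Q K') is numerically singular",
         call. = FALSE)
  }
  Q %*% t(Km) %*% solve(Sy, Y)
}

#' Optimise covariance hyperparameters by free-energy ascent
#'
#' Maximises the variational free energy over the log hyperparameters of a
#' covariance component model by Fisher-scored restricted maximum likelihood
#' with step halving, so the free-energy trace is non-decreasing.  Two
#' regimes: `"full"` optimises all components jointly (the minimum-norm
#' model: noise plus identity source covariance), and `"greedy"` grows a
#' sparse active set for MSP — starting from the patch whose sensor pattern
#' correlates most with the data, candidates are tried in correlation order
#' and an addition is kept only if it increases the free energy.
#'
#' @param Y Sensor data (channels x samples), usually reduced.
#' @param K Lead field (matrix or `leadfield`), same channel space as `Y`.
#' @param components Source components (see [free_energy()]).
#' @param method `"full"` or `"greedy"`.
#' @param seed Integer seed (tie-breaks in the candidate ordering).
#' @param hyperpriors `"lognormal"` (default) or `"flat"`.
#' @param control List of tuning constants: `max_iter` (128), `tol` (1e-4),
#'   `n_candidates` (trial budget, 32), `max_active` (12), `stall`
#'   (consecutive rejected additions before stopping, 6), `trial_iter`
#'   (ascent iterations per trial addition, 8), `hyperprior_mean` (-8),
#'   `hyperprior_precision` (1/256).
#'
#' @return List with `h` (named weights over *all* supplied components;
#'   inactive ones are 0), `h0` (noise scale), `F`, `trace` (non-decreasing
#'   free-energy trace), `converged`, and `active` (component indices).
#' @export
optimize_hyperparameters <- function(Y, K, components,
                                     method = c("full", "greedy"),
                                     seed = 1,
                                     hyperpriors = c("lognormal", "flat"),
                                     control = list()) {
  method <- match.arg(method)
  hyperpriors <- match.arg(hyperpriors)
  ctl <- utils::modifyList(list(
    max_iter = 128, tol = 1e-4, n_candidates = 32, max_active = 12,
    stall = 6, trial_iter = 8, hyperprior_mean = -8,
    hyperprior_precision = 1 / 256
  ), control)
  Km <- leadfield_matrix(K)
  Y <- as.matrix(Y)
  src <- sensor_components(components, Km)
  N <- ncol(Y)
  S <- tcrossprod(Y) / N
  nc <- nrow(Y)
  noise <- comp_identity(nc)
  hp_for <- function(k) {
    if (hyperpriors == "flat") NULL
    else default_hyperpriors(k, ctl$hyperprior_mean, ctl$hyperprior_precision)
  }

  finish <- function(fit, active) {
    h_all <- numeric(length(src))
    names(h_all) <- vapply(src, `[[`, "", "label")
    if (length(active)) h_all[active] <- fit$h[-1L]
    list(h = h_all, h0 = fit$h[1L], F = fit$F, trace = fit$trace,
         accuracy = fit$accuracy, complexity = fit$complexity,
         converged = fit$converged, active = active)
  }

  if (method == "full") {
    comps <- c(list(noise), src)
    fit <- reml_fit(comps, S, N, init_lambda(comps, S), hp_for(length(comps)),
                    max_iter = ctl$max_iter, tol = ctl$tol)
    return(finish(fit, seq_along(src)))
  }

  # greedy matching-pursuit search: candidates are ranked by the estimated
  # free-energy gain of adding them to the *current* model (the squared
  # evidence gradient at weight zero over its curvature), re-ranked after
  # every accepted addition so patches masked by already-explained variance
  # surface once the explaining component is in the model
  if (!all(vapply(src, `[[`, "", "kind") == "rank1")) {
    stop("greedy search expects rank-1 (patch) components", call. = FALSE)
  }
  A <- vapply(src, `[[`, numeric(nc), "a")

  # start from the noise-only model
  comps <- list(noise)
  fit <- reml_fit(comps, S, N, init_lambda(comps, S), hp_for(1L),
                  max_iter = ctl$max_iter, tol = ctl$tol)
  trace <- fit$trace
  active <- integer(0)
  tried <- rep(FALSE, length(src))
  stall <- 0L
  gain_estimate <- function() {
    core <- evidence_core(comps, fit$h, S, N)
    W <- core$W
    WA <- W %*% A
    u <- colSums(A * WA)                       # a' W a
    v <- colSums(WA * (S %*% WA))              # a' W S W a
    g <- 0.5 * N * (v - u)
    est <- ifelse(g > 0, g^2 / (N * u^2), -Inf) # one-Newton-step gain
    est[tried] <- -Inf
    est
  }
  budget <- ctl$n_candidates
  while (length(active) < ctl$max_active && stall < ctl$stall && budget > 0L) {
    est <- gain_estimate()
    cand <- which.max(est)
    if (!is.finite(est[cand]) || est[cand] <= 0) break
    tried[cand] <- TRUE
    budget <- budget - 1L
    comps_t <- c(list(noise), src[c(active, cand)])
    lam_new <- if (length(active)) min(fit$lambda[-1L]) else
      fit$lambda[1L] - 2
    fit_t <- reml_fit(comps_t, S, N, c(fit$lambda, lam_new),
                      hp_for(length(comps_t)),
                      max_iter = ctl$trial_iter, tol = ctl$tol)
    if (fit_t$F > fit$F) {
      active <- c(active, cand)
      comps <- comps_t
      fit <- fit_t
      trace <- c(trace, fit$F)
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
  }
  if (length(active) == 0L) {
    # no patch improves on the noise-only model; report it as-is
    return(finish(fit, active))
  }
  comps_f <- c(list(noise), src[active])
  fit_f <- reml_fit(comps_f, S, N, fit$lambda, hp_for(length(comps_f)),
                    max_iter = ctl$max_iter, tol = ctl$tol)
  if (fit_f$F >= fit$F) {
    fit <- fit_f
    trace <- c(trace, fit_f$F[fit_f$F > trace[length(trace)]])
  }
  fit$trace <- trace
  finish(fit, active)
}
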