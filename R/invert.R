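#' Invert sensor data onto a cortical surface model
#'
#' Full source reconstruction of one dataset on one anatomical model:
#' dimensionality reduction, hyperparameter optimisation by free-energy
#' ascent under either minimum-norm (`"MNM"`: identity prior source
#' covariance, a single deterministic fit) or multiple-sparse-priors
#' (`"MSP"`: optimised mixture of patch components, greedy search)
#' assumptions, posterior mean currents, and the free energy (log-evidence
#' bound) used for model comparison.
#'
#' For MSP, `n_restarts > 1` repeats the inversion with freshly randomised
#' patch libraries (seeds derived from `seed` by fixed offsets) and returns
#' the solution with the highest free energy; MNM has no stochastic element
#' and ignores restarts.
#'
#' When several anatomical models are compared, pass the *same* spatial
#' projector `U` (from the reference model's lead field) for every model so
#' the free energies refer to identical data; [run_experiment()] does this
#' automatically.
#'
#' @param Y Sensor data (channels x samples).
#' @param leadfield Lead field for this anatomy ([compute_leadfield()] or
#'   matrix).
#' @param method `"MSP"` or `"MNM"`.
#' @param mesh The anatomy's [cortical_mesh()]; needed to build patch
#'   libraries when `library` is not supplied.
#' @param library A [build_patch_library()] object (first restart's library).
#' @param n_patches,fwhm Patch-library parameters used when libraries are
#'   built internally.
#' @param n_restarts MSP restarts (default 1).
#' @param seed Integer master seed.
#' @param U Optional shared spatial projector (rows orthonormal).
#' @param n_spatial,n_temporal Reduction dimensions (defaults 60 / 16).
#' @param hyperpriors `"lognormal"` (default) or `"flat"`.
#' @param control Optimiser control, see [optimize_hyperparameters()].
#' @param reduced Optionally a pre-built [reduce_dimensionality()] object
#'   (overrides `U`/`n_spatial`/`n_temporal`).
#'
#' @return An object of class `inversion_result`: `J_hat` (`N_d` x
#'   `n_temporal` posterior mean currents in the reduced temporal basis),
#'   `V` (temporal modes, so `J_hat %*% t(V)` recovers the full time
#'   courses), `F`, `h`, `h0`, `posterior_var` (per-vertex posterior
#'   variance, diagonal), `explained_variance` (reduced space) and
#'   `explained_variance_spatial` (spatial-mode space, before temporal
#'   projection), `method`, `restart` (index of the winning restart) and
#'   `restart_F` (all restarts' free energies).
#' @export
invert <- function(Y, leadfield, method = c("MSP", "MNM"),
                   mesh = NULL, library = NULL,
                   n_patches = 128, fwhm = 10,
                   n_restarts = 1, seed = 1,
                   U = NULL, n_spatial = 60, n_temporal = 16,
                   hyperpriors = c("lognormal", "flat"),
                   control = list(), reduced = NULL) {
  method <- match.arg(method)
  hyperpriors <- match.arg(hyperpriors)
  Km <- leadfield_matrix(leadfield)
  if (is.null(reduced)) {
    reduced <- reduce_dimensionality(Km, Y, n_spatial, n_temporal, U = U)
  }
  Kr <- reduced$K
  Yr <- reduced$Y
  nd <- ncol(Kr)

  fit_one <- function(lib, rseed) {
    if (method == "MNM") {
      opt <- optimize_hyperparameters(Yr, Kr, "identity", method = "full",
                                      seed = rseed, hyperpriors = hyperpriors,
                                      control = control)
    } else {
      opt <- optimize_hyperparameters(Yr, Kr, lib, method = "greedy",
                                      seed = rseed, hyperpriors = hyperpriors,
                                      control = control)
    }
    list(opt = opt, lib = lib)
  }

  if (method == "MNM") {
    runs <- list(fit_one(NULL, seed))
  } else {
    if (is.null(library)) {
      if (is.null(mesh)) stop("supply `mesh` or `library` for MSP", call. = FALSE)
      library <- build_patch_library(mesh, n_patches, fwhm, seed = seed)
    }
    runs <- vector("list", n_restarts)
    runs[[1L]] <- fit_one(library, seed)
    if (n_restarts > 1) {
      for (r in 2:n_restarts) {
        lib_r <- build_patch_library(mesh, length(library$centres),
                                     library$fwhm, seed = seed + 7919L * r)
        runs[[r]] <- fit_one(lib_r, seed + 7919L * r)
      }
    }
  }
  Fs <- vapply(runs, function(r) r$opt$F, numeric(1))
  best <- which.max(Fs)
  opt <- runs[[best]]$opt
  lib <- runs[[best]]$lib

  # posterior mean and per-vertex posterior variance in source space
  nc <- nrow(Kr)
  if (method == "MNM") {
    h_mnm <- unname(opt$h[1L])
    Qdiag <- rep(h_mnm, nd)
    QKt <- h_mnm * t(Kr)
    Sy <- opt$h0 * diag(nc) + h_mnm * tcrossprod(Kr)
  } else {
    P <- lib$profiles
    hvec <- opt$h
    A <- as.matrix(Kr %*% P)
    Qdiag <- as.numeric((P^2) %*% hvec)
    QKt <- as.matrix(P %*% (hvec * t(A)))
    Sy <- opt$h0 * diag(nc) + A %*% (hvec * t(A))
  }
  W <- chol2inv(chol(Sy))
  J_hat <- QKt %*% (W %*% Yr)
  post_var <- pmax(0, Qdiag - rowSums((QKt %*% W) * QKt))
  fit_Y <- Kr %*% J_hat
  ev <- 1 - sum((Yr - fit_Y)^2) / sum(Yr^2)
  Yu <- reduced$U %*% if (is.matrix(Y)) Y else as.matrix(Y)
  fit_u <- fit_Y %*% t(reduced$V)
  ev_sp <- 1 - sum((Yu - fit_u)^2) / sum(Yu^2)

  structure(
    list(J_hat = J_hat, V = reduced$V, F = opt$F, h = opt$h, h0 = opt$h0,
         posterior_var = post_var,
         explained_variance = max(0, min(1, ev)),
         explained_variance_spatial = max(0, min(1, ev_sp)),
         method = method, hyperpriors = hyperpriors,
         active = opt$active, trace = opt$trace, converged = opt$converged,
         restart = best, restart_F = Fs, library = lib, seed = seed),
    class = "inversion_result"
  )
}

#' @export
print.inversion_result <- function(x, ...) {
  cat("<inversion_result> ", x$method, ": F = ", signif(x$F, 6),
      ", explained variance = ", signif(x$explained_variance, 3),
      ", ", length(x$active), " active component(s)\n", sep = "")
  invisible(x)
}

#' Tidy a source inversion
#'
#' @param x An `inversion_result`.
#' @param ... Unused.
#' @return A tibble with one row per source vertex: RMS posterior current
#'   over the reduced temporal modes and the posterior standard deviation.
#' @export
tidy.inversion_result <- function(x, ...) {
  tibble::tibble(
    vertex = seq_len(nrow(x$J_hat)),
    amplitude_rms = sqrt(rowMeans(x$J_hat^2)),
    posterior_sd = sqrt(x$posterior_var)
  )
}

#' @rdname tidy.inversion_result
#' @export
glance.inversion_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    F = x$F,
    explained_variance = x$explained_variance,
    explained_variance_spatial = x$explained_variance_spatial,
    n_active = length(x$active),
    converged = x$converged,
    restart = x$restart
  )
}
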