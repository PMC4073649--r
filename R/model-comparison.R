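#' Pairwise posterior probability of a surface model against the reference
#'
#' Under flat model priors (each model a priori equally likely), the
#' posterior probability that the reduced-order surface is the better model
#' than the reference anatomy is
#' \deqn{p(m = L | Y) = \frac{1}{1 + \exp(F_{ref} - F_L)},}
#' a logistic function of the log-evidence difference.  A difference of 3
#' log units makes the reduced model about 20 times less likely
#' (`p` just under 0.05), which is the conventional discrimination
#' threshold.
#'
#' @param F_L Log evidence(s) of the candidate model(s).
#' @param F_ref Log evidence of the reference (most complete) model.
#' @return Probabilities in `[0, 1]`, same length as `F_L`; monotone
#'   increasing in `F_L` and saturating gracefully at extreme differences.
#' @export
#' @examples
#' pairwise_posterior(0, 0)       # 0.5
#' pairwise_posterior(-3, 0)      # 1 / (1 + exp(3)) ~ 0.047
pairwise_posterior <- function(F_L, F_ref) {
  stopifnot(all(is.finite(F_L)), all(is.finite(F_ref)))
  stats::plogis(F_L - F_ref)
}

#' Highest distinguishable harmonic (HDH)
#'
#' The largest harmonic order whose surface model is still rejected against
#' the reference anatomy, i.e. the largest `L` with pairwise posterior below
#' `threshold`.  Because the spatial distortion of surface `L` bounds the
#' displacement of any estimate it supports, the HDH converts the evidence
#' curve into an empirical distortion bound.  If no model falls below
#' threshold the data do not distinguish any anatomy (`hdh = 0`,
#' `indistinguishable = TRUE`); the curve need not be monotone, and the
#' *highest* sub-threshold order is taken even if intermediate orders are
#' above threshold.
#'
#' @param p_by_L Pairwise posteriors, named (or indexed) by harmonic order
#'   `L = 1..Lmax-1`.
#' @param threshold Probability cutoff (default 0.05, the "20 times less
#'   likely" line).
#' @param L Optional explicit orders matching `p_by_L` (defaults to names or
#'   positions).
#' @return A list with `hdh` (integer order, 0 if none) and
#'   `indistinguishable` (logical).
#' @export
compute_hdh <- function(p_by_L, threshold = 0.05, L = NULL) {
  if (is.null(L)) {
    L <- if (!is.null(names(p_by_L))) as.integer(names(p_by_L))
         else seq_along(p_by_L)
  }
  stopifnot(length(L) == length(p_by_L))
  below <- which(p_by_L < threshold)
  if (length(below) == 0L) {
    return(list(hdh = 0L, indistinguishable = TRUE))
  }
  list(hdh = as.integer(max(L[below])), indistinguishable = FALSE)
}

#' Fixed-effects posterior over the surviving model set
#'
#' Softmax of the log evidences over the models that survive the HDH cut
#' (those not distinguishable from the reference).  Invariant to adding a
#' constant to every log evidence; sums to 1.
#'
#' @param F_models Log evidences of the surviving models (non-empty).
#' @return Probabilities summing to 1.
#' @export
fixed_effects_posterior <- function(F_models) {
  if (length(F_models) == 0L) stop("empty model set", call. = FALSE)
  stopifnot(all(is.finite(F_models)))
  z <- F_models - max(F_models)
  p <- exp(z)
  p / sum(p)
}

#' Pool log evidences across runs or data segments
#'
#' Fixed-effects pooling: independent runs (repetitions, data segments)
#' multiply evidences, so log evidences add elementwise per model.
#'
#' @param F_runs A numeric matrix (runs x models), or a data frame / tibble
#'   with columns identifying the model and a log-evidence column, or a list
#'   of equal-length named vectors.
#' @return Named vector of pooled log evidences (for matrix/list input).
#' @export
pool_evidence <- function(F_runs) {
  if (is.list(F_runs) && !is.data.frame(F_runs)) {
    lens <- lengths(F_runs)
    if (length(unique(lens)) != 1L) stop("ragged run list", call. = FALSE)
    F_runs <- do.call(rbind, F_runs)
  }
  F_runs <- as.matrix(F_runs)
  colSums(F_runs)
}

#' Build a model-comparison table from per-run log evidences
#'
#' Pools log evidences over runs (fixed effects), forms the pairwise
#' posterior of every order against the reference (highest) order, finds
#' the HDH, and computes the fixed-effects posterior over the surviving
#' models (orders above the HDH, including the reference).
#'
#' @param evidence A tibble/data.frame with columns `L`, `F` and optionally
#'   `run` (pooled over if present).
#' @param threshold HDH probability cutoff (default 0.05).
#' @param reference_L Reference order (default: the maximum `L` present).
#' @return A tibble of class `model_comparison` with columns `L`,
#'   `F_pooled`, `delta_F` (vs reference), `p_pairwise`, `in_surviving_set`,
#'   `posterior`, and attributes `hdh`, `indistinguishable`, `threshold`,
#'   `reference_L`.
#' @export
model_comparison_table <- function(evidence, threshold = 0.05,
                                   reference_L = NULL) {
  stopifnot(all(c("L", "F") %in% names(evidence)))
  tab <- evidence |>
    dplyr::group_by(.data$L) |>
    dplyr::summarise(F_pooled = sum(.data$F), n_runs = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$L)
  if (length(unique(tab$n_runs)) != 1L) {
    stop("unbalanced runs across models: every model must be evaluated on ",
         "the same runs for fixed-effects pooling", call. = FALSE)
  }
  if (is.null(reference_L)) reference_L <- max(tab$L)
  F_ref <- tab$F_pooled[tab$L == reference_L]
  if (length(F_ref) != 1L) stop("reference order not present", call. = FALSE)
  tab <- tab |>
    dplyr::mutate(
      delta_F = .data$F_pooled - F_ref,
      p_pairwise = pairwise_posterior(.data$F_pooled, F_ref)
    )
  lower <- tab$L < reference_L
  hdh <- compute_hdh(tab$p_pairwise[lower], threshold, L = tab$L[lower])
  tab <- tab |>
    dplyr::mutate(in_surviving_set = .data$L > hdh$hdh)
  post <- rep(NA_real_, nrow(tab))
  post[tab$in_surviving_set] <- fixed_effects_posterior(
    tab$F_pooled[tab$in_surviving_set])
  tab$posterior <- post
  tab$n_runs <- NULL
  attr(tab, "hdh") <- hdh$hdh
  attr(tab, "indistinguishable") <- hdh$indistinguishable
  attr(tab, "threshold") <- threshold
  attr(tab, "reference_L") <- reference_L
  class(tab) <- c("model_comparison", class(tab))
  tab
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("# Model comparison (reference L = ", attr(x, "reference_L"),
      ", threshold = ", attr(x, "threshold"), ")\n", sep = "")
  if (attr(x, "indistinguishable")) {
    cat("# HDH: none -- no surface model distinguishable from the reference\n")
  } else {
    cat("# HDH =", attr(x, "hdh"), "\n")
  }
  NextMethod()
}

#' @rdname model_comparison_table
#' @param x A `model_comparison` table.
#' @param ... Unused.
#' @export
glance.model_comparison <- function(x, ...) {
  tibble::tibble(
    hdh = attr(x, "hdh"),
    indistinguishable = attr(x, "indistinguishable"),
    threshold = attr(x, "threshold"),
    reference_L = attr(x, "reference_L"),
    map_L = x$L[which.max(dplyr::coalesce(x$posterior, -Inf))]
  )
}

#' Per-vertex log power modulation between two time windows
#'
#' The natural-log ratio of post-window to pre-window source power (mean
#' squared amplitude over the window) at each vertex, e.g. 1 s pre-stimulus
#' vs 1 s post-stimulus.  With several trials, a per-vertex t-statistic of
#' the log ratio across trials is added.
#'
#' @param J_hat `N_d x N_t` source current matrix, or a list of such
#'   matrices (one per trial).
#' @param pre_window,post_window Column (sample) indices of the two windows.
#' @return A tibble with columns `vertex`, `log_power_ratio` (and
#'   `t_statistic`, `n_trials` for multi-trial input).  Vertices with zero
#'   pre-window power get `NA` with a flag column `undefined`.
#' @export
power_modulation <- function(J_hat, pre_window, post_window) {
  stopifnot(length(pre_window) > 0, length(post_window) > 0)
  one <- function(J) {
    J <- as.matrix(J)
    pre <- rowMeans(J[, pre_window, drop = FALSE]^2)
    post <- rowMeans(J[, post_window, drop = FALSE]^2)
    ratio <- ifelse(pre > 0, log(post / pre), NA_real_)
    ratio
  }
  if (is.list(J_hat) && !is.matrix(J_hat)) {
    R <- vapply(J_hat, one, numeric(nrow(as.matrix(J_hat[[1]]))))
    mean_r <- rowMeans(R)
    sd_r <- apply(R, 1L, stats::sd)
    tstat <- mean_r / (sd_r / sqrt(ncol(R)))
    tibble::tibble(
      vertex = seq_along(mean_r),
      log_power_ratio = mean_r,
      t_statistic = tstat,
      n_trials = ncol(R),
      undefined = !is.finite(mean_r)
    )
  } else {
    r <- one(J_hat)
    tibble::tibble(
      vertex = seq_along(r),
      log_power_ratio = r,
      undefined = !is.finite(r)
    )
  }
}

#' Posterior probability of a power decrease per vertex, for one model
#'
#' Gaussian/sampling approximation of the vertex-wise posterior of the log
#' power ratio: currents are drawn from the inversion's posterior (mean
#' `J_hat`, per-vertex posterior variance) and the log ratio of post- to
#' pre-window power computed per draw.
#'
#' @param result An [invert()] result.
#' @param pre_window,post_window Sample indices into the reconstructed time
#'   courses (`J_hat %*% t(V)` space when `use_full_time = TRUE`, reduced
#'   temporal modes otherwise).
#' @param n_draws Monte-Carlo draws (default 1000).
#' @param seed Integer seed.
#' @param use_full_time Evaluate windows on the back-projected full-length
#'   time courses (default `TRUE`).
#' @return A tibble with `vertex`, `mean_log_ratio`, `sd_log_ratio`,
#'   `p_decrease`.
#' @export
modulation_posterior <- function(result, pre_window, post_window,
                                 n_draws = 1000, seed = 1,
                                 use_full_time = TRUE) {
  stopifnot(inherits(result, "inversion_result"))
  J <- if (use_full_time) result$J_hat %*% t(result$V) else result$J_hat
  nd <- nrow(J)
  sdv <- sqrt(result$posterior_var)
  npre <- length(pre_window); npost <- length(post_window)
  with_seed(seed, {
    acc_ratio <- matrix(0, nd, n_draws)
    for (d in seq_len(n_draws)) {
      Epre <- matrix(stats::rnorm(nd * npre), nd, npre) * sdv
      Epost <- matrix(stats::rnorm(nd * npost), nd, npost) * sdv
      pre <- rowMeans((J[, pre_window, drop = FALSE] + Epre)^2)
      post <- rowMeans((J[, post_window, drop = FALSE] + Epost)^2)
      acc_ratio[, d] <- log(post / pre)
    }
    tibble::tibble(
      vertex = seq_len(nd),
      mean_log_ratio = rowMeans(acc_ratio),
      sd_log_ratio = apply(acc_ratio, 1L, stats::sd),
      p_decrease = rowMeans(acc_ratio < 0)
    )
  })
}

#' Joint posterior probability of a power decrease over surviving models
#'
#' Integrates the per-model posterior probability of a negative log power
#' ratio over the fixed-effects posterior on the surviving anatomical
#' models: `P(decrease) = sum_L w_L * P(log ratio < 0 | model L)` per
#' vertex.  The result is a statement of the form "probability `p` of a
#' power decrease at this location to within the HDH distortion bound".
#'
#' @param modulations List (one per surviving model) of tibbles with columns
#'   `vertex` and `p_decrease` (as from [modulation_posterior()]).
#' @param weights Fixed-effects posterior weights, summing to 1.
#' @return A tibble with `vertex` and `p_decrease`.
#' @export
joint_modulation_probability <- function(modulations, weights) {
  stopifnot(length(modulations) == length(weights))
  if (abs(sum(weights) - 1) > 1e-8) {
    stop("`weights` must sum to 1", call. = FALSE)
  }
  p <- Reduce(`+`, Map(function(m, w) w * m$p_decrease, modulations, weights))
  tibble::tibble(vertex = modulations[[1]]$vertex, p_decrease = p)
}
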