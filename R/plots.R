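#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a model-comparison curve
#'
#' Pairwise posterior probability of each harmonic surface against the
#' reference anatomy, with the discrimination threshold; the highest order
#' crossing below the line is the HDH.
#'
#' @param object A [model_comparison_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.model_comparison <- function(object, ...) {
  thr <- attr(object, "threshold")
  hdh <- attr(object, "hdh")
  df <- dplyr::filter(object, .data$L < attr(object, "reference_L"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$L, y = .data$p_pairwise)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::labs(
      x = "harmonic order L",
      y = "p(m = L | Y) vs reference",
      subtitle = if (hdh > 0) paste0("HDH = ", hdh) else "indistinguishable"
    )
  if (hdh > 0) p <- p + ggplot2::geom_vline(xintercept = hdh, linetype = "dotted")
  p
}

#' Plot experiment evidence curves
#'
#' One pairwise-posterior curve per scenario and method against harmonic
#' order, with the discrimination threshold.
#'
#' @param object An [run_experiment()] result.
#' @param what `"p"` (pairwise posterior) or `"delta_F"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hdh_experiment <- function(object, what = c("p", "delta_F"), ...) {
  what <- match.arg(what)
  thr <- object$config$threshold
  ref_L <- object$config$Lmax
  df <- purrr::imap_dfr(object$tables, function(tab, key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    tibble::tibble(scenario = parts[1], method = parts[2],
                   L = tab$L, p_pairwise = tab$p_pairwise,
                   delta_F = tab$delta_F)
  }) |> dplyr::filter(.data$L < ref_L)
  if (what == "p") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$L, y = .data$p_pairwise,
                                     colour = .data$method)) +
      ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
      ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
      ggplot2::facet_wrap(ggplot2::vars(.data$scenario)) +
      ggplot2::labs(x = "harmonic order L", y = "p(m = L | Y) vs reference")
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$L, y = .data$delta_F,
                                     colour = .data$method)) +
      ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
      ggplot2::geom_hline(yintercept = -3, linetype = "dashed") +
      ggplot2::facet_wrap(ggplot2::vars(.data$scenario)) +
      ggplot2::labs(x = "harmonic order L",
                    y = "pooled log-evidence difference vs reference")
  }
}

#' Plot the distortion-vs-order curve of a harmonic family
#'
#' @param distortion A tibble with columns `L` and `distortion_mm` (as in
#'   [harmonic_family()] or an experiment's `$distortion`).
#' @return A ggplot.
#' @export
plot_distortion <- function(distortion) {
  ggplot2::ggplot(distortion,
                  ggplot2::aes(x = .data$L, y = .data$distortion_mm)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "harmonic order L",
                  y = "95th-percentile spatial distortion (mm)")
}
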