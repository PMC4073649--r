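#' Real orthonormal spherical-harmonic basis
#'
#' Evaluates the real, fully normalised spherical harmonics
#' \eqn{S_{lm}(\theta, \phi)} up to degree `L` at a set of points on the unit
#' sphere.  The basis is orthonormal under the uniform measure on the sphere
#' (the Gram matrix under dense quadrature is the identity) and uses the
#' Condon--Shortley phase convention; coefficient values produced by
#' [fit_wfs()] depend on this convention.
#'
#' Columns are ordered lexicographically in \eqn{(l, m)} with
#' \eqn{m = -l, \dots, l}, so column 1 is the constant harmonic
#' \eqn{S_{00} = 1/\sqrt{4\pi}} and there are \eqn{(L+1)^2} columns in total.
#' Negative orders carry the \eqn{\sin(|m|\phi)} azimuthal factor, positive
#' orders the \eqn{\cos(m\phi)} factor.
#'
#' @param theta Polar angles in `[0, pi]` (radians).
#' @param phi Azimuthal angles in `[0, 2*pi]` (radians).
#' @param L Maximum harmonic degree (non-negative integer).
#'
#' @return A `length(theta)` by `(L+1)^2` numeric matrix with attributes
#'   `degrees` and `orders` giving the \eqn{(l, m)} index of every column.
#' @export
#' @examples
#' B <- sh_basis(pi / 3, pi / 4, L = 2)
#' dim(B)           # 1 x 9
#' B[1, 1] * sqrt(4 * pi)  # constant harmonic: 1
sh_basis <- function(theta, phi, L) {
  stopifnot(length(theta) == length(phi))
  if (length(L) != 1L || is.na(L) || L < 0 || L != round(L)) {
    stop("`L` must be a single non-negative integer", call. = FALSE)
  }
  eps <- 1e-9
  if (any(theta < -eps | theta > pi + eps, na.rm = FALSE) || anyNA(theta)) {
    stop("`theta` must lie in [0, pi]", call. = FALSE)
  }
  if (any(phi < -eps | phi > 2 * pi + eps) || anyNA(phi)) {
    stop("`phi` must lie in [0, 2*pi]", call. = FALSE)
  }
  n <- length(theta)
  L <- as.integer(L)
  p <- legendre_normalised(cos(theta), L)  # list indexed by [l][m]
  ncol_out <- (L + 1L)^2
  out <- matrix(0, n, ncol_out)
  degrees <- integer(ncol_out)
  orders <- integer(ncol_out)
  sqrt2 <- sqrt(2)
  col <- 0L
  for (l in 0:L) {
    for (m in (-l):l) {
      col <- col + 1L
      degrees[col] <- l
      orders[col] <- m
      am <- abs(m)
      plm <- p[[l + 1L]][, am + 1L]
      out[, col] <- if (m < 0L) {
        sqrt2 * plm * sin(am * phi)
      } else if (m == 0L) {
        plm
      } else {
        sqrt2 * plm * cos(m * phi)
      }
    }
  }
  attr(out, "degrees") <- degrees
  attr(out, "orders") <- orders
  out
}

# Fully normalised associated Legendre functions \bar P_l^m(x), including the
# Condon--Shortley phase, via the standard stable three-term recursion.
# Normalisation is chosen so that \bar P_l^0(cos theta) is the m = 0 real
# spherical harmonic and sqrt(2) * \bar P_l^m(cos theta) * cos/sin(m phi) are
# the m != 0 harmonics.  Returns a list over l of n x (l+1) matrices (m = 0..l).
legendre_normalised <- function(x, L) {
  n <- length(x)
  sx <- sqrt(pmax(0, 1 - x^2))  # sin(theta)
  p <- vector("list", L + 1L)
  for (l in 0:L) p[[l + 1L]] <- matrix(0, n, l + 1L)
  p[[1L]][, 1L] <- 1 / sqrt(4 * pi)
  if (L == 0L) return(p)
  # diagonal terms \bar P_m^m
  for (m in 1:L) {
    p[[m + 1L]][, m + 1L] <- -sqrt((2 * m + 1) / (2 * m)) * sx * p[[m]][, m]
  }
  # first off-diagonal \bar P_{m+1}^m
  for (m in 0:(L - 1L)) {
    p[[m + 2L]][, m + 1L] <- sqrt(2 * m + 3) * x * p[[m + 1L]][, m + 1L]
  }
  # remaining terms
  if (L >= 2L) {
    for (l in 2:L) {
      ms <- 0:(l - 2L)
      for (m in ms) {
        a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
        b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
        p[[l + 1L]][, m + 1L] <-
          a * (x * p[[l]][, m + 1L] - b * p[[l - 1L]][, m + 1L])
      }
    }
  }
  p
}

#' Degree-dependent weighted-Fourier-series smoothing weights
#'
#' The weight applied to every degree-`l` coefficient when a surface is
#' rebuilt from its harmonic decomposition: `exp(-l * (l + 1) * sigma)`.
#' With `sigma = 0` the reconstruction is a pure truncation of the series.
#'
#' @param l Harmonic degrees.
#' @param sigma Smoothing-kernel bandwidth (dimensionless, `>= 0`).
#' @return Numeric weights in `(0, 1]`.
#' @export
wfs_weights <- function(l, sigma) {
  stopifnot(sigma >= 0)
  exp(-l * (l + 1) * sigma)
}
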