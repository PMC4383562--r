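# Shared numerical primitives: the truncated Gaussian window, smoothed
# Heaviside/Dirac pair, and the finite-difference operators used by the
# level set solvers.  All stencils are central differences on a unit grid
# with replicate-edge (Neumann) boundary handling.

#' Build a truncated Gaussian smoothing kernel
#'
#' Constructs the local window used by the clustering energy: a Gaussian
#' profile with standard deviation `sigma`, truncated to a square window of
#' size \eqn{(4k+1)\times(4k+1)} where `k` is the greatest integer strictly
#' smaller than `sigma`, then renormalized to unit sum so that constants
#' pass through the smoothing unchanged.
#'
#' @param sigma Positive standard deviation of the Gaussian, in pixels.
#' @return An object of class `ls_kernel`: a list with elements `sigma`,
#'   `half_width` (the integer `k`), `window_size` (`4k+1`), and `weights`
#'   (the normalized `window_size` x `window_size` weight matrix).
#' @examples
#' k <- build_kernel(3)
#' k$window_size      # 9
#' sum(k$weights)     # 1
#' @export
build_kernel <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("`sigma` must be a single positive finite number", call. = FALSE)
  }
  k <- if (sigma == floor(sigma)) as.integer(sigma) - 1L else
    as.integer(floor(sigma))
  k <- max(k, 1L)
  n <- 4L * k + 1L
  off <- seq.int(-2L * k, 2L * k)
  g1 <- exp(-off^2 / (2 * sigma^2))
  w <- outer(g1, g1)
  w <- w / sum(w)
  structure(
    list(sigma = sigma, half_width = k, window_size = n, weights = w),
    class = "ls_kernel"
  )
}

#' @export
print.ls_kernel <- function(x, ...) {
  cat(sprintf(
    "Truncated Gaussian kernel: sigma = %g, window %d x %d (k = %d)\n",
    x$sigma, x$window_size, x$window_size, x$half_width
  ))
  invisible(x)
}

#' Kernel smoothing of a 2-D field
#'
#' Convolves a field with a kernel from [build_kernel()], treating pixels
#' outside the image as copies of the nearest edge pixel (consistent with
#' the Neumann boundary condition of the level set evolution).  Output has
#' the same dimensions as the input.
#'
#' @param field Numeric matrix with finite entries.
#' @param kernel An `ls_kernel` object.
#' @return Numeric matrix, `field` smoothed by the kernel weights.
#' @export
local_convolve <- function(field, kernel) {
  stopifnot(inherits(kernel, "ls_kernel"), is.matrix(field))
  if (!all(is.finite(field))) {
    stop("`field` contains non-finite values", call. = FALSE)
  }
  # fields smaller than the window are replicate-padded first (the padded
  # convolution restricted to the original pixels equals the edge-clamped
  # window sum)
  pad <- max(0L, kernel$window_size - min(dim(field)))
  if (pad > 0L) {
    ri <- pmin(pmax(seq_len(nrow(field) + 2L * pad) - pad, 1L), nrow(field))
    ci <- pmin(pmax(seq_len(ncol(field) + 2L * pad) - pad, 1L), ncol(field))
    out <- EBImage::filter2(field[ri, ci, drop = FALSE], kernel$weights,
                            boundary = "replicate")
    return(unclass(out[pad + seq_len(nrow(field)),
                       pad + seq_len(ncol(field)), drop = FALSE]))
  }
  unclass(EBImage::filter2(field, kernel$weights, boundary = "replicate"))
}

#' Smoothed Heaviside step
#'
#' The arctangent-regularized step
#' \eqn{H_\varepsilon(s) = \frac12\left(1 + \frac{2}{\pi}\arctan(s/\varepsilon)\right)},
#' used to build soft class memberships from a level set function.
#'
#' @param s Numeric vector, matrix or array.
#' @param epsilon Positive smoothing width (same units as `s`).
#' @return Values in (0, 1), same shape as `s`.
#' @seealso [dirac()] for its derivative.
#' @export
heaviside <- function(s, epsilon = 1) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0)
  0.5 * (1 + (2 / pi) * atan(s / epsilon))
}

#' Smoothed Dirac delta
#'
#' Derivative of [heaviside()]:
#' \eqn{\delta_\varepsilon(s) = \frac{1}{\pi}\,\frac{\varepsilon}{\varepsilon^2 + s^2}}.
#' Non-negative, even, and integrates to 1 over the real line.
#'
#' @inheritParams heaviside
#' @return Non-negative values, same shape as `s`.
#' @export
dirac <- function(s, epsilon = 1) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0)
  (1 / pi) * epsilon / (epsilon^2 + s^2)
}

# Shift a matrix by (dr, dc) with replicate-edge padding; the workhorse of
# every finite-difference stencil below.
shift_mat <- function(m, dr, dc) {
  ri <- pmin(pmax(seq_len(nrow(m)) + dr, 1L), nrow(m))
  ci <- pmin(pmax(seq_len(ncol(m)) + dc, 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

# Central-difference gradient components, replicate edges.
grad_row <- function(m) (shift_mat(m, 1L, 0L) - shift_mat(m, -1L, 0L)) / 2
grad_col <- function(m) (shift_mat(m, 0L, 1L) - shift_mat(m, 0L, -1L)) / 2

#' Curvature of the level lines of a field
#'
#' Computes \eqn{\mathrm{div}(\nabla\phi / |\nabla\phi|)} by central
#' differences.  The gradient magnitude in the denominator is stabilized as
#' \eqn{\sqrt{\phi_x^2 + \phi_y^2 + 10^{-10}}} so flat regions return 0
#' instead of 0/0.
#'
#' @param phi Numeric matrix with finite entries.
#' @return Numeric matrix of the same size.
#' @export
curvature <- function(phi) {
  stopifnot(is.matrix(phi), all(is.finite(phi)))
  fx <- grad_row(phi)
  fy <- grad_col(phi)
  g <- sqrt(fx^2 + fy^2 + 1e-10)
  grad_row(fx / g) + grad_col(fy / g)
}

#' Five-point Laplacian
#'
#' Standard 5-point stencil \eqn{\nabla^2\phi} with replicated edges
#' (homogeneous Neumann boundary).
#'
#' @param phi Numeric matrix with finite entries.
#' @return Numeric matrix of the same size.
#' @export
laplacian <- function(phi) {
  stopifnot(is.matrix(phi), all(is.finite(phi)))
  shift_mat(phi, 1L, 0L) + shift_mat(phi, -1L, 0L) +
    shift_mat(phi, 0L, 1L) + shift_mat(phi, 0L, -1L) - 4 * phi
}

# Central-difference gradient magnitude (no stabilizer; used in the
# regularization energies where it is never divided by).
grad_mag <- function(m) {
  fx <- grad_row(m)
  fy <- grad_col(m)
  sqrt(fx^2 + fy^2)
}
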