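#' Sampled 2-D Gaussian kernel
#'
#' Samples the isotropic 2-D Gaussian
#' \deqn{G(t, \sigma) = \frac{1}{2\pi\sigma^2}
#'       \exp\!\left(-\frac{\|t\|^2}{2\sigma^2}\right)}
#' at integer pixel offsets on a `(2r+1) x (2r+1)` grid and (by default)
#' renormalizes it to unit sum so that convolution preserves the mean of a
#' constant image.
#'
#' @param sigma kernel width in pixels, > 0.
#' @param truncate_radius half-width of the sampling grid in pixels; must be
#'   at least `3 * sigma` so the discarded tail mass is negligible. Defaults
#'   to `ceiling(3 * sigma)`.
#' @param normalize renormalize the discrete kernel to sum to 1 (default).
#'   With `normalize = FALSE` the raw samples of the continuous density are
#'   returned (center value `1 / (2 pi sigma^2)`).
#' @return a square numeric matrix.
#' @examples
#' k <- make_gaussian_kernel(1)
#' sum(k)  # 1
#' @export
make_gaussian_kernel <- function(sigma, truncate_radius = ceiling(3 * sigma),
                                 normalize = TRUE) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("`sigma` must be a positive scalar", call. = FALSE)
  if (truncate_radius < 3 * sigma)
    stop("`truncate_radius` must be >= 3 * sigma", call. = FALSE)
  r <- as.integer(ceiling(truncate_radius))
  x <- seq.int(-r, r)
  g2 <- outer(x, x, function(xx, yy)
    exp(-(xx^2 + yy^2) / (2 * sigma^2)) / (2 * pi * sigma^2))
  if (normalize) g2 <- g2 / sum(g2)
  g2
}

# 1-D Gaussian and its first/second derivative sampled at integer offsets.
# The zeroth-order kernel is renormalized to unit sum; the second-derivative
# kernel is mean-subtracted so it annihilates constants exactly (its sampled
# sum is only approximately zero at small sigma).
gauss_kernels_1d <- function(sigma, truncate = 3) {
  r <- max(as.integer(ceiling(truncate * sigma)), 2L)
  x <- seq.int(-r, r)
  g <- exp(-x^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  g <- g / sum(g)
  gbase <- exp(-x^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  g1 <- (-x / sigma^2) * gbase                 # antisymmetric: sums to 0
  g2 <- ((x^2 - sigma^2) / sigma^4) * gbase
  g2 <- g2 - mean(g2)
  list(g = g, g1 = g1, g2 = g2, radius = r)
}

# Reflect-pad a matrix by (pr, pc) pixels (edge pixel repeated, scipy
# "reflect" style). pr/pc must not exceed the matrix dimensions.
reflect_pad <- function(m, pr, pc) {
  n <- nrow(m); p <- ncol(m)
  ri <- c(rev(seq_len(pr)), seq_len(n),
          seq.int(n, by = -1L, length.out = pr))
  ci <- c(rev(seq_len(pc)), seq_len(p),
          seq.int(p, by = -1L, length.out = pc))
  m[ri, ci, drop = FALSE]
}

# Separable convolution with reflect padding. kx acts along the column
# (x) direction, ky along the row (y) direction. True convolution semantics:
# out = img * (kx ky^T), implemented as correlation with reversed taps via a
# banded matrix product (fast under BLAS for the image sizes used here).
conv_sep <- function(img, kx, ky) {
  rx <- (length(kx) - 1L) %/% 2L
  ry <- (length(ky) - 1L) %/% 2L
  n <- nrow(img); p <- ncol(img)
  if (ry > n || rx > p)
    stop("kernel radius exceeds image size", call. = FALSE)
  pad <- reflect_pad(img, ry, rx)
  # correlation taps = reversed convolution kernel
  tx <- rev(kx); ty <- rev(ky)
  # along x: out[i, j] = sum_l pad[i, j + l - 1] * tx[l]
  Mx <- matrix(0, nrow = p + 2L * rx, ncol = p)
  for (l in seq_along(tx))
    Mx[cbind(seq_len(p) + l - 1L, seq_len(p))] <- tx[l]
  tmp <- pad %*% Mx                      # (n + 2ry) x p
  My <- matrix(0, nrow = n + 2L * ry, ncol = n)
  for (l in seq_along(ty))
    My[cbind(seq_len(n) + l - 1L, seq_len(n))] <- ty[l]
  t(crossprod(tmp, My))                  # n x p
}
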