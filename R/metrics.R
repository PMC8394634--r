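#' Pixelwise absolute difference
#'
#' `D_j = |e_j - z_j|`, the per-pixel absolute deviation used for
#' subtraction images.
#'
#' @param e,z images of identical length (vectors or matrices).
#' @return nonnegative vector (or matrix, if both inputs are matrices).
#' @export
pixel_abs_diff <- function(e, z) {
  if (length(e) != length(z))
    stop("'e' and 'z' must have the same length", call. = FALSE)
  out <- abs(e - z)
  if (is.matrix(e) && is.matrix(z)) out else as.numeric(out)
}

#' L2 evaluation function
#'
#' `E(z) = ||e - z||_2 = sqrt(sum_j D_j(z)^2)`, the Euclidean distance
#' between a reconstruction and the ground truth. Deliberately
#' unnormalized (no `1/J` factor), so its magnitude grows with the pixel
#' count; the packaged 128 x 128 experiments report it on that scale.
#'
#' @inheritParams pixel_abs_diff
#' @return nonnegative scalar.
#' @export
l2_error <- function(e, z) {
  if (length(e) != length(z))
    stop("'e' and 'z' must have the same length", call. = FALSE)
  sqrt(sum((as.numeric(e) - as.numeric(z))^2))
}

# 1-D Gaussian kernel, normalized; truncated to the classical 11-tap window.
gaussian_kernel <- function(size = 11L, sigma = 1.5) {
  r <- (size - 1) / 2
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Valid-mode separable 2-D correlation of an image with kernel k (outer(k,k)).
# Implemented as two banded-matrix products; returns an
# (n - size + 1) square matrix.
conv2_valid <- function(img, k) {
  n <- nrow(img)
  m <- n - length(k) + 1L
  if (m < 1L) stop("image smaller than the SSIM window", call. = FALSE)
  K <- matrix(0, m, n)
  for (i in seq_len(m)) K[i, i:(i + length(k) - 1L)] <- k
  K %*% img %*% t(K)
}

#' Structural similarity index (SSIM)
#'
#' Single-scale SSIM with the reference settings of the original
#' formulation: local statistics from an 11 x 11 Gaussian window with
#' `sigma = 1.5`, stability constants `C1 = (K1 * L)^2`, `C2 = (K2 * L)^2`
#' with `K1 = 0.01`, `K2 = 0.03` and `L = data_range`, population
#' (weighted) variances, and the mean of the local SSIM map over all fully
#' interior windows (valid convolution).
#'
#' @param a,b image matrices of identical dimensions.
#' @param data_range dynamic range `L` of the images (1 for `[0, 1]`
#'   phantoms).
#' @param size,sigma Gaussian window size and width.
#' @param K1,K2 stability constants.
#' @return scalar in `[-1, 1]`; 1 iff the images are identical.
#' @export
ssim <- function(a, b, data_range = 1, size = 11L, sigma = 1.5,
                 K1 = 0.01, K2 = 0.03) {
  if (!is.matrix(a) || !is.matrix(b) || !all(dim(a) == dim(b)))
    stop("'a' and 'b' must be matrices of identical dimensions", call. = FALSE)
  if (data_range <= 0) stop("'data_range' must be positive", call. = FALSE)
  k <- gaussian_kernel(size, sigma)
  mu_a <- conv2_valid(a, k)
  mu_b <- conv2_valid(b, k)
  var_a <- conv2_valid(a * a, k) - mu_a^2
  var_b <- conv2_valid(b * b, k) - mu_b^2
  cov_ab <- conv2_valid(a * b, k) - mu_a * mu_b
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  s <- ((2 * mu_a * mu_b + C1) * (2 * cov_ab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (var_a + var_b + C2))
  mean(s)
}

#' Horizontal line profile of an image
#'
#' Returns the pixel values of one image row in column order (left to
#' right), as used for density-profile plots across reconstructions.
#'
#' @param img image matrix.
#' @param row 1-based row index (row 1 is the top of the image).
#' @return numeric vector of length `ncol(img)`.
#' @export
line_profile <- function(img, row) {
  if (!is.matrix(img)) stop("'img' must be a matrix", call. = FALSE)
  row <- as.integer(row)
  if (is.na(row) || row < 1L || row > nrow(img))
    stop("'row' out of range", call. = FALSE)
  as.numeric(img[row, ])
}
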