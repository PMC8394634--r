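#' Parallel-beam acquisition geometry
#'
#' Describes a 2-D parallel-beam CT acquisition over a square pixel grid:
#' `n_views` equally spaced view angles over `[0, angular_range)` degrees
#' (half-open, so 180-degree sampling never duplicates the 0-degree view) and
#' `n_bins` detector bins per view, one ray through each bin centre. Detector
#' bin centres are placed symmetrically about the isocenter with spacing
#' `detector_spacing`; by default the spacing is chosen so that the detector
#' array spans the diagonal footprint of the image square
#' (`image_size * sqrt(2) / n_bins` pixel units), which is the smallest array
#' that sees the whole image at every angle.
#'
#' The total number of rays is `I = n_views * n_bins` and the number of
#' unknown pixels is `J = image_size^2`. Rays are indexed view-major:
#' ray `i = (view - 1) * n_bins + bin`. Pixels are indexed column-major over
#' the image matrix, whose row 1 is the top of the image.
#'
#' @param n_views number of projection angles (default 180).
#' @param n_bins number of detector bins per view (default 184).
#' @param image_size side length of the square reconstruction grid in pixels
#'   (default 128).
#' @param angular_range angular span in degrees (default 180).
#' @param detector_spacing detector bin width in pixel units; default
#'   `image_size * sqrt(2) / n_bins`.
#' @param pixel_size physical pixel width (dimensionless scale factor applied
#'   to all intersection lengths; default 1).
#' @return an object of class `ct_geometry`.
#' @examples
#' geom <- ct_geometry(n_views = 16, n_bins = 24, image_size = 16)
#' geom$n_rays
#' @export
ct_geometry <- function(n_views = 180L, n_bins = 184L, image_size = 128L,
                        angular_range = 180, detector_spacing = NULL,
                        pixel_size = 1) {
  n_views <- as.integer(n_views)
  n_bins <- as.integer(n_bins)
  image_size <- as.integer(image_size)
  if (is.na(n_views) || n_views < 1L)
    stop("'n_views' must be a positive integer", call. = FALSE)
  if (is.na(n_bins) || n_bins < 1L)
    stop("'n_bins' must be a positive integer", call. = FALSE)
  if (is.na(image_size) || image_size < 1L)
    stop("'image_size' must be a positive integer", call. = FALSE)
  if (!is.numeric(angular_range) || angular_range <= 0)
    stop("'angular_range' must be positive", call. = FALSE)
  if (is.null(detector_spacing))
    detector_spacing <- image_size * sqrt(2) / n_bins
  if (detector_spacing <= 0)
    stop("'detector_spacing' must be positive", call. = FALSE)
  structure(list(
    n_views = n_views,
    n_bins = n_bins,
    image_size = image_size,
    angular_range = angular_range,
    detector_spacing = detector_spacing,
    pixel_size = pixel_size,
    n_rays = n_views * n_bins,
    n_pixels = image_size^2L,
    view_angles = seq(0, angular_range, length.out = n_views + 1L)[seq_len(n_views)],
    det_coords = (seq_len(n_bins) - (n_bins + 1) / 2) * detector_spacing
  ), class = "ct_geometry")
}

#' @exportS3Method base::print
print.ct_geometry <- function(x, ...) {
  cat(sprintf(
    "parallel-beam CT geometry: %d views over [0, %g) deg x %d bins (I = %d rays)\n",
    x$n_views, x$angular_range, x$n_bins, x$n_rays))
  cat(sprintf("image grid: %d x %d px (J = %d), detector spacing %.4f px\n",
              x$image_size, x$image_size, x$n_pixels, x$detector_spacing))
  invisible(x)
}

#' Build the sparse system matrix for a parallel-beam geometry
#'
#' Traces one ray per detector bin (Siddon-style exact ray/pixel intersection
#' lengths) and assembles the sparse nonnegative system matrix `A` of size
#' `I x J`, where entry `A[i, j]` is the length of the intersection of ray `i`
#' with pixel `j` (times `pixel_size`). Forward projection of an image `x` is
#' `A %*% x`; backprojection of a sinogram `s` is `t(A) %*% s`.
#'
#' Rays that miss the image square entirely have all-zero rows. They are kept
#' in the matrix (so sinogram indexing stays view-major and rectangular) but
#' flagged in `valid_rays`; divergence sums and reconstruction updates ignore
#' them, which avoids 0/0 in the multiplicative factor.
#'
#' @param geometry a [ct_geometry()].
#' @return an object of class `ct_system`: a list with elements `A` (a
#'   `dgCMatrix`), `geometry`, `valid_rays` (logical length-I mask) and
#'   `row_sums` (row sums of `A`, i.e. chord lengths through the image).
#' @examples
#' sys <- build_system_matrix(ct_geometry(16, 24, 16))
#' dim(sys$A)
#' @export
build_system_matrix <- function(geometry) {
  if (!inherits(geometry, "ct_geometry"))
    stop("'geometry' must be a ct_geometry object", call. = FALSE)
  tr <- siddon_trace(geometry$image_size, geometry$view_angles,
                     geometry$det_coords, geometry$pixel_size)
  A <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                            dims = c(geometry$n_rays, geometry$n_pixels))
  rs <- Matrix::rowSums(A)
  structure(list(
    A = A,
    geometry = geometry,
    valid_rays = rs > 0,
    row_sums = rs
  ), class = "ct_system")
}

#' @exportS3Method base::print
print.ct_system <- function(x, ...) {
  cat(sprintf("ct_system: %d x %d sparse system matrix, %d nonzeros, %d/%d valid rays\n",
              nrow(x$A), ncol(x$A), Matrix::nnzero(x$A),
              sum(x$valid_rays), length(x$valid_rays)))
  invisible(x)
}

as_image_vector <- function(x, n_pixels) {
  if (is.matrix(x)) x <- as.vector(x)
  if (length(x) != n_pixels)
    stop(sprintf("image has %d elements; geometry expects %d",
                 length(x), n_pixels), call. = FALSE)
  as.numeric(x)
}

#' Forward-project an image
#'
#' Computes the sinogram `A %*% x` (noise-free ray sums of the image).
#'
#' @param system a [build_system_matrix()] result.
#' @param x image as a length-J vector or `image_size x image_size` matrix,
#'   nonnegative.
#' @return numeric length-I sinogram vector (view-major ray order).
#' @export
forward_project <- function(system, x) {
  x <- as_image_vector(x, system$geometry$n_pixels)
  if (any(x < 0)) stop("image values must be nonnegative", call. = FALSE)
  as.numeric(system$A %*% x)
}

#' Backproject a sinogram
#'
#' Computes the adjoint `t(A) %*% s`, the unfiltered backprojection used by
#' the FBP baseline and by the multiplicative-update factor sums.
#'
#' @param system a [build_system_matrix()] result.
#' @param s length-I sinogram vector.
#' @return numeric length-J image-domain vector.
#' @export
back_project <- function(system, s) {
  s <- as.numeric(s)
  if (length(s) != system$geometry$n_rays)
    stop(sprintf("sinogram has %d elements; geometry expects %d",
                 length(s), system$geometry$n_rays), call. = FALSE)
  as.numeric(Matrix::crossprod(system$A, s))
}

#' Reshape a sinogram vector to a bins-by-views matrix
#'
#' @param y length-I sinogram vector in view-major ray order.
#' @param geometry the matching [ct_geometry()].
#' @return `n_bins x n_views` numeric matrix (one column per view).
#' @export
sinogram_matrix <- function(y, geometry) {
  matrix(as.numeric(y), nrow = geometry$n_bins, ncol = geometry$n_views)
}

#' Reshape a length-J pixel vector to an image matrix
#'
#' @param x length-J vector in the package's column-major pixel order.
#' @param image_size side length in pixels.
#' @return `image_size x image_size` matrix, row 1 at the top of the image.
#' @export
image_matrix <- function(x, image_size) {
  matrix(as.numeric(x), nrow = image_size, ncol = image_size)
}
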