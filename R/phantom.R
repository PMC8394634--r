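#' Ellipse parameters of the modified (high-contrast) Shepp-Logan phantom
#'
#' Returns the standard 10-ellipse parameter table of the Shepp-Logan head
#' phantom. The `"modified"` variant (the default) uses the widely adopted
#' high-contrast additive densities, which keep every rasterized pixel value
#' in `[0, 1]` while making the internal features clearly visible; the
#' `"original"` variant uses the low-contrast densities of the historical
#' phantom.
#'
#' Columns: `density` (additive density; negative values carve nested
#' structures out of enclosing ellipses), `a`/`b` (semi-axes, normalized so
#' the image square is `[-1, 1]^2`), `x0`/`y0` (centre), `phi` (rotation in
#' degrees, counter-clockwise).
#'
#' @param variant `"modified"` (high contrast, default) or `"original"`.
#' @return a data.frame with 10 rows.
#' @export
shepp_logan_ellipses <- function(variant = c("modified", "original")) {
  variant <- match.arg(variant)
  dens <- switch(variant,
    modified = c(1, -0.8, -0.2, -0.2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1),
    original = c(2, -0.98, -0.02, -0.02, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01))
  data.frame(
    density = dens,
    a   = c(0.69, 0.6624, 0.11, 0.16, 0.21, 0.046, 0.046, 0.046, 0.023, 0.023),
    b   = c(0.92, 0.874, 0.31, 0.41, 0.25, 0.046, 0.046, 0.023, 0.023, 0.046),
    x0  = c(0, 0, 0.22, -0.22, 0, 0, 0, -0.08, 0, 0.06),
    y0  = c(0, -0.0184, 0, 0, 0.35, 0.1, -0.1, -0.605, -0.606, -0.605),
    phi = c(0, 0, -18, 18, 0, 0, 0, 0, 0, 0)
  )
}

#' Rasterize an ellipse table onto a square pixel grid
#'
#' Each pixel takes the sum of `density` over all ellipses whose interior
#' contains the pixel centre (no anti-aliasing), and negative sums are
#' clipped to 0 so the result is a valid nonnegative density image. Pixel
#' centres are placed symmetrically in the normalized square `[-1, 1]^2`
#' (centre of pixel `(r, c)` at `x = (2c - n - 1)/n`, `y = (n + 1 - 2r)/n`,
#' so row 1 is the top of the image).
#'
#' @param ellipses a data.frame as returned by [shepp_logan_ellipses()].
#' @param image_size side length in pixels.
#' @return `image_size x image_size` numeric matrix.
#' @export
rasterize_ellipses <- function(ellipses, image_size) {
  image_size <- as.integer(image_size)
  if (is.na(image_size) || image_size < 1L)
    stop("'image_size' must be a positive integer", call. = FALSE)
  n <- image_size
  img <- matrix(0, n, n)
  if (nrow(ellipses) == 0L) return(img)
  if (any(ellipses$a <= 0) || any(ellipses$b <= 0))
    stop("ellipse semi-axes must be positive", call. = FALSE)
  xs <- (2 * seq_len(n) - n - 1) / n          # column -> x
  ys <- (n + 1 - 2 * seq_len(n)) / n          # row -> y (row 1 on top)
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(ys, n, n)
  for (k in seq_len(nrow(ellipses))) {
    e <- ellipses[k, ]
    ph <- e$phi * pi / 180
    dx <- X - e$x0
    dy <- Y - e$y0
    xr <- dx * cos(ph) + dy * sin(ph)
    yr <- -dx * sin(ph) + dy * cos(ph)
    inside <- (xr / e$a)^2 + (yr / e$b)^2 <= 1
    img <- img + e$density * inside
  }
  pmax(img, 0)
}

#' The modified Shepp-Logan phantom image
#'
#' Convenience wrapper: rasterizes [shepp_logan_ellipses()] at the requested
#' resolution. All values lie in `[0, 1]`.
#'
#' @param image_size side length in pixels (default 128).
#' @param variant passed to [shepp_logan_ellipses()].
#' @return `image_size x image_size` numeric matrix.
#' @examples
#' e <- shepp_logan_phantom(64)
#' range(e)
#' @export
shepp_logan_phantom <- function(image_size = 128L, variant = "modified") {
  rasterize_ellipses(shepp_logan_ellipses(variant), image_size)
}

#' Add white Gaussian noise to a sinogram at a prescribed SNR
#'
#' Adds i.i.d. zero-mean Gaussian noise with variance
#' `sigma^2 = mean(y^2) / 10^(snr_db / 10)` (SNR taken as the power ratio
#' over all sinogram entries, in dB) and clips negative results to 0 so that
#' the power-divergence terms `y^gamma` remain well defined for fractional
#' `gamma`. The global RNG state is left untouched; the draw is fully
#' determined by `seed`.
#'
#' @param y length-I noise-free sinogram vector.
#' @param snr_db target signal-to-noise ratio in dB.
#' @param seed integer seed controlling the noise realization.
#' @return numeric vector of the same length with attributes `snr_db` and
#'   `seed` recording the noise provenance.
#' @export
add_projection_noise <- function(y, snr_db, seed) {
  y <- as.numeric(y)
  if (any(y < 0)) stop("noise-free sinogram must be nonnegative", call. = FALSE)
  if (!is.finite(snr_db)) stop("'snr_db' must be finite", call. = FALSE)
  sigma <- sqrt(mean(y^2) / 10^(snr_db / 10))
  delta <- local_rng(seed, stats::rnorm(length(y), sd = sigma))
  out <- pmax(y + delta, 0)
  attr(out, "snr_db") <- snr_db
  attr(out, "seed") <- as.integer(seed)
  out
}

# Evaluate `expr` under a temporary RNG stream seeded with `seed`,
# restoring the caller's RNG state afterwards.
local_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate a complete phantom study
#'
#' Generates the ground-truth phantom, builds (or reuses) the system matrix,
#' forward-projects to a consistent noise-free sinogram, and optionally adds
#' Gaussian noise at `snr_db`. This is the fixture generator behind the
#' packaged experiments.
#'
#' @param geometry a [ct_geometry()]; default is the 180-view x 184-bin,
#'   128 px study geometry.
#' @param snr_db noise level in dB, or `NULL` for a noise-free study.
#' @param seed noise seed (required when `snr_db` is given).
#' @param system optional precomputed [build_system_matrix()] result for
#'   `geometry` (reused across noise realizations).
#' @param phantom optional ground-truth image matrix; default the modified
#'   Shepp-Logan phantom at `geometry$image_size`.
#' @return a list with `phantom` (matrix), `system`, `y_clean`, and `y`
#'   (noisy if `snr_db` was given, otherwise identical to `y_clean`).
#' @export
simulate_ct_data <- function(geometry = ct_geometry(), snr_db = NULL,
                             seed = 1L, system = NULL, phantom = NULL) {
  if (is.null(system)) system <- build_system_matrix(geometry)
  if (is.null(phantom)) phantom <- shepp_logan_phantom(geometry$image_size)
  y_clean <- forward_project(system, phantom)
  y <- if (is.null(snr_db)) y_clean else add_projection_noise(y_clean, snr_db, seed)
  list(phantom = phantom, system = system, y_clean = y_clean, y = y)
}
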