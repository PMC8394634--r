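#' Multiplicative-update factors of the PDEM iteration
#'
#' For a current positive image `w`, computes
#' \deqn{\xi_j = \sum_i A_{ij}\, y_i^\gamma (A_i w)^{-\gamma\alpha}, \qquad
#'       \zeta_j = \sum_i A_{ij}\, (A_i w)^{\gamma(1-\alpha)},}
#' and the per-pixel ratio `f_j = xi_j / zeta_j` that multiplies the image in
#' the PDEM step. Rays outside the validity mask contribute 0 to both sums.
#' At `(gamma, alpha) = (1, 1)` the ratio is the classical MLEM factor
#' `[A^T (y / Aw)] / [A^T 1]`.
#'
#' The powers are formed in log space (`exp(gamma * (log y - alpha * log Aw))`)
#' when `gamma * alpha > 3`, avoiding overflow for large exponent products;
#' direct powers are used otherwise.
#'
#' @param system a [build_system_matrix()] result.
#' @param y length-I measured sinogram (nonnegative).
#' @param w nonnegative image with positive total mass (vector or matrix);
#'   a zero projection on a ray with positive measurement raises a
#'   degenerate-support error.
#' @param params an [epdm_params()].
#' @return list with `xi`, `zeta`, `f` (length-J vectors) and `Aw` (the
#'   forward projection, reusable by the caller).
#' @export
pdem_factors <- function(system, y, w, params) {
  params <- as_epdm_params(params)
  w <- as_image_vector(w, system$geometry$n_pixels)
  if (any(w < 0) || all(w == 0))
    stop("'w' must be nonnegative with positive total mass", call. = FALSE)
  y <- as.numeric(y)
  Aw <- as.numeric(system$A %*% w)
  fac <- factors_from_projection(system, y, Aw, params)
  c(fac, list(Aw = Aw))
}

# Floor applied to the forward projection of near-empty rays (valid rays
# whose measurement is exactly 0) before exponentiation; keeps the zeta sum
# finite when such rays' projections underflow as the pixels they see decay
# to zero. Rays with positive measurement are never floored: a vanishing
# projection there is a genuine support contradiction and raises an error.
.ray_floor <- 1e-12

factors_from_projection <- function(system, y, Aw, params) {
  v <- system$valid_rays
  gamma <- params$gamma; alpha <- params$alpha
  ga <- gamma * alpha

  yv <- y[v]; qv <- Aw[v]
  if (any(!is.finite(qv)) || any(qv <= 0 & yv > 0))
    stop("degenerate support: A w vanishes on a valid ray with positive measurement",
         call. = FALSE)
  qv <- pmax(qv, .ray_floor)

  num <- zet <- numeric(length(Aw))  # invalid rays stay 0 in both sums
  pos <- yv > 0
  numv <- numeric(length(yv))        # y_i = 0 contributes exactly 0 to xi
  if (ga > 3) {
    # log-space powers avoid overflow for large exponent products
    numv[pos] <- exp(gamma * (log(yv[pos]) - alpha * log(qv[pos])))
    zet[v] <- exp(gamma * (1 - alpha) * log(qv))
  } else {
    numv[pos] <- yv[pos]^gamma * qv[pos]^(-ga)
    zet[v] <- qv^(gamma * (1 - alpha))
  }
  num[v] <- numv

  xi <- as.numeric(Matrix::crossprod(system$A, num))
  zeta <- as.numeric(Matrix::crossprod(system$A, zet))
  if (any(zeta <= 0)) {
    bad <- which(zeta <= 0)
    stop(sprintf("pixel(s) unseen by any valid ray (first: %d); cannot form update",
                 bad[1]), call. = FALSE)
  }
  list(xi = xi, zeta = zeta, f = xi / zeta)
}

#' One PDEM iteration
#'
#' The multiplicative-Euler step `z_j <- z_j * f_j(z)^h` with `f` from
#' [pdem_factors()]. Strictly positive images map to strictly positive
#' images for every `gamma > 0`, `alpha >= 0`, `h > 0`; at
#' `(gamma, alpha, h) = (1, 1, 1)` the step is exactly one classical MLEM
#' iteration.
#'
#' @inheritParams pdem_factors
#' @param z strictly positive image (vector or matrix).
#' @return length-J positive vector.
#' @export
pdem_update <- function(system, y, z, params) {
  params <- as_epdm_params(params)
  fac <- pdem_factors(system, y, z, params)
  as_image_vector(z, system$geometry$n_pixels) * fac$f^params$h
}

default_z0 <- function(system, y) {
  v <- system$valid_rays
  mean(as.numeric(y)[v]) / mean(system$row_sums[v])
}

#' Iterative PDEM / MLEM reconstruction
#'
#' Runs `n_iter` multiplicative updates from a constant positive initial
#' image and records, for every iterate `z(n)` with `n = 0, ..., n_iter`,
#' the objective `V(z(n))` and — when a ground-truth image is supplied — the
#' L2 evaluation `E(z(n)) = ||e - z(n)||_2` and the SSIM against the truth.
#' The default initial constant is `mean(y) / mean(rowSums(A))` over valid
#' rays, a flat start whose forward projection has the scale of the data.
#'
#' @inheritParams pdem_factors
#' @param n_iter number of iterations (>= 0).
#' @param z0 positive scalar initial value, or a full positive initial
#'   image; `NULL` for the default scaled flat start.
#' @param ground_truth optional true image for E / SSIM logging.
#' @param keep_iterates if `TRUE`, every iterate is stored (memory-heavy);
#'   alternatively an integer vector of iteration numbers to snapshot.
#' @param ssim_data_range data range used for SSIM logging (default 1, the
#'   phantom scale).
#' @return an object of class `pdem_trace`: list with `z` (final image
#'   vector), `metrics` (data.frame `n`, `V`, `E`, `SSIM` with `n_iter + 1`
#'   rows), `params`, `n_iter`, `z0_value`, and `snapshots` (named list of
#'   stored iterates, possibly empty).
#' @examples
#' \donttest{
#' sim <- simulate_ct_data(ct_geometry(30, 24, 16))
#' tr <- pdem_reconstruct(sim$system, sim$y, epdm_params(1, 1), n_iter = 10,
#'                        ground_truth = sim$phantom)
#' tail(tr$metrics, 3)
#' }
#' @export
pdem_reconstruct <- function(system, y, params, n_iter = 200L, z0 = NULL,
                             ground_truth = NULL, keep_iterates = FALSE,
                             ssim_data_range = 1) {
  params <- as_epdm_params(params)
  n_iter <- as.integer(n_iter)
  if (is.na(n_iter) || n_iter < 0L)
    stop("'n_iter' must be a nonnegative integer", call. = FALSE)
  y <- as.numeric(y)
  J <- system$geometry$n_pixels
  n_px <- system$geometry$image_size

  if (is.null(z0)) z0 <- default_z0(system, y)
  if (length(z0) == 1L) {
    if (z0 <= 0) stop("'z0' must be positive", call. = FALSE)
    z <- rep(as.numeric(z0), J)
    z0_value <- as.numeric(z0)
  } else {
    z <- as_image_vector(z0, J)
    if (any(z <= 0)) stop("initial image must be strictly positive", call. = FALSE)
    z0_value <- NA_real_
  }

  e <- if (is.null(ground_truth)) NULL else as_image_vector(ground_truth, J)
  snap_at <- if (isTRUE(keep_iterates)) 0:n_iter
             else if (is.numeric(keep_iterates)) as.integer(keep_iterates)
             else integer(0)

  V <- E <- S <- rep(NA_real_, n_iter + 1L)
  snapshots <- list()
  for (n in 0:n_iter) {
    Az <- as.numeric(system$A %*% z)
    V[n + 1L] <- objective_from_projection(system, y, Az, params)
    if (!is.null(e)) {
      E[n + 1L] <- sqrt(sum((e - z)^2))
      # SSIM needs at least one full 11x11 window
      if (n_px >= 11L)
        S[n + 1L] <- ssim(image_matrix(e, n_px), image_matrix(z, n_px),
                          data_range = ssim_data_range)
    }
    if (n %in% snap_at) snapshots[[as.character(n)]] <- z
    if (n == n_iter) break
    fac <- factors_from_projection(system, y, Az, params)
    z <- z * fac$f^params$h
  }

  structure(list(
    z = z,
    metrics = data.frame(n = 0:n_iter, V = V, E = E, SSIM = S),
    params = params,
    n_iter = n_iter,
    z0_value = z0_value,
    snapshots = snapshots
  ), class = "pdem_trace")
}

#' @exportS3Method base::print
print.pdem_trace <- function(x, ...) {
  cat(sprintf("PDEM trace: gamma = %g, alpha = %g, h = %g, %d iterations\n",
              x$params$gamma, x$params$alpha, x$params$h, x$n_iter))
  last <- x$metrics[nrow(x$metrics), ]
  cat(sprintf("final V = %.6g%s\n", last$V,
              if (is.na(last$E)) "" else sprintf(", E = %.4f, SSIM = %.4f",
                                                 last$E, last$SSIM)))
  invisible(x)
}

#' Classical MLEM reconstruction
#'
#' The `(gamma, alpha) = (1, 1)`, `h = 1` member of the PDEM family — the
#' maximum-likelihood expectation-maximization algorithm.
#'
#' @inheritParams pdem_reconstruct
#' @return a `pdem_trace`.
#' @export
mlem_reconstruct <- function(system, y, n_iter = 200L, z0 = NULL,
                             ground_truth = NULL, keep_iterates = FALSE) {
  pdem_reconstruct(system, y, epdm_params(1, 1, 1), n_iter = n_iter, z0 = z0,
                   ground_truth = ground_truth, keep_iterates = keep_iterates)
}

#' Right-hand side of the continuous-time PDEM system
#'
#' The PDEM iteration is the multiplicative-Euler discretization of
#' `dx_j/dt = x_j * log f_j(x)`; this evaluates that vector field.
#' The consistent solution (`A e = y`) is an equilibrium.
#'
#' @inheritParams pdem_factors
#' @param x strictly positive image (vector or matrix).
#' @return length-J vector `x * (log xi - log zeta)`.
#' @export
pdem_ode_rhs <- function(x, system, y, params) {
  params <- as_epdm_params(params)
  fac <- pdem_factors(system, y, x, params)
  as_image_vector(x, system$geometry$n_pixels) * (log(fac$xi) - log(fac$zeta))
}

#' Lyapunov derivative of V along the continuous-time flow
#'
#' Evaluates `dV/dt = -(xi - zeta)^T diag(x) (log xi - log zeta)`, which is
#' nonpositive for every positive `x` (each term pairs a difference with the
#' same-signed difference of logs), certifying that `V` decreases along
#' trajectories of the continuous system.
#'
#' @inheritParams pdem_ode_rhs
#' @return a nonpositive scalar.
#' @export
pdem_dV_dt <- function(x, system, y, params) {
  params <- as_epdm_params(params)
  x <- as_image_vector(x, system$geometry$n_pixels)
  fac <- pdem_factors(system, y, x, params)
  -sum((fac$xi - fac$zeta) * x * (log(fac$xi) - log(fac$zeta)))
}

#' Integrate the continuous-time PDEM system
#'
#' Solves `dx_j/dt = x_j log f_j(x)` with the adaptive-step variable-order
#' Adams method of [deSolve::ode()]. The state is propagated as `u = log x`,
#' for which the
#' system reads `du_j/dt = log f_j(exp(u))`; this keeps every component of
#' `x = exp(u)` strictly positive at all times without step rejection.
#' The objective `V(x(t))` is reported alongside the trajectory.
#'
#' @inheritParams pdem_factors
#' @param times numeric vector of output times (starting at 0).
#' @param x0 positive scalar or length-J positive initial image; `NULL` for
#'   the same scaled flat start as [pdem_reconstruct()].
#' @param rtol,atol solver tolerances (defaults 1e-6, 1e-9).
#' @return a list with `times`, `x` (matrix, one row per output time) and
#'   `V` (objective at each output time).
#' @export
integrate_pdem_ode <- function(system, y, params, times, x0 = NULL,
                               rtol = 1e-6, atol = 1e-9) {
  params <- as_epdm_params(params)
  y <- as.numeric(y)
  J <- system$geometry$n_pixels
  if (is.null(x0)) x0 <- default_z0(system, y)
  x0 <- if (length(x0) == 1L) rep(as.numeric(x0), J) else as_image_vector(x0, J)
  if (any(x0 <= 0)) stop("'x0' must be strictly positive", call. = FALSE)

  rhs <- function(t, u, parms) {
    fac <- factors_from_projection(system, y,
                                   as.numeric(system$A %*% exp(u)), params)
    list(log(fac$f))
  }
  sol <- deSolve::ode(y = log(x0), times = times, func = rhs, parms = NULL,
                      method = "adams", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf("ODE integration failed; time reached: %g",
                 sol[nrow(sol), 1]), call. = FALSE)
  xs <- exp(sol[, -1, drop = FALSE])
  Vs <- apply(xs, 1L, function(x)
    objective_from_projection(system, y, as.numeric(system$A %*% x), params))
  list(times = sol[, 1], x = unname(xs), V = as.numeric(Vs))
}

#' Filtered backprojection baseline
#'
#' Ramp-filtered backprojection with the Shepp-Logan window: each view is
#' convolved (via FFT, zero-padded) with the discrete Shepp-Logan kernel
#' `h(k) = -2 / (pi^2 tau^2 (4k^2 - 1))` where `tau` is the detector
#' spacing, and the filtered sinogram is backprojected through the system
#' matrix adjoint with quadrature weight `pi / n_views * tau` (the
#' length-weighted rows of `A` spread each filtered sample over the pixels
#' the ray crosses). Output values are not clipped and may be negative.
#'
#' @param y length-I sinogram vector.
#' @param system a [build_system_matrix()] result.
#' @return `image_size x image_size` reconstruction matrix.
#' @export
fbp_reconstruct <- function(y, system) {
  g <- system$geometry
  tau <- g$detector_spacing
  P <- sinogram_matrix(y, g)
  nb <- g$n_bins

  npad <- 2^ceiling(log2(2 * nb))
  k <- c(0:(npad / 2), (-npad / 2 + 1):(-1))
  hk <- -2 / (pi^2 * tau^2 * (4 * k^2 - 1))  # Shepp-Logan kernel
  Hf <- stats::fft(hk)

  Q <- matrix(0, nb, g$n_views)
  for (v in seq_len(g$n_views)) {
    pf <- stats::fft(c(P[, v], rep(0, npad - nb)))
    qf <- Re(stats::fft(pf * Hf, inverse = TRUE)) / npad
    Q[, v] <- qf[seq_len(nb)] * tau   # Riemann weight of the convolution
  }
  b <- back_project(system, as.vector(Q))
  image_matrix(b * pi / g$n_views * tau / g$pixel_size^2, g$image_size)
}
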