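# Shared fixtures and independent oracles used across the test files.

# Dense brute-force projector: clips each ray against every pixel square
# (Liang-Barsky slab test), working in the same grid frame as the package
# (gx rightwards in [0, n], gy downwards in [0, n]; cell (r, c) spans
# [c-1, c) x [r-1, r), half-open like the traversal's floor() rule).
# Independent of the traversal code under test.
brute_force_matrix <- function(geom) {
  n <- geom$image_size
  half <- n / 2
  A <- matrix(0, geom$n_rays, n * n)
  for (v in seq_len(geom$n_views)) {
    th <- geom$view_angles[v] * pi / 180
    u <- c(cos(th), sin(th))
    dw <- c(-sin(th), cos(th))
    d <- c(dw[1], -dw[2])                      # grid-frame direction
    for (b in seq_len(geom$n_bins)) {
      ow <- geom$det_coords[b] * u
      o <- c(ow[1] + half, half - ow[2])       # grid-frame origin
      i <- (v - 1) * geom$n_bins + b
      for (cc in 1:n) for (r in 1:n) {
        lo <- c(cc - 1, r - 1)
        hi <- c(cc, r)
        smin <- -1e9; smax <- 1e9; ok <- TRUE
        for (ax in 1:2) {
          if (abs(d[ax]) < 1e-14) {
            if (o[ax] < lo[ax] || o[ax] >= hi[ax]) { ok <- FALSE; break }
          } else {
            s0 <- (lo[ax] - o[ax]) / d[ax]
            s1 <- (hi[ax] - o[ax]) / d[ax]
            if (s0 > s1) { tmp <- s0; s0 <- s1; s1 <- tmp }
            smin <- max(smin, s0)
            smax <- min(smax, s1)
          }
        }
        if (ok && smax > smin)
          A[i, (cc - 1) * n + r] <- (smax - smin) * geom$pixel_size
      }
    }
  }
  A
}

# Independently coded classical MLEM step: z * A^T(y / Az) / A^T(1),
# written directly from the textbook formula (zero-measurement rays
# contribute nothing to the numerator).
mlem_step_reference <- function(A, valid, y, z) {
  Az <- as.numeric(A %*% z)
  ratio <- numeric(length(y))
  pos <- valid & y > 0
  ratio[pos] <- y[pos] / Az[pos]
  num <- as.numeric(Matrix::crossprod(A, ratio))
  ones <- as.numeric(valid)
  den <- as.numeric(Matrix::crossprod(A, ones))
  z * num / den
}

# Direct special-case divergence formulas (independent of the closed-form
# branch code): generalized KL, half squared-L2, reverse KL.
kl_reference <- function(p, q) {
  sum(ifelse(p > 0, q - p - p * log(q / p), q))
}
half_l2_reference <- function(p, q) sum((q - p)^2) / 2
reverse_kl_reference <- function(p, q) {
  if (any(p == 0)) return(Inf)
  sum(log(q / p) + p / q - 1)
}

# Small consistent test problem with a strictly positive ground truth
# (the asymptotic-stability setting: y = Ae with e > 0).
consistent_problem <- function(image_size = 16, n_views = 24, n_bins = 24,
                               seed = 42) {
  set.seed(seed)
  geom <- ct_geometry(n_views, n_bins, image_size)
  sys <- build_system_matrix(geom)
  e <- matrix(runif(image_size^2, 0.2, 1), image_size, image_size)
  list(sys = sys, e = e, y = forward_project(sys, e))
}
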