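test_that("update factors reproduce hand arithmetic on a 2x2 toy system", {
  # two rays, two pixels, written out by hand
  A <- Matrix::Matrix(c(1, 0.5, 0.25, 1), 2, 2, sparse = TRUE)
  geom <- ct_geometry(2, 1, 1)      # placeholder shape carrier
  sys <- structure(list(A = methods::as(A, "CsparseMatrix"),
                        geometry = list(n_pixels = 2L, n_rays = 2L,
                                        image_size = 2L),
                        valid_rays = c(TRUE, TRUE),
                        row_sums = Matrix::rowSums(A)), class = "ct_system")
  y <- c(2, 3); w <- c(1, 2)
  gamma <- 0.5; alpha <- 1.2
  Aw <- c(1 * 1 + 0.25 * 2, 0.5 * 1 + 1 * 2)   # (1.5, 2.5)
  xi_hand <- c(1 * 2^gamma * 1.5^(-gamma * alpha) + 0.5 * 3^gamma * 2.5^(-gamma * alpha),
               0.25 * 2^gamma * 1.5^(-gamma * alpha) + 1 * 3^gamma * 2.5^(-gamma * alpha))
  zeta_hand <- c(1 * 1.5^(gamma * (1 - alpha)) + 0.5 * 2.5^(gamma * (1 - alpha)),
                 0.25 * 1.5^(gamma * (1 - alpha)) + 1 * 2.5^(gamma * (1 - alpha)))
  fac <- pdem_factors(sys, y, w, epdm_params(gamma, alpha))
  expect_equal(fac$Aw, Aw, tolerance = 1e-15)
  expect_equal(fac$xi, xi_hand, tolerance = 1e-14)
  expect_equal(fac$zeta, zeta_hand, tolerance = 1e-14)
  expect_equal(fac$f, xi_hand / zeta_hand, tolerance = 1e-14)
})

test_that("consistent data make the true image a fixed point", {
  pb <- consistent_problem(12, 20, 18, seed = 8)
  for (pr in list(epdm_params(1, 1), epdm_params(0.5, 1.2),
                  epdm_params(1.3, 1.2))) {
    fac <- pdem_factors(pb$sys, pb$y, pb$e, pr)
    expect_equal(fac$f, rep(1, 144), tolerance = 1e-12)
    z1 <- pdem_update(pb$sys, pb$y, pb$e, pr)
    expect_equal(z1, as.vector(pb$e), tolerance = 1e-12)
  }
})

test_that("the (1,1,1) member reproduces an independent MLEM implementation", {
  pb <- consistent_problem(32, 48, 46, seed = 13)
  yn <- add_projection_noise(pb$y, 25, seed = 2)
  z_pkg <- rep(1, 1024)
  z_ref <- rep(1, 1024)
  pr <- epdm_params(1, 1, 1)
  for (n in 1:10) {
    z_pkg <- pdem_update(pb$sys, yn, z_pkg, pr)
    z_ref <- mlem_step_reference(pb$sys$A, pb$sys$valid_rays, as.numeric(yn), z_ref)
    expect_equal(z_pkg, z_ref, tolerance = 1e-12)
  }
})

test_that("multiplicative updates preserve positivity across the parameter family", {
  pb <- consistent_problem(10, 16, 14, seed = 17)
  yn <- add_projection_noise(pb$y, 20, seed = 4)
  for (pr in list(epdm_params(0.3, 1.2), epdm_params(1, 0),
                  epdm_params(1.5, 1.4, 0.5), epdm_params(0.1, 0.7, 2))) {
    z <- rep(0.5, 100)
    for (n in 1:20) z <- pdem_update(pb$sys, yn, z, pr)
    expect_true(all(z > 0))
    expect_true(all(is.finite(z)))
  }
})

test_that("objective decreases monotonically on consistent data", {
  pb <- consistent_problem(16, 24, 24, seed = 19)
  for (pr in list(epdm_params(0.5, 1.2), epdm_params(1, 1),
                  epdm_params(1.3, 1.2))) {
    tr <- pdem_reconstruct(pb$sys, pb$y, pr, n_iter = 60, ground_truth = pb$e)
    expect_equal(nrow(tr$metrics), 61L)
    expect_true(all(diff(tr$metrics$V) <= 1e-12 * abs(tr$metrics$V[-61]) + 1e-300))
    expect_true(all(diff(tr$metrics$E) < 0))
  }
})

test_that("reconstruction trace bookkeeping is exact", {
  pb <- consistent_problem(8, 12, 12, seed = 23)
  tr0 <- pdem_reconstruct(pb$sys, pb$y, epdm_params(1, 1), n_iter = 0)
  expect_equal(nrow(tr0$metrics), 1L)
  expect_equal(tr0$z, rep(tr0$z0_value, 64))
  tr <- pdem_reconstruct(pb$sys, pb$y, epdm_params(0.8, 1.2), n_iter = 5,
                         keep_iterates = c(0, 3, 5))
  expect_named(tr$snapshots, c("0", "3", "5"))
  expect_identical(tr$snapshots[["5"]], tr$z)
  # deterministic: same inputs, same trace
  tr2 <- pdem_reconstruct(pb$sys, pb$y, epdm_params(0.8, 1.2), n_iter = 5)
  expect_identical(tr$z, tr2$z)
})

test_that("continuous-time system: equilibrium, Lyapunov decrease, discrete agreement", {
  # smooth strictly positive truth: a nested-ellipse object on a 0.2
  # background (high-frequency random images converge much more slowly)
  geom <- ct_geometry(24, 24, 16)
  pb <- list(sys = build_system_matrix(geom))
  pb$e <- rasterize_ellipses(
    data.frame(density = c(0.6, 0.3), a = c(0.8, 0.35), b = c(0.7, 0.3),
               x0 = c(0, 0.15), y0 = c(0, -0.1), phi = c(0, 20)), 16) + 0.2
  pb$y <- forward_project(pb$sys, pb$e)
  pr <- epdm_params(0.5, 1.2)
  # vector field vanishes at the consistent solution
  expect_equal(pdem_ode_rhs(pb$e, pb$sys, pb$y, pr), rep(0, 256),
               tolerance = 1e-10)
  expect_equal(pdem_ode_rhs(pb$e, pb$sys, pb$y, pr),
               as.vector(pb$e) * log(pdem_factors(pb$sys, pb$y, pb$e, pr)$f))
  # trajectory from the equilibrium stays there
  eq <- integrate_pdem_ode(pb$sys, pb$y, pr, times = c(0, 1, 3), x0 = pb$e)
  expect_lt(max(abs(t(eq$x) - as.vector(pb$e))), 1e-6)
  # Lyapunov function is non-increasing along a flat-start trajectory,
  # and the quadratic-form derivative is nonpositive at every sample
  tr <- integrate_pdem_ode(pb$sys, pb$y, pr, times = seq(0, 40, by = 2))
  expect_true(all(diff(tr$V) <= 1e-9 * tr$V[-length(tr$V)] + 1e-12))
  dV <- apply(tr$x, 1, function(x) pdem_dV_dt(x, pb$sys, pb$y, pr))
  expect_true(all(dV <= 1e-12))
  # discrete iteration with h = 1 tracks the flow qualitatively: both
  # reduce E below 10% of the starting error
  ode_end <- integrate_pdem_ode(pb$sys, pb$y, pr, times = c(0, 120))
  disc <- pdem_reconstruct(pb$sys, pb$y, pr, n_iter = 120, ground_truth = pb$e)
  E0 <- disc$metrics$E[1]
  E_ode <- l2_error(as.vector(pb$e), ode_end$x[2, ])
  expect_lt(E_ode / E0, 0.10)
  expect_lt(disc$metrics$E[121] / E0, 0.10)
})

test_that("degenerate support is detected, not floored, when data demand mass", {
  pb <- consistent_problem(6, 8, 10, seed = 31)
  # an image that projects zero onto rays with positive measurement
  w <- matrix(0, 6, 6); w[1, 1] <- 1
  expect_error(pdem_factors(pb$sys, pb$y, w, epdm_params(1, 1)),
               "degenerate support")
  expect_error(pdem_factors(pb$sys, pb$y, rep(0, 36), epdm_params(1, 1)),
               "positive total mass")
})

test_that("filtered backprojection reconstructs the phantom at the study scale", {
  sys <- build_system_matrix(ct_geometry(180, 184, 128))
  e <- shepp_logan_phantom(128)
  y <- forward_project(sys, e)
  r <- fbp_reconstruct(y, sys)
  # correct-FBP sanity bound for a line-integral projector at this sampling
  expect_lt(l2_error(e, r) / sqrt(sum(e^2)), 0.22)
  expect_lt(min(r), 0)   # unclipped output retains filter undershoot
  expect_equal(fbp_reconstruct(rep(0, 33120), sys), matrix(0, 128, 128))
  # rotationally symmetric object gives a symmetric reconstruction
  circ <- rasterize_ellipses(
    data.frame(density = 1, a = 0.5, b = 0.5, x0 = 0, y0 = 0, phi = 0), 128)
  rc <- fbp_reconstruct(forward_project(sys, circ), sys)
  expect_lt(max(abs(rc - t(rc))), 1e-10)
  expect_lt(max(abs(rc - rc[128:1, ])), 1e-10)
})
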