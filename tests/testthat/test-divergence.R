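test_that("divergence vanishes iff the arguments coincide", {
  set.seed(11)
  grid <- expand.grid(gamma = c(0.1, 0.5, 1, 1.3, 1.5),
                      alpha = c(0, 0.5, 1, 1.2, 1.4))
  for (k in seq_len(nrow(grid))) {
    pr <- epdm_params(grid$gamma[k], grid$alpha[k])
    q <- runif(6, 0.1, 3)
    expect_identical(epdm_divergence(q, q, pr), 0)
    p <- q * exp(runif(6, -0.5, 0.5))
    expect_gt(epdm_divergence(p, q, pr), 0)
  }
})

test_that("hand-computed closed forms are reproduced", {
  # half squared-L2 member: (3-1)^2/2 + 0
  expect_equal(epdm_divergence(c(1, 2), c(3, 2), epdm_params(1, 0)), 2.0)
  # KL member on (1, e): e - 1 - log(e) = e - 2
  expect_equal(epdm_divergence(1, exp(1), epdm_params(1, 1)), exp(1) - 2,
               tolerance = 1e-12)
  # Neyman chi-squared member (2, 1): antiderivative of (s^2 - p^2)/s^2 is
  # s + p^2/s, giving (q - p)^2 / q
  p <- 1.5; q <- 2.5
  expect_equal(epdm_divergence(p, q, epdm_params(2, 1)),
               (q - p)^2 / q, tolerance = 1e-12)
})

test_that("closed form agrees with adaptive quadrature across the parameter grid", {
  set.seed(21)
  params <- list(c(1, 1), c(2, 1), c(1, 2), c(0.5, 1.2), c(1.3, 1.2),
                 c(1, 1.5), c(0.1, 0), c(1.5, 1.4))
  for (pr in params) {
    for (k in 1:5) {
      p <- runif(4, 0.05, 4)
      q <- runif(4, 0.05, 4)
      cf <- epdm_divergence(p, q, pr)
      qd <- epdm_divergence_quadrature(p, q, pr)
      expect_lt(abs(cf - qd) / max(qd, 1e-300), 1e-8)
    }
  }
})

test_that("branch boundaries are continuous and cancellation-free in the parameters", {
  set.seed(31)
  p <- runif(5, 0.2, 2); q <- runif(5, 0.2, 2)
  # at and near each logarithmic branch point the closed form must stay on
  # the quadrature oracle (no cancellation blow-up in the 1/(1 - g*a) and
  # 1/(1 + g - g*a) factors) ...
  for (pars in list(c(0.8, 1.25), c(0.8, 1.25 + 1e-4), c(0.8, 1.25 - 1e-4),
                    c(1, 2), c(1, 2 + 1e-4), c(1, 2 - 1e-4))) {
    cf <- epdm_divergence(p, q, pars)
    qd <- epdm_divergence_quadrature(p, q, pars)
    expect_lt(abs(cf - qd) / qd, 1e-8)
  }
  # ... and the general branch converges to the special branch value as the
  # pole is approached
  at1 <- epdm_divergence(p, q, epdm_params(0.8, 1.25))
  at2 <- epdm_divergence(p, q, epdm_params(1, 2))
  for (eps in c(-1e-7, 1e-7)) {
    expect_equal(epdm_divergence(p, q, epdm_params(0.8, 1.25 + eps / 0.8)),
                 at1, tolerance = 1e-6)
    expect_equal(epdm_divergence(p, q, epdm_params(1, 2 + eps)),
                 at2, tolerance = 1e-6)
  }
})

test_that("special members reduce to their classical divergences", {
  set.seed(41)
  for (k in 1:20) {
    p <- runif(8, 0.05, 5)
    q <- runif(8, 0.05, 5)
    kl <- epdm_divergence(p, q, epdm_params(1, 1))
    expect_lt(abs(kl - kl_reference(p, q)) / kl_reference(p, q), 1e-10)
    l2 <- epdm_divergence(p, q, epdm_params(1, 0))
    expect_lt(abs(l2 - half_l2_reference(p, q)) / half_l2_reference(p, q), 1e-10)
    rkl <- epdm_divergence(p, q, epdm_params(1, 2))
    expect_lt(abs(rkl - reverse_kl_reference(p, q)) / reverse_kl_reference(p, q),
              1e-10)
  }
})

test_that("zero measured entries follow the integrability condition", {
  # term for p = 0 is finite iff gamma*(1 - alpha) > -1
  expect_equal(epdm_divergence(0, 2, epdm_params(1, 1)), 2)   # q^1/1
  expect_equal(epdm_divergence(0, 2, epdm_params(1, 0)), 2)   # q^2/2
  expect_identical(epdm_divergence(0, 2, epdm_params(1, 2)), Inf)
  expect_identical(epdm_divergence(0, 2, epdm_params(0.5, 4)), Inf)
  # near the boundary but integrable: gamma (1 - alpha) = -0.9
  expect_true(is.finite(epdm_divergence(0, 2, epdm_params(0.9, 2))))
})

test_that("invalid inputs are rejected", {
  expect_error(epdm_params(0, 1), "gamma")
  expect_error(epdm_params(1, -0.1), "alpha")
  expect_error(epdm_params(1, 1, 0), "h")
  expect_error(epdm_divergence(c(-1, 1), c(1, 1), epdm_params(1, 1)), "nonnegative")
  expect_error(epdm_divergence(c(1, 1), c(0, 1), epdm_params(1, 1)), "positive")
  expect_error(epdm_divergence(1, c(1, 2), epdm_params(1, 1)), "length")
})

test_that("objective equals the divergence of the forward projection", {
  pb <- consistent_problem(8, 10, 12, seed = 5)
  pr <- epdm_params(1.2, 0.7)
  x <- matrix(runif(64, 0.3, 1), 8, 8)
  q <- forward_project(pb$sys, x)
  v <- pb$sys$valid_rays
  expect_equal(epdm_objective(pb$sys, pb$y, x, pr),
               epdm_divergence(pb$y[v], q[v], pr))
  # zero at the consistent solution
  expect_equal(epdm_objective(pb$sys, pb$y, pb$e, pr), 0, tolerance = 1e-20)
  # independent generalized-KL check at (1, 1)
  expect_equal(epdm_objective(pb$sys, pb$y, x, epdm_params(1, 1)),
               kl_reference(pb$y[v], q[v]), tolerance = 1e-10)
})
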