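test_that("zero-frequency q = 2 kernel is the sensitivity outer product", {
  g <- small_alpha_grid()
  kern <- build_depth_kernel(small_alpha_prf(2), g, rho = c(0, 0.05))
  S <- alpha_sensitivity(g$z, alpha_model())
  expect_equal(kern$K[1, , ], outer(S, S), tolerance = 1e-4)
  # single-depth grid: K = sum_b |Phat_b|^2, a nonnegative scalar per
  # frequency; for q = 2 the zero-frequency value is S(z)^2
  g1 <- depth_grid(10, 40, dz = 2)
  prf1 <- alpha_prf_grid(10, 2, small_alpha_bins(), alpha_model())
  k1 <- build_depth_kernel(prf1, g1, rho = c(0, 0.1, 0.2))
  expect_true(all(k1$K >= 0))
  expect_equal(k1$K[1, 1, 1], alpha_sensitivity(10, alpha_model())^2,
               tolerance = 1e-4)
})

test_that("kernels are symmetric positive semidefinite at every frequency", {
  for (q in c(2, 3, 4)) {
    sys <- small_alpha_system(q)
    K <- sys$kernel$K
    for (k in seq_along(sys$kernel$rho)) {
      Kk <- K[k, , ]
      expect_lt(max(abs(Kk - t(Kk))), 1e-10 * max(abs(Kk)))
      ev <- eigen(Kk, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), -1e-10 * max(ev))
    }
    # Hilbert-Schmidt sum is finite on the discrete grid
    expect_true(all(is.finite(K)))
  }
})

test_that("kernel built along (rho, 0) equals kernel built along (0, rho)", {
  g <- small_alpha_grid()
  rho <- c(0.03, 0.11, 0.21)
  kx <- build_depth_kernel(small_alpha_prf(3), g, rho)
  ky <- build_depth_kernel(small_alpha_prf(3), g, rho,
                           rho_vec = cbind(0, rho))
  expect_lt(max(abs(kx$K - ky$K)) / max(abs(kx$K)), 1e-6)
})

test_that("frequencies above the lateral Nyquist are rejected", {
  g <- small_alpha_grid()
  nyq <- 1 / (2 * small_alpha_bins()$lateral_width)
  expect_error(build_depth_kernel(small_alpha_prf(2), g, rho = nyq * 1.01),
               "Nyquist")
  bad_grid <- depth_grid(c(5, 15, 25, 35), 40)
  expect_error(build_depth_kernel(small_alpha_prf(2), bad_grid, 0),
               "do not match")
})

test_that("weighted eigendecomposition solves small closed-form cases", {
  # 1 x 1 kernel [c]: eigenvalue c * dz, eigenvector 1/sqrt(dz)
  g1 <- depth_grid(10, 40, dz = 2)
  k1 <- structure(list(rho = 0, K = array(3, c(1, 1, 1)), depths = 10,
                       dz = 2, attrs = attribute_spec(2),
                       bins = small_alpha_bins(), modality = "alpha",
                       source = NULL, imag_residual = 0),
                  class = "depth_kernel")
  e1 <- eigendecompose_kernel(k1, g1)
  expect_equal(e1$mu[1, 1], 6)
  expect_equal(abs(e1$W[1, 1, 1]), 1 / sqrt(2))
  # symmetric 2 x 2 [[a, b], [b, a]] with dz = 1: eigenvalues a + b, a - b
  a <- 0.7; b <- 0.2
  g2 <- depth_grid(c(10, 20), 40, dz = 1)
  k2 <- structure(list(rho = 0,
                       K = array(matrix(c(a, b, b, a), 2), c(1, 2, 2)),
                       depths = c(10, 20), dz = c(1, 1),
                       attrs = attribute_spec(2), bins = small_alpha_bins(),
                       modality = "alpha", source = NULL, imag_residual = 0),
                  class = "depth_kernel")
  e2 <- eigendecompose_kernel(k2, g2)
  expect_equal(sort(e2$mu[, 1]), sort(c(a + b, a - b)))
})

test_that("spectral reconstruction and orthonormality hold", {
  sys <- small_alpha_system(3)
  g <- small_alpha_grid()
  D <- diag(g$dz)
  for (k in c(1, 8, 16)) {
    K <- sys$kernel$K[k, , ]
    mu <- sys$eigen$mu[, k]
    W <- sys$eigen$W[, , k]
    # sum_n mu_n W_n W_n^T reconstructs K
    expect_equal(W %*% diag(mu) %*% t(W), K, tolerance = 1e-8)
    # dz-weighted orthonormality
    expect_equal(t(W) %*% D %*% W, diag(nrow(K)), tolerance = 1e-8)
    # eigenvalue count equals the number of depth samples
    expect_length(mu, length(g$z))
    # trace identity: sum mu = trace of the weighted kernel
    expect_equal(sum(mu), sum(diag(K) * g$dz), tolerance = 1e-8)
  }
})

test_that("normalized spectra are proper and scale invariant", {
  sys <- small_alpha_system(3)
  tab <- normalized_spectrum(sys$eigen)
  expect_equal(max(tab$lambda), 1)
  expect_equal(sum(tab$lambda == 1), 1)   # exactly one (n, rho) attains 1
  expect_true(all(tab$lambda >= 0 & tab$lambda <= 1))
  # non-increasing in n at fixed rho
  for (r in unique(tab$rho)[c(1, 10)]) {
    lam <- tab$lambda[tab$rho == r]
    expect_true(all(diff(lam) <= 1e-14))
  }
  # scaling all PRF masses leaves lambda unchanged
  prf2 <- small_alpha_prf(3)
  prf2$cells$mass <- 2 * prf2$cells$mass
  sys2 <- cpet_system(prf2, small_alpha_grid(), n_rho = 24)
  expect_equal(sys2$eigen$lambda, sys$eigen$lambda, tolerance = 1e-10)
})

test_that("q = 2 kernel at rho = 0 has numerical rank one", {
  sys <- small_alpha_system(2)
  lam0 <- sys$eigen$lambda[, 1]
  expect_equal(sum(lam0 >= 1e-6), 1)
})

test_that("unsymmetrized Monte Carlo histograms are caught by the realness check", {
  g2 <- depth_grid(c(20, 50), 100, dz = 5)
  bins <- bin_spec(8, 512, energy_max = 640)
  raw <- beta_prf_grid(g2, 4000, bins, attrs = 4, seed = 8,
                       symmetrize = FALSE)
  expect_error(build_depth_kernel(raw, g2, rho = 0.02), "imaginary")
  sym <- beta_prf_grid(g2, 4000, bins, attrs = 4, seed = 8,
                       symmetrize = TRUE)
  expect_s3_class(build_depth_kernel(sym, g2, rho = 0.02), "depth_kernel")
})
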