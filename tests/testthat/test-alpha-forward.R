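test_that("sensitivity matches the closed form and a ray-casting oracle", {
  m <- alpha_model()
  expect_equal(alpha_sensitivity(39.4, m), 0)
  expect_equal(alpha_sensitivity(1e-9, m), 0.5, tolerance = 1e-9)
  expect_equal(alpha_sensitivity(19.7, m), 0.25)
  # Monte Carlo ray casting: isotropic directions, straight tracks
  set.seed(42)
  n <- 1e6
  u <- runif(n, -1, 1)              # cosine w.r.t. +z; detector is below
  z <- 19.7
  frac <- mean(-u > z / m$full_range)
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  expect_error(alpha_sensitivity(0, m), "positive")
})

test_that("PRF mass equals sensitivity at every depth and every q", {
  m <- alpha_model()
  g <- small_alpha_grid()
  for (q in c(2, 3, 4, 5)) {
    prf <- small_alpha_prf(q)
    for (i in seq_along(g$z)) {
      mass <- sum(prf$cells$mass[prf$cells$iz == i])
      expect_lt(abs(mass - alpha_sensitivity(g$z[i], m)) /
                  alpha_sensitivity(g$z[i], m), 1e-4)
    }
  }
})

test_that("depths at or beyond the full range give all-zero grids", {
  m <- alpha_model()
  prf <- alpha_prf_grid(c(39.4, 39.9), 3, small_alpha_bins(), m)
  expect_equal(nrow(prf$cells), 0)
  expect_equal(prf$sensitivity, c(0, 0))
})

test_that("marginalizing the q = 5 grid reproduces the lower-q grids", {
  prf5 <- small_alpha_prf5()
  for (q in c(2, 3, 4)) {
    direct <- alpha_prf_grid(small_alpha_grid(), q, small_alpha_bins(),
                             alpha_model())
    marg <- marginalize_prf(prf5, attribute_spec(q))
    key_cols <- setdiff(names(direct$cells), "mass")
    kd <- interaction_key(direct$cells[key_cols])
    km <- interaction_key(marg$cells[key_cols])
    expect_setequal(kd, km)
    expect_equal(marg$cells$mass[match(kd, km)], direct$cells$mass,
                 tolerance = 1e-10)
  }
})

test_that("PRF support respects the geometric and energy bounds", {
  m <- alpha_model()
  g <- small_alpha_grid()
  prf <- small_alpha_prf5()
  centers <- cpetnull:::lateral_centers(prf$bins)
  for (i in seq_along(g$z)) {
    cells <- prf$cells[prf$cells$iz == i, ]
    r_max <- sqrt(m$full_range^2 - g$z[i]^2)
    r_cell <- sqrt(centers[cells$ix + 1]^2 + centers[cells$iy + 1]^2)
    # cell centers stay within the support radius (up to half a bin diagonal)
    expect_lt(max(r_cell), r_max + prf$bins$lateral_width / sqrt(2))
    E_hi <- (cells$iE + 1) * prf$bins$energy_width
    expect_lte(max(E_hi), 5150 + prf$bins$energy_width)
    expect_gte(min(cells$iE), 0)
  }
})

test_that("central lateral density matches 1/(4 pi z^2)", {
  # q = 2 PRF at z = 10: density at zero offset is cos^3(0)/(4 pi z^2)
  z <- 10
  bins <- small_alpha_bins(width = 2)
  prf <- alpha_prf_grid(z, 2, bins, alpha_model())
  K <- (bins$n_lateral - 1) %/% 2
  central <- prf$cells[prf$cells$ix == K & prf$cells$iy == K, ]
  density <- central$mass / bins$lateral_width^2
  expect_equal(density, 1 / (4 * pi * z^2), tolerance = 0.01)
})

test_that("undersized lateral coverage raises a coverage error", {
  small <- bin_spec(2, 16, energy_max = 5160)   # support radius ~ 38 um
  expect_error(alpha_prf_grid(10, 2, small, alpha_model()),
               "do not cover")
  expect_error(alpha_prf_grid(10, 3, bin_spec(2, 80, energy_max = 4000),
                              alpha_model()),
               "energy axis")
})

test_that("the exact sampler reproduces sensitivity and determinism", {
  m <- alpha_model()
  tab <- sample_alpha_listmode(c(0, 0, 19.7), 1e5, seed = 11, m,
                               slab_geometry(40, 400))
  frac <- nrow(tab) / 1e5
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / 1e5))
  tab2 <- sample_alpha_listmode(c(0, 0, 19.7), 1e5, seed = 11, m,
                                slab_geometry(40, 400))
  expect_identical(as.data.frame(tab), as.data.frame(tab2))
  # beyond the range: empty table
  m2 <- range_energy_model(5.15, 15, 1.8)
  expect_equal(nrow(sample_alpha_listmode(c(0, 0, 20), 100, 1, m2,
                                          slab_geometry(40, 400))), 0)
  expect_error(sample_alpha_listmode(c(0, 0, 50), 10, 1, m,
                                     slab_geometry(40, 400)),
               "inside the slab")
})

test_that("sampled histograms agree with the analytic grid (chi-square)", {
  m <- alpha_model()
  n <- 2e5
  # detector much larger than the support so no event is lost laterally
  geom <- slab_geometry(40, 400)
  bins <- bin_spec(4, 80, energy_max = 5160)
  for (z in c(10, 25)) {
    tab <- sample_alpha_listmode(c(0, 0, z), n, seed = 5 + z, m, geom)
    for (q in c(2, 3)) {
      prf <- alpha_prf_grid(z, q, bins, m)
      p <- prf_sampler_chisq(prf, tab, n)
      expect_gt(p, 0.001)
    }
  }
})
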