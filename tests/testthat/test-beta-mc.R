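test_that("emission-energy sampling matches its stated density", {
  mono <- beta_source("e400", "monoenergetic", energy = 400)
  expect_equal(sample_emission_energy(mono, 5, seed = 1), rep(400, 5))
  src <- beta_source()                      # 18F-like, Q = 633.5 keV
  E <- sample_emission_energy(src, 1e5, seed = 2)
  expect_lte(max(E), src$energy)
  expect_gt(min(E), 0)
  # quadrature oracle for the mean of the allowed-shape spectrum
  Q <- src$energy
  dens <- function(x) cpetnull:::beta_spectrum_density(x, Q)
  norm <- stats::integrate(dens, 0, Q)$value
  mean_th <- stats::integrate(function(x) x * dens(x), 0, Q)$value / norm
  var_th <- stats::integrate(function(x) x^2 * dens(x), 0, Q)$value / norm -
    mean_th^2
  expect_lt(abs(mean(E) - mean_th), 3 * sqrt(var_th / length(E)))
  expect_error(sample_emission_energy(src, 0), "outside|finite")
})

test_that("ballistic transport reduces to straight-line CSDA physics", {
  geom <- beta_geom()
  par0 <- transport_params(scatter = FALSE)
  z <- 40
  st <- electron_state(c(0, 0, z), c(0, 0, -1), 500)
  rec <- transport_electron(st, par0, geom)
  expect_equal(rec$status, "detected")
  expect_equal(rec$path, z, tolerance = 1e-9)
  expect_equal(c(rec$x_d, rec$y_d), c(0, 0), tolerance = 1e-9)
  expect_lt(rec$E, 500)
  # CSDA oracle: integrate dE/ds = -S(E) with tiny Euler steps
  Eo <- 500
  S <- cpetnull:::cpp_scol_water
  h <- 0.001
  for (i in seq_len(z / h)) Eo <- Eo - h * S(Eo)
  expect_lt(abs(rec$E - Eo) / Eo, 1e-3)
})

test_that("transport records respect energy and direction constraints", {
  tab <- simulate_point_source(20, 2e4, seed = 3)
  expect_gt(nrow(tab), 0)
  expect_true(all(tab$E_keV >= 0))
  expect_lte(max(tab$E_keV), beta_source()$energy)
  expect_true(all(tab$s_x^2 + tab$s_y^2 <= 1 + 1e-12))
  # determinism: identical seed gives bit-identical tables
  tab2 <- simulate_point_source(20, 2e4, seed = 3)
  expect_identical(as.data.frame(tab), as.data.frame(tab2))
})

test_that("deeper sources are detected less often", {
  shallow <- simulate_point_source(5, 1e4, seed = 4)
  deep <- simulate_point_source(95, 1e4, seed = 5)
  expect_gt(nrow(shallow), nrow(deep))
})

test_that("sources beyond the electron range give empty tables", {
  # a 50-keV source has sub-50-um CSDA range; 95 um of water absorbs it
  src <- beta_source("e50", "monoenergetic", energy = 50)
  tab <- simulate_point_source(95, 2000, src = src, seed = 6)
  expect_equal(nrow(tab), 0)
  expect_error(simulate_point_source(150, 100, seed = 1), "outside|valid range")
})

test_that("invalid electron states are rejected", {
  expect_error(electron_state(c(0, 0, 10), c(0, 0.5, -0.5), 100), "unit")
  expect_error(electron_state(c(0, NA, 10), c(0, 0, -1), 100), "finite")
  st <- electron_state(c(0, 0, 10), c(0, 0, -1), 100)
  expect_error(transport_electron(st, transport_params(cutoff = 200),
                                  beta_geom()), "cutoff")
})

test_that("ballistic monoenergetic beta matches the alpha lateral density", {
  # same straight-line geometry when the range-energy models coincide
  m <- alpha_model()
  par0 <- transport_params(
    scatter = FALSE, cutoff = 1e-6, step_max = 0.5,
    stopping = "powerlaw",
    powerlaw = list(E0 = 5150, R0 = m$full_range, p = m$exponent))
  src <- beta_source("alpha-like", "monoenergetic", energy = 5150)
  geom <- slab_geometry(40, 400)
  z <- 10
  n <- 5e4
  tab <- simulate_point_source(z, n, src = src, params = par0, geom = geom,
                               seed = 7)
  # detected fraction matches the straight-line sensitivity
  expect_lt(abs(nrow(tab) / n - alpha_sensitivity(z, m)),
            4 * sqrt(0.37 * 0.63 / n))
  prf <- alpha_prf_grid(z, 2, bin_spec(4, 80, energy_max = 5160), m)
  p <- prf_sampler_chisq(prf, tab, n)
  expect_gt(p, 0.001)
})
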