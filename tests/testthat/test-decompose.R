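test_that("cylinder voxelization matches analytic volumes within 2%", {
  geom <- alpha_geom()
  grid <- depth_grid(seq(1, 39, by = 2), 40)
  # heights aligned with slice boundaries so depth discretization is exact
  cyl <- cylinder_spec(c(10, -20), radius = 12, top = 6, height = 20)
  obj <- build_test_object(list(cyl), geom, grid, voxel_size = 1)
  vol_analytic <- pi * 12^2 * 20
  vol_vox <- sum(obj$values > 0) * 1 * 1 * 2
  expect_lt(abs(vol_vox - vol_analytic) / vol_analytic, 0.02)
  # total activity with a second, denser cylinder
  cyl2 <- cylinder_spec(c(-20, 10), radius = 6, top = 12, height = 10,
                        density = 2.5)
  obj2 <- build_test_object(list(cyl, cyl2), geom, grid, 1)
  act_analytic <- vol_analytic + 2.5 * pi * 6^2 * 10
  act_vox <- sum(obj2$values) * 2
  expect_lt(abs(act_vox - act_analytic) / act_analytic, 0.02)
  # empty spec list gives the zero object; out-of-slab cylinders error
  expect_equal(sum(build_test_object(list(), geom, grid, 2)$values), 0)
  expect_error(build_test_object(
    list(cylinder_spec(c(0, 0), 5, top = 30, height = 20)), geom, grid, 2),
    "outside")
})

test_that("the measurement projector fixes, annihilates and is idempotent", {
  # q = 2: each frequency retains a single depth mode, so both retained and
  # discarded eigenprofiles exist
  sys <- small_alpha_system(2)
  g <- small_alpha_grid()
  n <- 40
  vox <- 4
  # choose a lateral Fourier mode on the object grid and fetch the exact
  # eigen-system the decomposition uses at its radius
  fr <- cpetnull:::fft_freq(n, vox)
  kx <- 4L; ky <- 3L
  r <- sqrt(fr[kx + 1]^2 + fr[ky + 1]^2)
  Kr <- cpetnull:::interpolate_kernel(sys$kernel, round(r, 10))
  e <- cpetnull:::eigen_weighted(Kr, g$dz)
  lam <- e$mu / sys$eigen$mu_max
  stopifnot(lam[1] >= 1e-6, lam[length(lam)] < 1e-6)
  xs <- seq_len(n) - 1
  mode2d <- cos(2 * pi * (outer(xs, rep(1, n)) * kx +
                            outer(rep(1, n), xs) * ky) / n)
  make_obj <- function(profile) {
    vals <- array(0, c(n, n, length(g$z)))
    for (iz in seq_along(g$z)) vals[, , iz] <- mode2d * profile[iz]
    cpetnull:::new_voxel_object(vals, vox, g)
  }
  f_keep <- make_obj(e$W[, 1])
  f_kill <- make_obj(e$W[, length(lam)])
  expect_equal(measurement_component(f_keep, sys)$values, f_keep$values,
               tolerance = 1e-8)
  expect_lt(max(abs(measurement_component(f_kill, sys)$values)),
            1e-8 * max(abs(f_kill$values)))
  # idempotence on a generic object
  sys3 <- small_alpha_system(3)
  obj <- small_phantom_object()
  once <- measurement_component(obj, sys3)
  twice <- measurement_component(once, sys3)
  expect_equal(twice$values, once$values, tolerance = 1e-8)
  expect_error(measurement_component(obj, sys, lambda_min = 2), "0, 1")
})

test_that("decomposition is an exact orthogonal split", {
  obj <- small_phantom_object()
  for (q in c(2, 3)) {
    dec <- null_decompose(obj, small_alpha_system(q))
    # f = f_meas + f_null exactly
    expect_identical(dec$f_null$values, obj$values - dec$f_meas$values)
    expect_lt(abs(dec$orthogonality), 1e-6)
    expect_lt(dec$pythagoras, 1e-6)
    # Pythagorean identity for the scaled norm
    expect_equal(dec$scaled_null_norm,
                 sqrt(max(0, 1 - (l2 <- cpetnull:::l2_norm(dec$f_meas))^2 /
                            cpetnull:::l2_norm(obj)^2)),
                 tolerance = 1e-8)
  }
})

test_that("null component and scaled norm handle the trivial cases", {
  obj <- small_phantom_object()
  zero <- cpetnull:::new_voxel_object(array(0, dim(obj$values)),
                                      obj$voxel_size, small_alpha_grid())
  expect_equal(null_component(obj, obj)$values, zero$values)
  expect_equal(null_component(obj, zero)$values, obj$values)
  expect_equal(scaled_null_norm(zero, obj), 0)
  expect_equal(scaled_null_norm(obj, obj), 1)
  expect_error(scaled_null_norm(obj, zero), "zero norm")
  small <- cpetnull:::new_voxel_object(array(1, c(2, 2, 4)), 2,
                                       small_alpha_grid())
  expect_error(null_component(obj, small), "different grids")
})

test_that("forward projection reproduces shifted PRF slices for point sources", {
  g <- small_alpha_grid()
  prf <- small_alpha_prf(3)
  vox <- prf$bins$lateral_width
  n <- prf$bins$n_lateral - 1L   # even-sized object grid, same spacing
  iz0 <- 2L
  vals <- array(0, c(n, n, length(g$z)))
  sx <- 11L; sy <- 26L
  vals[sx, sy, iz0] <- 1
  point <- cpetnull:::new_voxel_object(vals, vox, g)
  u <- forward_project(point, prf)
  # compare a handful of data bins against the PRF mass at the offset
  centers <- (seq_len(n) - 0.5) * vox - n * vox / 2
  dV <- vox^2 * g$dz[iz0]
  cells <- prf$cells[prf$cells$iz == iz0, ]
  lat <- cpetnull:::lateral_centers(prf$bins)
  bt <- u$b_table
  for (row in c(which.max(cells$mass), which(cells$mass > 0)[200])) {
    cr <- cells[row, ]
    bi <- which(bt$iE == cr$iE)
    ix <- ((sx - 1L + round(lat[cr$ix + 1] / vox)) %% n) + 1L
    iy <- ((sy - 1L + round(lat[cr$iy + 1] / vox)) %% n) + 1L
    expect_equal(u$arrays[bi, ix, iy], cr$mass * dV, tolerance = 1e-9)
  }
  # zero object -> zero data
  expect_equal(sum(abs(forward_project(
    cpetnull:::new_voxel_object(array(0, dim(vals)), vox, g), prf)$arrays)), 0)
})

test_that("the adjoint identity <u, Lf> = <adj(u), f> holds on random grids", {
  set.seed(31)
  g <- depth_grid(c(8, 18, 28), 40, dz = 10)
  bins <- bin_spec(8, 40, energy_max = 5160)
  prf <- alpha_prf_grid(g, 3, bins, alpha_model())
  n <- 10
  f <- cpetnull:::new_voxel_object(array(runif(n * n * 3), c(n, n, 3)), 8, g)
  Lf <- forward_project(f, prf)
  u <- Lf
  u$arrays <- array(runif(length(Lf$arrays)), dim(Lf$arrays))
  lhs <- sum(u$arrays * Lf$arrays) * u$lateral_width^2
  bp <- adjoint_backproject(u, prf)
  rhs <- cpetnull:::inner_product(bp, f)
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("backprojecting a single event returns its PRF profile", {
  g <- small_alpha_grid()
  prf <- small_alpha_prf(3)
  cells <- prf$cells[prf$cells$iz == 3, ]
  cr <- cells[which.max(cells$mass), ]
  lat <- cpetnull:::lateral_centers(prf$bins)
  ev <- listmode_table(lat[cr$ix + 1], lat[cr$iy + 1], 0, 0,
                       (cr$iE + 0.5) * prf$bins$energy_width)
  bp <- adjoint_backproject(ev, prf)
  # at the source position (origin), depth 3: value = PRF mass of that bin
  K <- (prf$bins$n_lateral - 1L) %/% 2L
  expect_equal(bp$values[K + 1L, K + 1L, 3], cr$mass, tolerance = 1e-12)
  expect_equal(sum(abs(bp$values)) > 0, TRUE)
})
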