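test_that("list-mode tables validate their schema and physics", {
  t1 <- listmode_table(1, 2, 0.1, 0.2, 500)
  expect_s3_class(t1, "listmode_table")
  expect_error(listmode_table(1, 2, 0.9, 0.9, 500), "unit norm")
  expect_error(listmode_table(1, 2, 0.1, 0.2, -5), "negative")
  expect_error(listmode_table(1:2, 2, 0.1, 0.2, 500), "equal length")
})

test_that("CSV round trip preserves values and metadata", {
  tab <- listmode_table(c(1.25, -3.5, 80.125), c(0, 633.5e-3, -2),
                        c(0.25, -0.5, 0), c(0.1, 0.2, -0.99),
                        c(633.5, 10.2, 0),
                        meta = list(depth = 15, n_emitted = 10, seed = 3))
  f <- tempfile(fileext = ".csv")
  write_listmode(tab, f)
  back <- read_listmode(f)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
  expect_equal(attr(back, "meta")$depth, 15)
  # plain decimal parsing
  expect_equal(back$E_keV[1], 633.5)
  unlink(c(f, paste0(f, ".json")))
})

test_that("malformed CSV input is rejected with a located error", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("x_d_um,y_d_um,s_x,s_y", "1,2,0.1,0.2"), f)
  expect_error(read_listmode(f), "missing column.*E_keV")
  writeLines(c("x_d_um,y_d_um,s_x,s_y,E_keV", "1,2,0.1,oops,500"), f)
  expect_error(read_listmode(f), "non-numeric.*s_y.*row 1")
  unlink(f)
})

test_that("histogramming conserves mass and respects half-open bins", {
  bins <- bin_spec(4, 80, energy_max = 5160)
  # empty table -> empty grid
  empty <- histogram_listmode(listmode_table(), bins, 3, n_emitted = 10)
  expect_equal(nrow(empty$cells), 0)
  expect_equal(empty$sensitivity, 0)
  # one event at a bin center, n_emitted = 1 -> single bin of mass 1
  one <- histogram_listmode(listmode_table(4, -8, 0.3, 0.4, 510), bins, 5,
                            n_emitted = 1)
  expect_equal(nrow(one$cells), 1)
  expect_equal(one$cells$mass, 1)
  # boundary values land in the upper bin: lateral edge at 2 um (bins are
  # centered on multiples of 4) and the 20-keV energy edge are exact
  s <- sin(3 * pi / 180)
  edge <- histogram_listmode(listmode_table(2, 0, s, 0, 20), bins, 5,
                             n_emitted = 1)
  K <- (bins$n_lateral - 1) %/% 2
  expect_equal(edge$cells$ix, K + 1L)   # upper lateral bin
  expect_equal(edge$cells$ith, 1L)      # 3 deg sits in the second theta bin
  expect_equal(edge$cells$iE, 1L)
  # out-of-range rows are counted, in-range mass is exact
  mix <- listmode_table(c(0, 500), c(0, 0), c(0, 0), c(0, 0), c(100, 100))
  h <- histogram_listmode(mix, bins, 3, n_emitted = 8)
  expect_equal(sum(h$cells$mass), 1 / 8)
  expect_equal(h$n_outside, 1)
})

test_that("symmetrized histograms carry the point-reflection symmetry", {
  set.seed(9)
  n <- 500
  s <- runif(n, 0, 0.9)
  ph <- runif(n, 0, 2 * pi)
  tab <- listmode_table(runif(n, -60, 60), runif(n, -60, 60),
                        s * cos(ph), s * sin(ph), runif(n, 0, 600))
  bins <- bin_spec(4, 80, energy_max = 640)
  h <- histogram_listmode(tab, bins, 5, n_emitted = n, symmetrize = TRUE)
  expect_equal(sum(h$cells$mass), 1, tolerance = 1e-12)
  # every cell must have its point-reflected partner with equal mass
  K <- (bins$n_lateral - 1) %/% 2
  cells <- h$cells
  refl_key <- interaction_key(data.frame(
    ix = 2L * K - cells$ix, iy = 2L * K - cells$iy, ith = cells$ith,
    iph = (cells$iph + bins$n_phi %/% 2L) %% bins$n_phi, iE = cells$iE))
  own_key <- interaction_key(cells[c("ix", "iy", "ith", "iph", "iE")])
  j <- match(refl_key, own_key)
  expect_false(anyNA(j))
  expect_equal(cells$mass[j], cells$mass, tolerance = 1e-12)
})
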