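test_that("shift_aperture translates rigidly and preserves area", {
  sq <- aperture_rect(50, 50)
  expect_equal(shift_aperture(sq, c(0, 0)), sq)
  sh <- shift_aperture(sq, c(3, -2))
  expect_setequal(sh$x_mm, c(28, -22))
  expect_setequal(sh$y_mm, c(23, -27))
  for (d in list(c(1.3, -7.2), c(-100, 0.001))) {
    expect_equal(aperture_area(shift_aperture(sq, d)), aperture_area(sq))
  }
  expect_error(shift_aperture(sq, c(NA, 0)), "finite")
  expect_error(shift_aperture(sq, c(Inf, 0)), "finite")
})

test_that("aperture constructor validates and normalizes orientation", {
  cw <- aperture(data.frame(x_mm = c(-1, -1, 1, 1), y_mm = c(-1, 1, 1, -1)))
  expect_gt(trackmargin:::shoelace_area(cw$x_mm, cw$y_mm), 0)
  expect_error(aperture(data.frame(x_mm = c(0, 1), y_mm = c(0, 1))), "3")
  bowtie <- data.frame(x_mm = c(0, 1, 0, 1), y_mm = c(0, 1, 1, 0))
  expect_error(aperture(bowtie), "self-intersect")
})

test_that("dilation kernel extents follow half-up margin quantization", {
  k <- build_dilation_kernel(c(4, 2), 0.25)
  expect_identical(c(k$n_minus, k$n_center, k$n_plus, k$total),
                   c(16L, 1L, 8L, 25L))
  k0 <- build_dilation_kernel(c(0, 0), 0.1)
  expect_identical(c(k0$n_minus, k0$n_center, k0$n_plus, k0$total),
                   c(0L, 1L, 0L, 1L))
  k2 <- build_dilation_kernel(c(1, 1), 0.5)
  expect_identical(c(k2$n_minus, k2$n_plus, k2$total), c(2L, 2L, 5L))
  expect_warning(kc <- build_dilation_kernel(c(30, 0), 0.25, max_margin = 20),
                 "capped")
  expect_identical(kc$n_minus, 80L)
  expect_error(build_dilation_kernel(c(-1, 0), 0.25), ">= 0")
})

test_that("rasterization occupies exactly the cell-center-inside cells", {
  m <- rasterize_aperture(aperture_rect(10, 10), 0.25, pad = 2)
  expect_identical(sum(m$occ), 1600L)
  expect_warning(
    z <- rasterize_aperture(
      aperture(data.frame(x_mm = c(0, 1, 2), y_mm = c(0, 1, 2))), 0.25, pad = 1),
    "zero-area")
  expect_identical(sum(z$occ), 0L)
  mc <- rasterize_aperture(aperture_circle(25, n_vertices = 256), 0.25, pad = 1)
  expect_lt(abs(mask_area(mc) - pi * 625) / (pi * 625), 0.01)
})

test_that("dilation is extensive, monotone, separable and matches counts", {
  # pad generously so the random dilations below never extend the grid
  # (extension would re-origin the matrix and break direct cell indexing)
  m <- rasterize_aperture(aperture_rect(10, 10), 0.25, pad = 8)
  expect_identical(dilate_mask(m, margin_spec())$occ, m$occ)
  d <- dilate_mask(m, margin_spec(x_plus = 2, x_minus = 2))
  expect_identical(sum(apply(d$occ, 1, any)), 56L)  # 14 mm of columns
  expect_identical(sum(apply(d$occ, 2, any)), 40L)  # y untouched
  withr::with_seed(42, {
    for (i in 1:5) {
      ms <- margin_spec(runif(1, 0, 5), runif(1, 0, 5),
                        runif(1, 0, 5), runif(1, 0, 5))
      dd <- dilate_mask(m, ms)
      expect_true(all(dd$occ[m$occ]))  # extensivity
      bigger <- margin_spec(ms[["x_plus"]] + 1, ms[["x_minus"]],
                            ms[["y_plus"]], ms[["y_minus"]] + 0.5)
      db <- dilate_mask(m, bigger)
      expect_true(all(db$occ[dd$occ]))  # monotone in each component
    }
  })
  # axis order does not matter (separable structuring element)
  occ_xy <- trackmargin:::dilate_axis(
    trackmargin:::dilate_axis(m$occ, 3L, 7L, "x"), 2L, 5L, "y")
  occ_yx <- trackmargin:::dilate_axis(
    trackmargin:::dilate_axis(m$occ, 2L, 5L, "y"), 3L, 7L, "x")
  expect_identical(occ_xy, occ_yx)
})

test_that("mask outline extraction inverts rasterization", {
  m <- rasterize_aperture(aperture_rect(12, 8), 0.25, pad = 1)
  p <- mask_to_polygon(m)
  expect_identical(nrow(p), 4L)  # collinear vertices simplified away
  # round trip is exact on the shared grid
  mc <- rasterize_aperture(aperture_circle(10, n_vertices = 128), 0.25, pad = 1)
  p2 <- mask_to_polygon(mc)
  m2 <- rasterize_aperture(p2, 0.25, pad = 1)
  ax1 <- trackmargin:::mask_axes(mc); ax2 <- trackmargin:::mask_axes(m2)
  common_x <- intersect(round(ax1$x, 6), round(ax2$x, 6))
  expect_equal(mask_area(m2), mask_area(mc))
  # area change bounded by one boundary-cell band in any case
  expect_lt(abs(mask_area(m2) - mask_area(mc)),
            (2 * pi * 10) * 0.25 + 1e-9)
  # two disjoint blobs: largest kept, with a warning
  occ <- matrix(FALSE, 40, 40)
  occ[5:20, 5:20] <- TRUE   # 16 x 16
  occ[30:34, 30:34] <- TRUE # 5 x 5
  two <- raster_mask(occ, 0.25, c(0, 0))
  expect_warning(pl <- mask_to_polygon(two), "largest")
  expect_equal(aperture_area(pl), (16 * 0.25)^2)
  empty <- raster_mask(matrix(FALSE, 4, 4), 0.25, c(0, 0))
  expect_error(mask_to_polygon(empty), "vanished")
})

test_that("leaf fitting averages sub-leaf chords and matches brute force", {
  geom <- leaf_bank_geometry(n_pairs = 8, leaf_width = 5)
  rect <- aperture_rect(20, 20)
  bk <- fit_leaves(rect, geom, 10)
  open <- !bk$closed
  expect_equal(bk$left_mm[open], rep(-10, sum(open)))
  expect_equal(bk$right_mm[open], rep(10, sum(open)))
  # n_subleaves = 1 degenerates to the single center-line chord
  circ <- aperture_circle(10, n_vertices = 256)
  b1 <- fit_leaves(circ, geom, 1)
  for (p in which(!b1$closed)) {
    yc <- (b1$y_low_mm[p] + b1$y_high_mm[p]) / 2
    chord <- sqrt(100 - yc^2)
    expect_equal(b1$left_mm[p], -chord, tolerance = 1e-3)
    expect_equal(b1$right_mm[p], chord, tolerance = 1e-3)
  }
  # closed pairs park at the centroid x
  shifted <- shift_aperture(circ, c(4, 0))
  bs <- fit_leaves(shifted, geom, 10)
  expect_true(all(abs(bs$left_mm[bs$closed] - 4) < 1e-6))
  expect_true(all(bs$left_mm[bs$closed] == bs$right_mm[bs$closed]))
  expect_warning(fit_leaves(shift_aperture(circ, c(0, 500)), geom, 10),
                 "outside")
})

test_that("leaf fitting equals a dense brute-force oracle on random shapes", {
  geom <- leaf_bank_geometry(n_pairs = 16, leaf_width = 5)
  withr::with_seed(99, {
    for (i in 1:20) {
      poly <- random_polygon()
      got <- suppressMessages(fit_leaves(poly, geom, 10))
      want <- brute_force_leaves(poly, geom, 10)
      compared <- expect_leaves_match_oracle(got, want)
      expect_gte(compared, 4L)  # most pairs are in generic position
    }
  })
})

test_that("jaws track the polygon extent plus the perpendicular margins", {
  geom <- leaf_bank_geometry(n_pairs = 8, leaf_width = 5)
  rect <- aperture_rect(20, 17)
  bk <- fit_leaves(rect, geom, 10)
  b0 <- set_jaws(bk, margin_spec(), rect)
  expect_equal(attr(b0, "jaw_y_plus"), 8.5)
  expect_equal(attr(b0, "jaw_y_minus"), -8.5)
  b3 <- set_jaws(bk, margin_spec(y_plus = 3), rect)
  expect_equal(attr(b3, "jaw_y_plus"), 11.5)
  expect_equal(attr(b3, "jaw_y_minus"), -8.5)
  sh <- shift_aperture(rect, c(0, 2.5))
  bsh <- set_jaws(fit_leaves(sh, geom, 10), margin_spec(), sh)
  expect_equal(attr(bsh, "jaw_y_plus"), 11)
  expect_equal(attr(bsh, "jaw_y_minus"), -6)
})
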