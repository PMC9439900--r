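test_that("gradients give the closed-form field on constants and ramps, and ignore offsets", {
  g0 <- gradients(matrix(0.3, 6, 6))
  expect_true(all(g0$fx == 0) && all(g0$fy == 0) && all(g0$magnitude == 0))

  # H(x, y) = x: one unit per column -> interior fx = 2, fy = 0, |G| = 2
  ramp <- matrix(rep(1:8, each = 8), 8, 8)
  g <- gradients(ramp)
  interior <- 2:7
  expect_true(all(g$fx[interior, interior] == 2))
  expect_true(all(g$fy[interior, interior] == 0))
  expect_true(all(g$magnitude[interior, interior] == 2))

  m <- random_image(7, 7, seed = 2)
  ga <- gradients(m); gb <- gradients(m + 0.37)
  expect_equal(ga$fx, gb$fx, tolerance = 1e-12)
  expect_equal(ga$fy, gb$fy, tolerance = 1e-12)
})

test_that("the as_printed orientation formula reflects angles about 45 degrees", {
  ramp <- matrix(rep(1:8, each = 8), 8, 8)  # pure horizontal gradient
  conv <- gradients(ramp, hog_config())
  printed <- gradients(ramp, hog_config(orientation_formula = "as_printed"))
  expect_true(all(conv$orientation[2:7, 2:7] == 0))
  expect_true(all(printed$orientation[2:7, 2:7] == 90))
})

test_that("votes exactly at a bin center land entirely in that bin", {
  # column ramp -> angle 0 everywhere, which is the first bin's center;
  # interior pixels have magnitude exactly 2
  ramp <- matrix(rep(1:4, each = 4), 4, 4)
  d <- unclass(cell_histograms(gradients(ramp), hog_config(cell_size = 2L)))
  expect_equal(dim(d), c(2L, 2L, 9L))
  expect_equal(sum(d[, , -1]), 0)        # only bin 1 receives mass
  expect_true(all(d[, , 1] > 0))
  g <- gradients(ramp)
  expect_equal(sum(d[, , 1]), sum(g$magnitude), tolerance = 1e-12)
})

test_that("cell_histograms equals the per-pixel voting oracle on random images", {
  set.seed(14)
  for (cs in c(2L, 4L)) {
    for (rep_ in 1:5) {
      m <- matrix(runif(64), 8, 8)
      got <- unclass(cell_histograms(gradients(m), hog_config(cell_size = cs)))
      want <- oracle_hog_cells(m, cs)
      expect_equal(got, want, tolerance = 1e-9, ignore_attr = TRUE)
    }
  }
})

test_that("votes are conserved and scale with image contrast", {
  m <- random_image(8, 8, seed = 4)
  g <- gradients(m)
  d <- unclass(cell_histograms(g, hog_config(cell_size = 4L)))
  for (iy in 1:2) for (ix in 1:2) {
    cell_mag <- g$magnitude[(iy - 1) * 4 + 1:4, (ix - 1) * 4 + 1:4]
    expect_equal(sum(d[iy, ix, ]), sum(cell_mag), tolerance = 1e-9)
  }
  d2 <- unclass(cell_histograms(gradients(3 * m), hog_config(cell_size = 4L)))
  expect_equal(d2, 3 * d, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("render_hog_image respects locality, extent, range, and zero degenerate", {
  zero <- structure(array(0, c(2, 2, 9)), config = hog_config(),
                    class = c("hog_descriptor", "array"))
  expect_true(all(unclass(render_hog_image(zero, c(8, 8))) == 0))

  one <- structure(array(0, c(2, 2, 9)), config = hog_config(),
                   class = c("hog_descriptor", "array"))
  one[2, 1, 3] <- 5
  img <- unclass(render_hog_image(one, c(8, 8)))
  expect_true(all(img[5:8, 1:4] == 1))
  expect_true(all(img[-(5:8), ] == 0) && all(img[, -(1:4)] == 0))

  m <- random_image(8, 8, seed = 8)
  for (mode in c("dominant", "glyph")) {
    r <- render_hog_image(cell_histograms(gradients(m), hog_config(render_mode = mode)),
                          c(10, 12))
    expect_equal(dim(r), c(10L, 12L))
    expect_true(all(unclass(r) >= 0 & unclass(r) <= 1))
  }
})

test_that("the rendered HOG image is invariant to intensity offsets of the input", {
  m <- random_image(12, 12, seed = 6)
  a <- unclass(hog_image(m))
  b <- unclass(hog_image(m + 0.21))
  expect_equal(a, b, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("gradient and cell operations validate their input sizes", {
  expect_error(gradients(matrix(1, 2, 2)), "at least 3x3")
  expect_error(cell_histograms(gradients(matrix(runif(9), 3, 3)),
                               hog_config(cell_size = 4L)), "exceeds")
})
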