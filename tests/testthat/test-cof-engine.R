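three_annulus_kernel <- function() {
  crv <- of_curve(tibble::tibble(radius_cm = c(0.1, 0.2),
                                 output_factor = c(0.10, 0.15)))
  build_kernel(crv, resolution_mm = 1, max_radius_cm = 0.3)
}

test_that("COF is the double sum of the kernel over the open aperture", {
  k <- three_annulus_kernel()
  v <- matrix(0L, 9, 9); v[4:6, 4:6] <- 1L
  mask <- make_mask(v)
  for (method in c("fft", "direct")) {
    cm <- compute_cof_map(k, mask, method = method)
    expect_equal(cm$values[5, 5], 0.10 + 8 * 0.00625, tolerance = 1e-12)
    expect_equal(cm$values, naive_conv_same(v, k$values), tolerance = 1e-12)
  }
  # empty aperture: a zero map, and no maximum to report
  zero <- compute_cof_map(k, make_mask(matrix(0L, 9, 9)))
  expect_true(all(zero$values == 0))
  expect_error(find_max_point(zero), "empty aperture")
})

test_that("fast convolution routes agree with the naive double sum on random cases", {
  crv <- random_monotone_curve(21)
  k <- build_kernel(crv, max_radius_cm = 0.5) # 11x11
  for (seed in 1:5) {
    mask <- random_padded_mask(25, margin = 5, seed = seed)
    direct <- compute_cof_map(k, mask, method = "direct")
    fftv <- compute_cof_map(k, mask, method = "fft")
    oracle <- naive_conv_same(mask$values, k$values)
    expect_equal(direct$values, oracle, tolerance = 1e-12)
    expect_lt(max(abs(fftv$values - oracle)), 1e-9)
  }
})

test_that("COF at the center of a circular aperture recovers the curve value", {
  crv <- preset_curve("9E")
  k <- build_kernel(crv)
  msk <- rasterize(synth_cutout("circle", radius_cm = 3, n = 512),
                   resolution_mm = 1, padding_cm = 6.2)
  cm <- compute_cof_map(k, msk)
  expect_equal(cof_at_point(cm, 0, 0), of_evaluate(crv, 3), tolerance = 5e-4)
  # map values never exceed the maximal disk sum
  expect_true(all(cm$values <= of_evaluate(crv, crv$r_max) + 1e-12))
  expect_true(all(cm$values >= -1e-15))
})

test_that("whole-pixel mask translation translates the COF map exactly", {
  k <- build_kernel(random_monotone_curve(13), max_radius_cm = 1)
  base <- synth_cutout("irregular", radius_cm = 1.5, amplitude = 0.3, seed = 6)
  m0 <- rasterize(base, 1, 1.1)
  shifted <- cutout_shape(tibble::tibble(x_cm = base$vertices$x_cm + 0.4,
                                         y_cm = base$vertices$y_cm + 0.9))
  m1 <- rasterize(shifted, 1, 1.1)
  c0 <- compute_cof_map(k, m0)
  c1 <- compute_cof_map(k, m1)
  expect_identical(m0$values, m1$values)
  expect_equal(c0$values, c1$values, tolerance = 1e-15)
  expect_equal(c1$origin - c0$origin, c(x_cm = 0.4, y_cm = 0.9))
})

test_that("enlarging the aperture never lowers the COF anywhere", {
  k <- build_kernel(random_monotone_curve(17), max_radius_cm = 0.8)
  for (seed in 1:5) {
    small <- random_padded_mask(30, margin = 8, p_open = 0.3, seed = seed)
    extra <- random_padded_mask(30, margin = 8, p_open = 0.2, seed = seed + 100)
    big <- make_mask(pmax(small$values, extra$values))
    c_small <- compute_cof_map(k, small, method = "direct")
    c_big <- compute_cof_map(k, big, method = "direct")
    expect_true(all(c_big$values - c_small$values >= -1e-15))
  }
})

test_that("geometry contract violations are reported", {
  k <- build_kernel(random_monotone_curve(1), max_radius_cm = 1)
  shp <- synth_cutout("circle", radius_cm = 1, n = 64)
  expect_error(compute_cof_map(k, rasterize(shp, 2, 2)), "resolution mismatch")
  expect_error(compute_cof_map(k, rasterize(shp, 1, 0.2)),
               "insufficient mask padding")
})

test_that("point queries honor the nearest/bilinear modes and the map extent", {
  cm <- structure(
    list(values = matrix(c(1, 2, 3, 4, 5, 6), 2, 3, byrow = TRUE),
         resolution_mm = 10, origin = c(x_cm = 0, y_cm = 0),
         energy = "6E", ssd_cm = 100, label = "toy"),
    class = "cof_map"
  )
  expect_identical(cof_at_point(cm, 1, 1), 5)          # exact pixel center
  expect_identical(cof_at_point(cm, 0.2, 0.1), 1)      # nearest
  expect_equal(cof_at_point(cm, 0.5, 0, method = "bilinear"), 1.5)
  expect_equal(cof_at_point(cm, 1, 0.5, method = "bilinear"), 3.5)
  expect_error(cof_at_point(cm, 5, 0), "outside")
})

test_that("the convolution maximum sits in the largest opening with a plateau set", {
  crv <- preset_curve("6E")
  k <- build_kernel(crv, max_radius_cm = 2)
  n <- 121
  v <- matrix(0L, n, n)
  g <- expand.grid(i = 1:n, j = 1:n)
  # two disjoint disks: radius 10 px at (31, 31), radius 20 px at (81, 81)
  v[(g$i - 31)^2 + (g$j - 31)^2 < 10^2] <- 1L
  v[(g$i - 81)^2 + (g$j - 81)^2 < 20^2] <- 1L
  cm <- compute_cof_map(k, make_mask(v))
  mx <- find_max_point(cm)
  expect_equal(c(mx$x_cm, mx$y_cm), c(8, 8), tolerance = 0.15)
  expect_gt(mx$cof, of_evaluate(crv, 1.9))

  # uniform plateau: row-major tie-break, every pixel in the plateau set
  flat <- structure(
    list(values = matrix(1, 3, 3), resolution_mm = 1,
         origin = c(x_cm = 0, y_cm = 0), energy = "6E", ssd_cm = 100,
         label = "flat"),
    class = "cof_map"
  )
  fm <- find_max_point(flat)
  expect_identical(c(fm$x_cm, fm$y_cm), c(0, 0))
  expect_identical(nrow(fm$plateau), 9L)
})
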