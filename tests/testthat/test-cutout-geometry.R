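test_that("axis-aligned square rasterizes to exactly its pixel count", {
  sq <- cutout_shape(tibble::tibble(x_cm = c(0, 2, 2, 0),
                                    y_cm = c(0, 0, 2, 2)))
  m <- rasterize(sq, resolution_mm = 1, padding_cm = 0)
  expect_identical(sum(m$values), 400L)
  # padding adds blocked pixels only
  mp <- rasterize(sq, resolution_mm = 1, padding_cm = 1)
  expect_identical(sum(mp$values), 400L)
  expect_gt(length(mp$values), length(m$values))
})

test_that("rasterized circle counts the lattice points inside its radius", {
  # 3.03 cm radius: no lattice point within the polygon sagitta of the rim,
  # so the inscribed 512-gon and the true circle enclose the same centers
  r_cm <- 3.03
  circ <- synth_cutout("circle", radius_cm = r_cm, n = 512)
  m <- rasterize(circ, resolution_mm = 1, padding_cm = 0.5)
  expect_identical(sum(m$values), lattice_count_in_circle(r_cm * 10))
})

test_that("whole-pixel translation of the polygon translates the mask identically", {
  base <- synth_cutout("irregular", radius_cm = 2.5, amplitude = 0.25, seed = 8)
  m0 <- rasterize(base, 1, 0.4)
  shifted <- cutout_shape(
    tibble::tibble(x_cm = base$vertices$x_cm + 0.7,   # 7 px
                   y_cm = base$vertices$y_cm - 1.3),  # -13 px
    label = base$label
  )
  m1 <- rasterize(shifted, 1, 0.4)
  expect_identical(m0$values, m1$values)
  expect_equal(m1$origin - m0$origin, c(x_cm = 0.7, y_cm = -1.3))
})

test_that("pixel-center inclusion agrees with an independent point-in-polygon", {
  for (seed in c(1, 5, 9)) {
    shp <- synth_cutout("irregular", radius_cm = 3, amplitude = 0.35,
                        seed = seed)
    m <- rasterize(shp, resolution_mm = 2, padding_cm = 0.3)
    pts <- tidy(m)
    bnd <- as.matrix(rbind(shp$vertices, shp$vertices[1, ]))
    ref <- mgcv::in.out(bnd, cbind(pts$x_cm, pts$y_cm))
    # boundary-grazing centers may legitimately differ; none expected here
    expect_identical(ref, pts$open == 1L)
  }
})

test_that("P2A matches closed forms and the isoperimetric bound", {
  sq <- cutout_shape(tibble::tibble(x_cm = c(0, 1, 1, 0),
                                    y_cm = c(0, 0, 1, 1)))
  expect_identical(p2a(sq), 16)
  expect_equal(p2a(synth_cutout("rectangle", width_cm = 1, height_cm = 9)),
               400 / 9, tolerance = 1e-12)
  expect_equal(p2a(synth_cutout("circle", radius_cm = 3, n = 200)), 4 * pi,
               tolerance = 1e-3)
  for (seed in 1:50) {
    shp <- synth_cutout("irregular", radius_cm = 2,
                        amplitude = 0.05 + 0.4 * ((seed * 37) %% 100) / 100,
                        seed = seed)
    expect_gte(p2a(shp), 4 * pi)
  }
})

test_that("P2A is invariant under rigid motion and uniform scaling", {
  shp <- synth_cutout("irregular", radius_cm = 2.5, amplitude = 0.3, seed = 4)
  base <- p2a(shp)
  th <- 0.7; s <- 3.2
  v <- shp$vertices
  moved <- tibble::tibble(
    x_cm = s * (cos(th) * v$x_cm - sin(th) * v$y_cm) + 5,
    y_cm = s * (sin(th) * v$x_cm + cos(th) * v$y_cm) - 2
  )
  expect_equal(p2a(cutout_shape(moved)), base, tolerance = 1e-12)
})

test_that("complexity classification uses an inclusive cutoff of 30", {
  expect_identical(classify_complexity(16), "reliable")
  expect_identical(classify_complexity(44.4), "caution")
  expect_identical(classify_complexity(30), "reliable")
  expect_identical(classify_complexity(c(13, 31)), c("reliable", "caution"))
  expect_error(classify_complexity(10), "4\\*pi")
})

test_that("degenerate polygons are rejected", {
  expect_error(cutout_shape(tibble::tibble(x_cm = c(0, 1), y_cm = c(0, 1))),
               "3 vertices")
  expect_error(cutout_shape(tibble::tibble(x_cm = c(0, 1, 2),
                                           y_cm = c(0, 0, 0))),
               "zero area")
  bowtie <- tibble::tibble(x_cm = c(0, 3, 3, 0), y_cm = c(0, 2, 0, 1))
  expect_error(cutout_shape(bowtie), "self-intersecting")
  # perfectly symmetric bowtie has zero net area and is caught earlier
  expect_error(cutout_shape(tibble::tibble(x_cm = c(0, 1, 1, 0),
                                           y_cm = c(0, 1, 0, 1))),
               "zero area")
  expect_error(rasterize(cutout_shape(
    tibble::tibble(x_cm = c(0, 1, 1, 0), y_cm = c(0, 0, 1, 1))), 0), "> 0")
})

test_that("rasterized area converges to the shoelace area", {
  shapes <- list(
    synth_cutout("circle", radius_cm = 2, n = 256),
    synth_cutout("rectangle", width_cm = 3, height_cm = 2),
    synth_cutout("irregular", radius_cm = 2.2, amplitude = 0.3, seed = 2)
  )
  for (shp in shapes) {
    true_area <- glance(shp)$area_cm2
    at <- function(res) sum(rasterize(shp, res, 0.2)$values) * (res / 10)^2
    expect_lt(abs(at(1) - true_area) / true_area, 0.01)
    expect_lt(abs(at(0.5) - true_area), abs(at(2) - true_area) + 1e-9)
  }
})
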