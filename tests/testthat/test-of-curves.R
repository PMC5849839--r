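test_that("fitted curve reproduces every sample and honors the origin/plateau conventions", {
  samples <- tibble::tibble(radius_cm = 1:6,
                            output_factor = c(0.5, 0.8, 0.95, 1, 1, 1))
  for (interp in c("monotone_cubic", "linear")) {
    crv <- of_curve(samples, energy = "6E", ssd_cm = 100,
                    interpolation = interp)
    expect_equal(of_evaluate(crv, samples$radius_cm), samples$output_factor,
                 tolerance = 0)
    expect_identical(of_evaluate(crv, 0), 0)
    expect_identical(of_evaluate(crv, 8), 1)   # constant plateau beyond r_max
    expect_identical(of_evaluate(crv, 4), 1)
  }
})

test_that("linear interpolation gives the hand-computable segment values", {
  crv <- of_curve(tibble::tibble(radius_cm = c(1, 2),
                                 output_factor = c(0.5, 0.7)),
                  interpolation = "linear")
  expect_equal(of_evaluate(crv, 1.5), 0.6)
  # below the smallest sample the segment runs from the (0, 0) anchor
  expect_equal(of_evaluate(crv, 0.5), 0.25)
})

test_that("monotone interpolant descends to zero below the first sample without overshoot", {
  crv <- of_curve(tibble::tibble(radius_cm = c(1, 2),
                                 output_factor = c(0.5, 0.7)))
  v <- of_evaluate(crv, 0.5)
  expect_gt(v, 0)
  expect_lt(v, 0.5)
  # monotone samples => monotone curve on [0, r_max], several random curves
  for (seed in 1:5) {
    crv <- random_monotone_curve(seed)
    fine <- of_evaluate(crv, seq(0, 6, by = 0.01))
    expect_true(all(diff(fine) >= -1e-12))
    expect_true(all(fine >= 0 & fine <= crv$plateau + 1e-12))
  }
})

test_that("curve construction rejects bad input", {
  expect_error(of_curve(tibble::tibble(radius_cm = 1, output_factor = 0.5)),
               "insufficient samples")
  expect_error(of_curve(tibble::tibble(radius_cm = c(2, 1),
                                       output_factor = c(0.5, 0.6))),
               "increasing")
  expect_error(of_curve(tibble::tibble(radius_cm = c(1, 2),
                                       output_factor = c(0.5, NA))),
               "finite")
  expect_error(of_curve(tibble::tibble(radius_cm = c(-1, 2),
                                       output_factor = c(0.5, 0.6))),
               "positive")
  crv <- random_monotone_curve(1)
  expect_error(of_evaluate(crv, -0.5), "non-negative")
  expect_error(of_evaluate(crv, Inf), "finite")
})

test_that("inverse-square extension matches the closed form and is identity at the nominal SSD", {
  crv <- of_curve(tibble::tibble(radius_cm = 3:6,
                                 output_factor = c(0.78, 0.8, 0.8, 0.8)))
  id <- of_extend_inverse_square(
    crv, beam_geometry(100, 100, 95, 1.5), min_radius_cm = 4)
  expect_equal(id$samples$output_factor,
               crv$samples$output_factor[crv$samples$radius_cm >= 4],
               tolerance = 1e-15)

  ext <- of_extend_inverse_square(crv, beam_geometry(100, 110, 95, 1.5))
  expect_equal(ext$samples$output_factor[1],
               0.8 / ((106.5 / 96.5)^2), tolerance = 1e-12)
  expect_equal(ext$samples$output_factor[1], 0.6568, tolerance = 1e-4)
  expect_true(ext$partial)
  expect_identical(ext$ssd_cm, 110)

  # strictly decreasing in the SSD extension
  ofs <- vapply(c(100, 105, 110, 120), function(s) {
    of_extend_inverse_square(crv, beam_geometry(100, s, 95, 1.5))$
      samples$output_factor[1]
  }, numeric(1))
  expect_true(all(diff(ofs) < 0))

  expect_error(beam_geometry(100, 95, 95, 1.5), "ssd_ext")
  expect_error(
    of_extend_inverse_square(crv, beam_geometry(100, 110, 95, 1.5),
                             min_radius_cm = 6.5),
    "too few"
  )
})

test_that("merging measured small-radius samples restores a full extended-SSD curve", {
  crv <- of_curve(tibble::tibble(radius_cm = 1:6,
                                 output_factor = c(0.5, 0.7, 0.78, 0.8, 0.8, 0.8)))
  ext <- of_extend_inverse_square(crv, beam_geometry(100, 110, 95, 1.5))
  measured <- tibble::tibble(radius_cm = 1:3, output_factor = c(0.38, 0.55, 0.63))
  full <- of_merge_samples(ext, measured)
  expect_false(full$partial)
  expect_identical(full$samples$radius_cm, as.numeric(1:6))
  expect_equal(full$samples$output_factor[1:3], measured$output_factor)
  expect_equal(full$samples$output_factor[4:6], ext$samples$output_factor)
  # direct measurements win on overlapping radii
  overlap <- of_merge_samples(
    ext, tibble::tibble(radius_cm = c(1, 4), output_factor = c(0.38, 0.99)))
  expect_equal(
    overlap$samples$output_factor[overlap$samples$radius_cm == 4], 0.99)
})

test_that("percentage difference is the mean-normalized symmetric difference", {
  expect_identical(pct_difference(0.8, 0.8), 0)
  expect_equal(pct_difference(1.0, 0.9), 0.1 / 0.95 * 100, tolerance = 1e-12)
  withr::with_seed(42, {
    a <- runif(50, 0.1, 2); b <- runif(50, 0.1, 2)
    expect_equal(pct_difference(a, b), pct_difference(b, a))
    expect_true(all(pct_difference(a, b) >= 0))
    expect_identical(pct_difference(a, b) == 0, a == b)
  })
  expect_error(pct_difference(0, 1), "positive")
  expect_error(pct_difference(1, -0.2), "positive")
})

test_that("curve accessors expose tidy samples and summary rows", {
  crv <- random_monotone_curve(3)
  td <- tidy(crv)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("radius_cm", "output_factor", "energy", "ssd_cm"))
  gl <- glance(crv)
  expect_identical(gl$n_samples, 6L)
  expect_identical(gl$plateau, crv$plateau)
  expect_s3_class(autoplot(crv), "ggplot")
})
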