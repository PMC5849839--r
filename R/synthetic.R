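#' Synthetic circular-field output-factor curve
#'
#' Generates a measured-looking OF(r) table from a saturating-exponential
#' model, `OF(r) = plateau * (1 - exp(-(r / rise_scale)^shape_exponent))`,
#' optionally with seeded zero-mean Gaussian noise (truncated to keep values
#' positive). The noiseless curve rises strictly monotonically to an
#' energy-dependent plateau, flattening by roughly 4 cm radius like measured
#' electron cutout curves.
#'
#' @param radii_cm Sample radii in cm (default 1--6 cm in 1 cm steps, the
#'   usual commissioning protocol).
#' @param plateau Asymptotic output factor (> 0).
#' @param rise_scale_cm Radius scale of the rise, cm (> 0).
#' @param shape_exponent Steepness exponent (>= 1).
#' @param noise_sd Standard deviation of additive noise (default 0).
#' @param seed Integer seed; the same seed reproduces the same curve.
#' @param energy,ssd_cm Labels stored on the curve.
#' @param interpolation Passed to [of_curve()].
#' @return An [of_curve()].
#' @export
synth_of_curve <- function(radii_cm = 1:6, plateau = 1, rise_scale_cm = 1.5,
                           shape_exponent = 2, noise_sd = 0, seed = 1,
                           energy = "synthetic", ssd_cm = 100,
                           interpolation = c("monotone_cubic", "linear")) {
  stop_if_not_number(plateau, "plateau", positive = TRUE)
  stop_if_not_number(rise_scale_cm, "rise_scale_cm", positive = TRUE)
  stop_if_not_number(shape_exponent, "shape_exponent", positive = TRUE)
  if (shape_exponent < 1) abort("`shape_exponent` must be >= 1.")
  stop_if_not_number(noise_sd, "noise_sd", nonneg = TRUE)
  of <- plateau * (1 - exp(-(radii_cm / rise_scale_cm)^shape_exponent))
  if (noise_sd > 0) {
    noise <- withr::with_seed(seed, rnorm(length(of), 0, noise_sd))
    of <- pmax(of + noise, 1e-6) # truncate to keep positivity
  }
  of_curve(tibble::tibble(radius_cm = radii_cm, output_factor = of),
           energy = energy, ssd_cm = ssd_cm,
           interpolation = match.arg(interpolation))
}

#' Preset synthetic curves emulating 6E / 9E / 15E beams
#'
#' Three parameter sets whose noiseless curves converge to plateaus of 1.0,
#' 0.9, and 0.8 and flatten by about 4 cm radius. The low-energy preset
#' rises slowly (scatter spreads the kernel toward its edge) while the
#' high-energy preset rises fast (the central kernel value dominates),
#' mirroring the qualitative energy dependence of measured kernels.
#'
#' @param energy `"6E"`, `"9E"`, or `"15E"`.
#' @param ... Overrides passed to [synth_of_curve()].
#' @return An [of_curve()].
#' @export
preset_curve <- function(energy = c("6E", "9E", "15E"), ...) {
  energy <- match.arg(energy)
  pars <- switch(energy,
    "6E" = list(plateau = 1.0, rise_scale_cm = 1.8, shape_exponent = 2),
    "9E" = list(plateau = 0.9, rise_scale_cm = 1.3, shape_exponent = 2),
    "15E" = list(plateau = 0.8, rise_scale_cm = 0.8, shape_exponent = 1.5)
  )
  dots <- list(...)
  pars[names(dots)] <- dots
  do.call(synth_of_curve, c(pars, list(energy = energy)))
}

#' Synthetic cutout shapes: circles, rectangles, radial perturbations
#'
#' `"circle"` gives a regular `n`-gon inscribed in the circle of radius
#' `radius_cm`; `"rectangle"` a `width_cm` by `height_cm` box centered at the
#' origin; `"irregular"` a star-shaped outline
#' `r(theta) = radius_cm * (1 + amplitude * sum_k c_k sin(k theta + phi_k))`
#' with seeded coefficients over `harmonics` low-order modes, normalized so
#' the radial modulation never exceeds `amplitude` (< 0.5 guarantees a
#' simple polygon).
#'
#' @param kind `"circle"`, `"rectangle"`, or `"irregular"`.
#' @param radius_cm Circle / base radius, cm.
#' @param width_cm,height_cm Rectangle dimensions, cm.
#' @param amplitude Relative radial perturbation in `[0, 0.5)`.
#' @param harmonics Number of sinusoidal modes (default 4).
#' @param n Boundary vertex count for circle/irregular (default 128).
#' @param seed Integer seed for the irregular coefficients.
#' @param label Shape label; defaults to a description.
#' @return A [cutout_shape()].
#' @export
synth_cutout <- function(kind = c("circle", "rectangle", "irregular"),
                         radius_cm = 3, width_cm = 4, height_cm = 4,
                         amplitude = 0.3, harmonics = 4, n = 128, seed = 1,
                         label = NULL) {
  kind <- match.arg(kind)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  verts <- switch(kind,
    circle = {
      stop_if_not_number(radius_cm, "radius_cm", positive = TRUE)
      tibble::tibble(x_cm = radius_cm * cos(theta),
                     y_cm = radius_cm * sin(theta))
    },
    rectangle = {
      stop_if_not_number(width_cm, "width_cm", positive = TRUE)
      stop_if_not_number(height_cm, "height_cm", positive = TRUE)
      tibble::tibble(
        x_cm = c(-1, 1, 1, -1) * width_cm / 2,
        y_cm = c(-1, -1, 1, 1) * height_cm / 2
      )
    },
    irregular = {
      stop_if_not_number(radius_cm, "radius_cm", positive = TRUE)
      stop_if_not_number(amplitude, "amplitude", nonneg = TRUE)
      if (amplitude >= 0.5) {
        abort("`amplitude` must be < 0.5 (self-intersection risk).")
      }
      coef <- withr::with_seed(seed, list(
        c = rnorm(harmonics), phi = runif(harmonics, 0, 2 * pi)
      ))
      mod <- vapply(theta, function(t) {
        sum(coef$c * sin(seq_len(harmonics) * t + coef$phi))
      }, numeric(1))
      scale <- max(abs(mod))
      if (scale > 0) mod <- mod / scale # |modulation| <= 1
      r <- radius_cm * (1 + amplitude * mod)
      tibble::tibble(x_cm = r * cos(theta), y_cm = r * sin(theta))
    }
  )
  if (is.null(label)) {
    label <- switch(kind,
      circle = sprintf("circle r=%g cm", radius_cm),
      rectangle = sprintf("rect %gx%g cm", width_cm, height_cm),
      irregular = sprintf("irregular r=%g a=%g seed=%d", radius_cm, amplitude,
                          as.integer(seed))
    )
  }
  cutout_shape(verts, label = label)
}

#' Synthetic film-like measurement of a COF map
#'
#' Emulates a registered planar film measurement of a computed map:
#' resamples the map with an optional sub-pixel rigid shift (bilinear, zero
#' outside the grid) and adds seeded Gaussian noise expressed in percent of
#' the map maximum. The result lives on the same grid as the input, as a
#' registered film scan would.
#'
#' @param map A `cof_map` or `planar_distribution`.
#' @param noise_sd_pct Noise standard deviation, percent of the map maximum.
#' @param shift_mm Length-2 rigid shift (dx, dy) in mm applied to the field.
#' @param seed Integer seed.
#' @return A [planar_distribution()].
#' @export
synth_film <- function(map, noise_sd_pct = 0, shift_mm = c(0, 0), seed = 1) {
  src <- as_planar_distribution(map)
  stop_if_not_number(noise_sd_pct, "noise_sd_pct", nonneg = TRUE)
  if (length(shift_mm) != 2L || anyNA(shift_mm)) {
    abort("`shift_mm` must be two finite numbers (dx, dy).")
  }
  v <- shift_bilinear(src$values, shift_mm / src$resolution_mm)
  if (noise_sd_pct > 0) {
    sd_abs <- noise_sd_pct / 100 * max(src$values)
    v <- v + withr::with_seed(seed, matrix(rnorm(length(v), 0, sd_abs),
                                           nrow(v), ncol(v)))
    v <- pmax(v, 0)
  }
  planar_distribution(v, src$resolution_mm, src$origin)
}

# sample f at (x - dx, y - dy) by bilinear interpolation, zero outside;
# shift_px = c(dx_px, dy_px) moves the field by +x (columns), +y (rows)
shift_bilinear <- function(m, shift_px) {
  dx <- shift_px[1]; dy <- shift_px[2]
  if (dx == 0 && dy == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  sample_at <- function(i, j) { # fractional 1-based indices, zero outside
    out <- matrix(0, length(i), length(j))
    i0 <- floor(i); j0 <- floor(j)
    ti <- i - i0; tj <- j - j0
    for (a in 0:1) for (b in 0:1) {
      ia <- i0 + a; jb <- j0 + b
      wi <- if (a == 0) 1 - ti else ti
      wj <- if (b == 0) 1 - tj else tj
      ok_i <- ia >= 1 & ia <= nr
      ok_j <- jb >= 1 & jb <= nc
      mm <- matrix(0, length(i), length(j))
      mm[ok_i, ok_j] <- m[ia[ok_i], jb[ok_j], drop = FALSE]
      out <- out + outer(wi, wj) * mm
    }
    out
  }
  sample_at(seq_len(nr) - dy, seq_len(nc) - dx)
}
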