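#' Fit an output-factor curve from circular-cutout measurements
#'
#' An output factor (OF) is the dose per monitor unit for a given field
#' relative to the reference open applicator, measured on the central axis at
#' the depth of maximum dose. `of_curve()` takes the measured (radius, OF)
#' pairs for circular cutouts at one beam energy and SSD and fits an
#' interpolating curve through them, anchored at the origin with OF(0) = 0 so
#' that the annular decomposition used by [build_kernel()] telescopes exactly:
#' the kernel summed over a disk of radius R returns OF(R).
#'
#' The default interpolant is the Fritsch--Carlson monotone shape-preserving
#' piecewise cubic ([stats::splinefun()] with `method = "monoH.FC"`), which
#' reproduces every sample exactly and introduces no overshoot when the
#' samples are monotone. Beyond the largest measured radius the curve is
#' extrapolated as a constant at the last value, reflecting the plateau that
#' measured electron OF curves reach by roughly 4 cm radius.
#'
#' @param data Data frame with columns `radius_cm` (strictly increasing,
#'   positive) and `output_factor` (positive), one row per measured circular
#'   cutout.
#' @param energy Beam energy label, e.g. `"6E"`.
#' @param ssd_cm Source-to-surface distance of the measurements in cm.
#' @param interpolation `"monotone_cubic"` (default) or `"linear"`.
#'
#' @return An object of class `of_curve`. Evaluate it with [of_evaluate()] or
#'   `predict()`; inspect samples with [tidy()] and summary values with
#'   [glance()].
#' @examples
#' crv <- of_curve(
#'   tibble::tibble(radius_cm = 1:6,
#'                  output_factor = c(0.5, 0.8, 0.95, 1, 1, 1)),
#'   energy = "6E", ssd_cm = 100
#' )
#' of_evaluate(crv, c(0, 1.5, 4, 8))
#' @export
of_curve <- function(data, energy = "beam", ssd_cm = 100,
                     interpolation = c("monotone_cubic", "linear")) {
  interpolation <- match.arg(interpolation)
  if (!is.data.frame(data) ||
      !all(c("radius_cm", "output_factor") %in% names(data))) {
    abort("`data` must have columns `radius_cm` and `output_factor`.")
  }
  r <- as.numeric(data$radius_cm)
  of <- as.numeric(data$output_factor)
  if (length(r) < 2L) abort("insufficient samples: need at least 2 (radius, OF) pairs.")
  if (anyNA(r) || anyNA(of) || !all(is.finite(r)) || !all(is.finite(of))) {
    abort("radii and output factors must be finite.")
  }
  if (any(r <= 0)) abort("measured radii must be positive.")
  if (any(diff(r) <= 0)) abort("radii must be strictly increasing.")
  if (any(of <= 0)) abort("output factors must be positive.")
  stop_if_not_number(ssd_cm, "ssd_cm", positive = TRUE)

  structure(
    list(
      samples = tibble::tibble(radius_cm = r, output_factor = of),
      energy = as.character(energy)[1],
      ssd_cm = ssd_cm,
      interpolation = interpolation,
      plateau = of[length(of)],
      r_max = r[length(r)],
      partial = FALSE
    ),
    class = "of_curve"
  )
}

# interpolant through (0,0) and the samples; built lazily so the object
# stays plain-list serializable
of_interpolant <- function(curve) {
  x <- c(0, curve$samples$radius_cm)
  y <- c(0, curve$samples$output_factor)
  if (curve$interpolation == "linear") {
    approxfun(x, y, rule = 2)
  } else {
    fritsch_carlson_spline(x, y)
  }
}

# Fritsch-Carlson monotone piecewise cubic Hermite interpolant. Knot
# derivatives start at secant-slope averages and are then restricted to the
# disk alpha^2 + beta^2 <= 9 (alpha, beta the derivative/secant ratios of
# each interval), which is sufficient for monotonicity on every interval
# where the data are monotone -- a guarantee stats::splinefun's "monoH.FC"
# filtering does not quite deliver.
fritsch_carlson_spline <- function(x, y) {
  n <- length(x)
  h <- diff(x)
  delta <- diff(y) / h
  m <- numeric(n)
  m[1] <- delta[1]
  m[n] <- delta[n - 1]
  if (n > 2) {
    for (i in 2:(n - 1)) {
      m[i] <- if (delta[i - 1] * delta[i] <= 0) 0 else
        (delta[i - 1] + delta[i]) / 2
    }
  }
  for (i in seq_len(n - 1)) {
    if (delta[i] == 0) {
      m[i] <- 0
      m[i + 1] <- 0
    } else {
      a <- m[i] / delta[i]
      b <- m[i + 1] / delta[i]
      if (a < 0) { m[i] <- 0; a <- 0 }
      if (b < 0) { m[i + 1] <- 0; b <- 0 }
      s <- a * a + b * b
      if (s > 9) {
        tau <- 3 / sqrt(s)
        m[i] <- tau * a * delta[i]
        m[i + 1] <- tau * b * delta[i]
      }
    }
  }
  function(xo) {
    i <- pmin(pmax(findInterval(xo, x), 1L), n - 1L)
    t <- (xo - x[i]) / h[i]
    at_knot <- t == 0 | t == 1
    t2 <- t * t; t3 <- t2 * t
    v <- y[i] * (2 * t3 - 3 * t2 + 1) + h[i] * m[i] * (t3 - 2 * t2 + t) +
      y[i + 1] * (3 * t2 - 2 * t3) + h[i] * m[i + 1] * (t3 - t2)
    # knots are reproduced exactly, untouched by polynomial roundoff
    v[at_knot] <- y[i[at_knot] + (t[at_knot] == 1)]
    v
  }
}

#' Evaluate an output-factor curve at arbitrary radii
#'
#' Returns OF(r) with the fitted interpolant: exact at every measured radius,
#' 0 at r = 0, and constant at the plateau beyond the largest measured radius.
#'
#' @param curve An [of_curve()].
#' @param r Radii in cm; must be finite and non-negative.
#' @return Numeric vector of output factors, same length as `r`.
#' @export
of_evaluate <- function(curve, r) {
  stopifnot(inherits(curve, "of_curve"))
  if (!is.numeric(r) || anyNA(r) || !all(is.finite(r))) {
    abort("`r` must be finite.")
  }
  if (any(r < 0)) abort("`r` must be non-negative.")
  f <- of_interpolant(curve)
  f(pmin(r, curve$r_max))
}

#' @rdname of_evaluate
#' @param object,newdata,... `predict()` interface: `newdata` is a numeric
#'   vector of radii or a data frame with a `radius_cm` column.
#' @export
predict.of_curve <- function(object, newdata, ...) {
  r <- if (is.data.frame(newdata)) newdata$radius_cm else newdata
  of_evaluate(object, r)
}

#' @export
print.of_curve <- function(x, ...) {
  cat(sprintf(
    "<of_curve> %s @ SSD %g cm: %d samples on [%g, %g] cm, plateau %.4g (%s)%s\n",
    x$energy, x$ssd_cm, nrow(x$samples), min(x$samples$radius_cm), x$r_max,
    x$plateau, x$interpolation,
    if (isTRUE(x$partial)) " [partial: r >= ISL minimum only]" else ""
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.of_curve <- function(x, ...) {
  dplyr::mutate(x$samples, energy = x$energy, ssd_cm = x$ssd_cm)
}

#' @exportS3Method generics::glance
glance.of_curve <- function(x, ...) {
  tibble::tibble(
    energy = x$energy, ssd_cm = x$ssd_cm, n_samples = nrow(x$samples),
    r_min_cm = min(x$samples$radius_cm), r_max_cm = x$r_max,
    plateau = x$plateau, interpolation = x$interpolation,
    partial = isTRUE(x$partial)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.of_curve <- function(object, n = 200, ...) {
  grid <- tibble::tibble(radius_cm = seq(0, object$r_max * 1.2, length.out = n))
  grid$output_factor <- of_evaluate(object, grid$radius_cm)
  ggplot2::ggplot(grid, ggplot2::aes(.data$radius_cm, .data$output_factor)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object$samples) +
    ggplot2::labs(
      x = "circular cutout radius (cm)", y = "output factor",
      title = sprintf("%s output-factor curve, SSD %g cm",
                      object$energy, object$ssd_cm)
    )
}

#' Beam geometry for inverse-square SSD corrections
#'
#' Bundles the distances used by the effective-SSD inverse-square law:
#' the nominal SSD, the extended SSD at which a curve is wanted, the
#' effective SSD (distance from the virtual electron source to the
#' nominal-SSD plane), and the depth of maximum dose.
#'
#' @param ssd0_cm Nominal SSD in cm (default 100).
#' @param ssd_ext_cm Extended SSD in cm; must be `>= ssd0_cm`.
#' @param ssd_eff_cm Effective SSD in cm.
#' @param dmax_cm Depth of maximum dose in cm.
#' @return A `beam_geometry` list.
#' @export
beam_geometry <- function(ssd0_cm = 100, ssd_ext_cm, ssd_eff_cm, dmax_cm) {
  stop_if_not_number(ssd0_cm, "ssd0_cm", positive = TRUE)
  stop_if_not_number(ssd_ext_cm, "ssd_ext_cm", positive = TRUE)
  stop_if_not_number(ssd_eff_cm, "ssd_eff_cm", positive = TRUE)
  stop_if_not_number(dmax_cm, "dmax_cm", positive = TRUE)
  if (ssd_ext_cm < ssd0_cm) {
    abort("`ssd_ext_cm` must be >= `ssd0_cm` for the extension use case.")
  }
  structure(
    list(ssd0_cm = ssd0_cm, ssd_ext_cm = ssd_ext_cm,
         ssd_eff_cm = ssd_eff_cm, dmax_cm = dmax_cm),
    class = "beam_geometry"
  )
}

#' Extend a nominal-SSD curve to an extended SSD by the inverse-square law
#'
#' For circular cutouts with radius at or above `min_radius_cm` the effective
#' SSD changes little with field size, so the extended-SSD output factor can
#' be derived from the nominal-SSD one:
#' \deqn{OF_{ext}(r) = OF_0(r) \Big/
#'   \left(\frac{SSD_{eff} + d_{max} + SSD_{ext} - SSD_0}
#'              {SSD_{eff} + d_{max}}\right)^2}
#' Samples below `min_radius_cm` are not derived; the returned curve contains
#' only the derived large-radius subset and is flagged `partial`. Combine it
#' with directly measured small-radius extended-SSD samples via
#' [of_merge_samples()] before building a kernel.
#'
#' @param curve An [of_curve()] measured at the nominal SSD.
#' @param geom A [beam_geometry()].
#' @param min_radius_cm Smallest radius (cm) for which the inverse-square
#'   derivation is trusted; default 4.
#' @return A partial `of_curve` at `geom$ssd_ext_cm`.
#' @examples
#' crv <- of_curve(tibble::tibble(radius_cm = 1:6,
#'                                output_factor = c(.5, .8, .95, 1, 1, 1)))
#' g <- beam_geometry(100, 110, 95, 1.5)
#' tidy(of_extend_inverse_square(crv, g))
#' @export
of_extend_inverse_square <- function(curve, geom, min_radius_cm = 4) {
  stopifnot(inherits(curve, "of_curve"), inherits(geom, "beam_geometry"))
  stop_if_not_number(min_radius_cm, "min_radius_cm", nonneg = TRUE)
  denom <- geom$ssd_eff_cm + geom$dmax_cm
  if (denom <= 0) abort("SSD_eff + d_max must be positive.")
  factor <- ((denom + geom$ssd_ext_cm - geom$ssd0_cm) / denom)^2

  keep <- curve$samples$radius_cm >= min_radius_cm
  if (sum(keep) < 2L) {
    abort(sprintf(
      "only %d sample(s) at radius >= %g cm: too few to derive a curve; measure more circular cutouts or lower `min_radius_cm`.",
      sum(keep), min_radius_cm
    ))
  }
  out <- of_curve(
    tibble::tibble(
      radius_cm = curve$samples$radius_cm[keep],
      output_factor = curve$samples$output_factor[keep] / factor
    ),
    energy = curve$energy, ssd_cm = geom$ssd_ext_cm,
    interpolation = curve$interpolation
  )
  out$partial <- any(!keep)
  out
}

#' Merge directly measured and inverse-square-derived output-factor samples
#'
#' Combines small-radius samples measured directly at the extended SSD with
#' the large-radius samples derived by [of_extend_inverse_square()], giving a
#' full curve for kernel construction from a reduced measurement set.
#'
#' @param derived A partial `of_curve` from [of_extend_inverse_square()].
#' @param measured Data frame with `radius_cm` and `output_factor` columns:
#'   direct measurements at the extended SSD. Radii overlapping the derived
#'   subset are taken from `measured` (a direct measurement wins).
#' @return A complete `of_curve` at the extended SSD.
#' @export
of_merge_samples <- function(derived, measured) {
  stopifnot(inherits(derived, "of_curve"))
  if (!is.data.frame(measured) ||
      !all(c("radius_cm", "output_factor") %in% names(measured))) {
    abort("`measured` must have columns `radius_cm` and `output_factor`.")
  }
  keep <- !(derived$samples$radius_cm %in% measured$radius_cm)
  combined <- dplyr::arrange(
    dplyr::bind_rows(
      measured[, c("radius_cm", "output_factor")],
      derived$samples[keep, ]
    ),
    .data$radius_cm
  )
  of_curve(combined, energy = derived$energy, ssd_cm = derived$ssd_cm,
           interpolation = derived$interpolation)
}

#' Percentage difference between two cutout output factors
#'
#' Symmetric percentage difference with the arithmetic-mean denominator:
#' \eqn{100\,|a - b| / (0.5 (a + b))}. Used to compare COFs from kernels built
#' on full versus reduced circular-field measurement sets.
#'
#' @param cof_full,cof_limited Positive output factors (vectorized).
#' @return Percentage difference(s).
#' @examples
#' pct_difference(1.0, 0.9) # 10.526...
#' @export
pct_difference <- function(cof_full, cof_limited) {
  if (!is.numeric(cof_full) || !is.numeric(cof_limited) ||
      anyNA(cof_full) || anyNA(cof_limited) ||
      any(!is.finite(cof_full)) || any(!is.finite(cof_limited))) {
    abort("inputs must be finite numbers.")
  }
  if (any(cof_full <= 0) || any(cof_limited <= 0)) {
    abort("output factors must be positive.")
  }
  100 * abs(cof_full - cof_limited) / (0.5 * (cof_full + cof_limited))
}
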