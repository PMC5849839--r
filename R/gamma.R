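#' Planar relative-dose distribution
#'
#' A dense grid of relative dose/output values with its geometry, the common
#' container for film scans, computed COF maps, and synthetic fields entering
#' gamma analysis.
#'
#' @param values Numeric matrix, finite and non-negative; rows index y
#'   (increasing), columns x.
#' @param resolution_mm Pixel pitch in mm.
#' @param origin Physical (x, y) of the center of pixel `[1, 1]`, cm.
#' @return A `planar_distribution`.
#' @export
planar_distribution <- function(values, resolution_mm = 1,
                                origin = c(x_cm = 0, y_cm = 0)) {
  if (!is.matrix(values) || length(values) == 0L) {
    abort("`values` must be a non-empty matrix.")
  }
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0)) {
    abort("`values` must be finite and non-negative.")
  }
  stop_if_not_number(resolution_mm, "resolution_mm", positive = TRUE)
  structure(
    list(values = values, resolution_mm = resolution_mm,
         origin = c(x_cm = unname(origin[1]), y_cm = unname(origin[2]))),
    class = "planar_distribution"
  )
}

#' Coerce a COF map to a planar distribution
#' @param map A `cof_map`.
#' @return A `planar_distribution` on the same grid.
#' @export
as_planar_distribution <- function(map) {
  if (inherits(map, "planar_distribution")) return(map)
  stopifnot(inherits(map, "cof_map"))
  planar_distribution(map$values, map$resolution_mm, map$origin)
}

#' Gamma-index comparison of two planar distributions
#'
#' For each reference point, gamma is the minimum over nearby evaluated
#' points of \eqn{\sqrt{r^2/\Delta d^2 + \delta^2/\Delta D^2}}, where `r` is
#' the spatial separation, `delta` the dose difference expressed in percent
#' of the normalization value, and the criteria default to 3 mm
#' distance-to-agreement and 3% dose difference. Normalization is global at
#' the reference maximum (the convention that gives the best achievable
#' global passing rate); set `local = TRUE` to normalize each point by its
#' own reference dose instead.
#'
#' The search covers a disk of radius `search_factor * dta_mm` on the
#' evaluated grid upsampled `upsample`-fold by bilinear interpolation.
#' Reference points whose search window leaves the evaluated extent are
#' excluded (NA in the gamma map) and counted in `n_edge_excluded`. Both
#' distributions must share one grid (registered inputs).
#'
#' @param reference,evaluated [planar_distribution()]s (or `cof_map`s) on the
#'   same grid.
#' @param dose_pct Dose-difference criterion, percent (default 3).
#' @param dta_mm Distance-to-agreement criterion, mm (default 3).
#' @param search_factor Search radius in units of `dta_mm` (default 3).
#' @param upsample Sub-pixel refinement factor of the evaluated grid
#'   (default 3).
#' @param local Use local dose normalization (default `FALSE`, global at the
#'   reference maximum).
#' @param low_dose_threshold_pct Points with reference dose below this
#'   percentage of the normalization value are left out of the default
#'   passing-rate denominator (default 10). Recompute with [passing_rate()].
#' @return A `gamma_result` with the gamma map, criteria, normalization, and
#'   the default passing rate.
#' @export
gamma_index <- function(reference, evaluated, dose_pct = 3, dta_mm = 3,
                        search_factor = 3, upsample = 3, local = FALSE,
                        low_dose_threshold_pct = 10) {
  reference <- as_planar_distribution(reference)
  evaluated <- as_planar_distribution(evaluated)
  stop_if_not_number(dose_pct, "dose_pct", positive = TRUE)
  stop_if_not_number(dta_mm, "dta_mm", positive = TRUE)
  stop_if_not_number(search_factor, "search_factor", positive = TRUE)
  if (upsample < 1 || upsample != round(upsample)) {
    abort("`upsample` must be a positive integer.")
  }
  if (!identical(dim(reference$values), dim(evaluated$values)) ||
      reference$resolution_mm != evaluated$resolution_mm ||
      any(abs(reference$origin - evaluated$origin) > 1e-9)) {
    abort("reference and evaluated must share one grid (same extent, resolution, origin); register the distributions first.")
  }
  norm <- max(reference$values)
  if (norm <= 0) abort("zero normalization value: reference has no dose.")

  r_vals <- reference$values
  e_up <- bilinear_upsample(evaluated$values, upsample)
  res_up <- reference$resolution_mm / upsample
  w <- ceiling(search_factor * dta_mm / res_up) # window half-width, up-px

  nr <- nrow(r_vals); nc <- ncol(r_vals)
  # reference point (i, j) sits at upsampled index ((i-1)*u + 1, (j-1)*u + 1)
  u <- upsample
  ref_i_up <- (seq_len(nr) - 1L) * u + 1L
  ref_j_up <- (seq_len(nc) - 1L) * u + 1L
  in_i <- which(ref_i_up - w >= 1L & ref_i_up + w <= nrow(e_up))
  in_j <- which(ref_j_up - w >= 1L & ref_j_up + w <= ncol(e_up))
  gamma_map <- matrix(NA_real_, nr, nc)
  n_edge <- nr * nc - length(in_i) * length(in_j)
  if (length(in_i) == 0L || length(in_j) == 0L) {
    abort("search window exceeds the evaluated extent everywhere; reduce `search_factor * dta_mm` or supply a larger evaluated grid.")
  }

  offs <- expand.grid(di = -w:w, dj = -w:w)
  dist2_mm2 <- (offs$di^2 + offs$dj^2) * res_up^2
  keep <- dist2_mm2 <= (search_factor * dta_mm)^2
  offs <- offs[keep, ]; dist2_mm2 <- dist2_mm2[keep]
  ord <- order(dist2_mm2) # nearest first: min typically found early
  offs <- offs[ord, ]; dist2_mm2 <- dist2_mm2[ord]

  r_in <- r_vals[in_i, in_j, drop = FALSE]
  denom_d <- if (local) (dose_pct / 100)^2 * r_in^2 else
    (dose_pct / 100)^2 * norm^2
  g2 <- matrix(Inf, length(in_i), length(in_j))
  base_i <- ref_i_up[in_i]; base_j <- ref_j_up[in_j]
  for (s in seq_len(nrow(offs))) {
    # offsets are distance-sorted: once the pure-distance term alone exceeds
    # the worst current gamma^2, no later offset can improve any point
    if (dist2_mm2[s] / dta_mm^2 >= max(g2)) break
    e_sub <- e_up[base_i + offs$di[s], base_j + offs$dj[s], drop = FALSE]
    diff2 <- (e_sub - r_in)^2
    cand <- dist2_mm2[s] / dta_mm^2 + diff2 / denom_d
    g2 <- pmin(g2, cand)
  }
  gamma_map[in_i, in_j] <- sqrt(g2)

  res <- structure(
    list(
      gamma_map = gamma_map,
      reference_values = r_vals,
      dose_criterion_pct = dose_pct, dta_mm = dta_mm,
      normalization_value = norm, local = local,
      search_factor = search_factor, upsample = upsample,
      resolution_mm = reference$resolution_mm, origin = reference$origin,
      n_edge_excluded = n_edge,
      low_dose_threshold_pct = low_dose_threshold_pct,
      passing_rate_pct = NA_real_
    ),
    class = "gamma_result"
  )
  res$passing_rate_pct <- passing_rate(res, low_dose_threshold_pct)
  res
}

# separable bilinear upsampling: (n-1)*u + 1 samples per axis, endpoints kept
bilinear_upsample <- function(m, u) {
  if (u == 1L) return(m)
  up_axis <- function(mat) {
    n <- nrow(mat)
    if (n == 1L) return(mat)
    p <- seq(0, n - 1, by = 1 / u)
    i0 <- pmin(floor(p), n - 2)
    t <- p - i0
    mat[i0 + 1, , drop = FALSE] * (1 - t) + mat[i0 + 2, , drop = FALSE] * t
  }
  t(up_axis(t(up_axis(m))))
}

#' Gamma passing rate with a low-dose threshold
#'
#' Percentage of analyzable points with gamma at most 1, counting only
#' points whose reference dose is at least `low_dose_threshold_pct` percent
#' of the normalization value (0 includes every point); edge-excluded points
#' never enter the denominator.
#'
#' @param result A [gamma_index()] result.
#' @param low_dose_threshold_pct Threshold, percent of normalization.
#' @return Passing rate in percent.
#' @export
passing_rate <- function(result, low_dose_threshold_pct = 10) {
  stopifnot(inherits(result, "gamma_result"))
  stop_if_not_number(low_dose_threshold_pct, "low_dose_threshold_pct",
                     nonneg = TRUE)
  sel <- !is.na(result$gamma_map) &
    result$reference_values >=
      low_dose_threshold_pct / 100 * result$normalization_value
  if (!any(sel)) abort("no points above the low-dose threshold.")
  100 * mean(result$gamma_map[sel] <= 1)
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf(
    "<gamma_result> %g%%/%g mm (%s): passing %.2f%% (threshold %g%%), %d edge-excluded px\n",
    x$dose_criterion_pct, x$dta_mm,
    if (x$local) "local" else "global",
    x$passing_rate_pct, x$low_dose_threshold_pct, x$n_edge_excluded
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gamma_result <- function(x, ...) {
  out <- grid_tidy(x$gamma_map, x$resolution_mm, x$origin, "gamma")
  out$reference <- as.vector(t(x$reference_values))
  out$pass <- out$gamma <= 1
  out
}

#' @exportS3Method generics::glance
glance.gamma_result <- function(x, ...) {
  tibble::tibble(
    dose_criterion_pct = x$dose_criterion_pct, dta_mm = x$dta_mm,
    local = x$local, normalization_value = x$normalization_value,
    passing_rate_pct = x$passing_rate_pct,
    low_dose_threshold_pct = x$low_dose_threshold_pct,
    n_edge_excluded = x$n_edge_excluded,
    max_gamma = max(x$gamma_map, na.rm = TRUE),
    mean_gamma = mean(x$gamma_map, na.rm = TRUE)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.gamma_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$x_cm, .data$y_cm, fill = .data$gamma)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey50") +
    ggplot2::labs(
      x = "x (cm)", y = "y (cm)", fill = expression(gamma),
      title = sprintf("Gamma map %g%%/%g mm, passing %.1f%%",
                      object$dose_criterion_pct, object$dta_mm,
                      object$passing_rate_pct)
    )
}

#' @exportS3Method generics::tidy
tidy.planar_distribution <- function(x, ...) {
  grid_tidy(x$values, x$resolution_mm, x$origin, "value")
}

#' @export
print.planar_distribution <- function(x, ...) {
  cat(sprintf("<planar_distribution> %dx%d px @ %g mm, max %.4g, origin (%g, %g) cm\n",
              nrow(x$values), ncol(x$values), x$resolution_mm, max(x$values),
              x$origin[1], x$origin[2]))
  invisible(x)
}
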