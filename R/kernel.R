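#' Annulus index of a pixel offset
#'
#' Assigns a pixel at integer offset (row, col) from the kernel center to an
#' annular bin by its center distance: bin `k` holds distances
#' `[k * delta_r, (k + 1) * delta_r)` (half-open), with
#' `d = resolution_mm * sqrt(row^2 + col^2)`.
#'
#' @param offset_row,offset_col Integer pixel offsets (vectorized).
#' @param resolution_mm Pixel pitch in mm.
#' @param delta_r_mm Annulus width in mm.
#' @return Integer annulus indices (0 = central pixel's bin).
#' @examples
#' annulus_index(1, 1) # sqrt(2) mm -> bin 1
#' @export
annulus_index <- function(offset_row, offset_col,
                          resolution_mm = 1, delta_r_mm = 1) {
  stop_if_not_number(resolution_mm, "resolution_mm", positive = TRUE)
  stop_if_not_number(delta_r_mm, "delta_r_mm", positive = TRUE)
  if (anyNA(offset_row) || anyNA(offset_col)) abort("offsets must be finite.")
  d <- resolution_mm * sqrt(offset_row^2 + offset_col^2)
  as.integer(floor(d / delta_r_mm))
}

#' Build the 2D annular output kernel from an output-factor curve
#'
#' The annular output factor of ring `k` is
#' `AOF_k = OF((k + 1) dr) - OF(k dr)`: the output contribution of the annulus
#' obtained by subtracting a circular field of radius `k dr` from one of
#' radius `(k + 1) dr`. Each kernel pixel in annulus `k` (by center-distance
#' binning, see [annulus_index()]) carries `AOF_k / NP_k`, where `NP_k` is the
#' number of pixels in that annulus, so the kernel is circularly symmetric and
#' its sum over the binned disk of radius `K dr` telescopes exactly to
#' `OF(K dr)` (the curve is anchored at OF(0) = 0).
#'
#' @param curve An [of_curve()].
#' @param resolution_mm Pixel pitch in mm (default 1, matching 1 mm curve
#'   sampling).
#' @param max_radius_cm Kernel support radius in cm; defaults to the largest
#'   measured radius. Pixels at or beyond this distance are zero.
#' @param delta_r_mm Annulus width in mm; defaults to the pixel pitch.
#' @param clip_negative_aof If `TRUE`, negative annular output factors (from
#'   measurement noise) are clipped to zero; this breaks the telescoping
#'   identity, so the default keeps them and warns.
#' @param negative_aof Either `"warn"` (default) or `"error"`.
#' @return An `of_kernel`: an odd-sized square matrix of per-pixel output
#'   contributions plus its geometry. Inspect with [kernel_profile()],
#'   [tidy()], [glance()], [autoplot()].
#' @export
build_kernel <- function(curve, resolution_mm = 1,
                         max_radius_cm = curve$r_max,
                         delta_r_mm = resolution_mm,
                         clip_negative_aof = FALSE,
                         negative_aof = c("warn", "error")) {
  stopifnot(inherits(curve, "of_curve"))
  negative_aof <- match.arg(negative_aof)
  stop_if_not_number(resolution_mm, "resolution_mm", positive = TRUE)
  stop_if_not_number(delta_r_mm, "delta_r_mm", positive = TRUE)
  stop_if_not_number(max_radius_cm, "max_radius_cm", positive = TRUE)
  max_radius_mm <- max_radius_cm * 10
  if (max_radius_mm < resolution_mm) {
    abort("`max_radius_cm` is smaller than one pixel.")
  }

  n_annuli <- floor(max_radius_mm / delta_r_mm) # support: annuli 0 .. n-1
  half <- as.integer(ceiling(n_annuli * delta_r_mm / resolution_mm))
  m <- 2L * half + 1L
  off <- seq.int(-half, half)
  k <- annulus_index(
    matrix(off, m, m), matrix(off, m, m, byrow = TRUE),
    resolution_mm, delta_r_mm
  )

  aof <- diff(of_evaluate(curve, (0:n_annuli) * delta_r_mm / 10))
  flagged <- any(aof < -1e-12) # roundoff-level negativity is not a signal
  if (flagged) {
    if (negative_aof == "error") {
      abort("negative annular output factor: curve is not non-decreasing.")
    }
    warn("negative annular output factor(s): noisy or non-monotone curve.")
    if (clip_negative_aof) aof <- pmax(aof, 0)
  }

  np <- tabulate(k + 1L, nbins = n_annuli) # pixels per annulus inside support
  values <- matrix(0, m, m)
  inside <- k < n_annuli
  values[inside] <- (aof / np)[k[inside] + 1L]

  structure(
    list(
      values = values, resolution_mm = resolution_mm,
      delta_r_mm = delta_r_mm,
      center_index = c(row = half + 1L, col = half + 1L),
      max_radius_cm = max_radius_cm,
      energy = curve$energy, ssd_cm = curve$ssd_cm,
      negative_aof = flagged && !clip_negative_aof
    ),
    class = "of_kernel"
  )
}

#' Per-annulus kernel profile
#'
#' One row per annulus: its representative radius (inner edge, `k * delta_r`),
#' the per-pixel kernel value, the pixel count, and the annular output factor
#' it carries. Useful for comparing kernel shapes across beam energies.
#'
#' @param kernel An `of_kernel`.
#' @return A tibble with columns `annulus`, `radius_mm`, `value`, `n_pixels`,
#'   `aof`.
#' @export
kernel_profile <- function(kernel) {
  stopifnot(inherits(kernel, "of_kernel"))
  half <- kernel$center_index[["row"]] - 1L
  off <- seq.int(-half, half)
  m <- 2L * half + 1L
  k <- annulus_index(matrix(off, m, m), matrix(off, m, m, byrow = TRUE),
                     kernel$resolution_mm, kernel$delta_r_mm)
  n_annuli <- as.integer(floor(kernel$max_radius_cm * 10 / kernel$delta_r_mm))
  idx <- k < n_annuli
  first <- match(0:(n_annuli - 1L), k[idx])
  np <- tabulate(k[idx] + 1L, nbins = n_annuli)
  v <- ifelse(is.na(first), 0, kernel$values[idx][first]) # 0 for empty annuli
  tibble::tibble(
    annulus = 0:(n_annuli - 1L),
    radius_mm = (0:(n_annuli - 1L)) * kernel$delta_r_mm,
    value = v,
    n_pixels = np,
    aof = v * np
  )
}

#' @export
print.of_kernel <- function(x, ...) {
  cat(sprintf(
    "<of_kernel> %s @ SSD %g cm: %dx%d px, %g mm/px, support %g cm, max %.4g, sum %.4g%s\n",
    x$energy, x$ssd_cm, nrow(x$values), ncol(x$values), x$resolution_mm,
    x$max_radius_cm, max(x$values), sum(x$values),
    if (isTRUE(x$negative_aof)) " [contains negative AOF]" else ""
  ))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.of_kernel <- function(x, ...) {
  tibble::tibble(
    energy = x$energy, ssd_cm = x$ssd_cm,
    size_px = nrow(x$values), resolution_mm = x$resolution_mm,
    delta_r_mm = x$delta_r_mm, max_radius_cm = x$max_radius_cm,
    max_value = max(x$values), total = sum(x$values),
    negative_aof = isTRUE(x$negative_aof)
  )
}

# long-tibble view of any grid object (kernel / mask / map / gamma)
grid_tidy <- function(values, resolution_mm, origin, value_name) {
  res_cm <- resolution_mm / 10
  out <- tidyr::expand_grid(row = seq_len(nrow(values)),
                            col = seq_len(ncol(values)))
  out$x_cm <- origin[1] + (out$col - 1) * res_cm
  out$y_cm <- origin[2] + (out$row - 1) * res_cm
  out[[value_name]] <- as.vector(t(values)) # row-major to match expand_grid
  out
}

#' @exportS3Method generics::tidy
tidy.of_kernel <- function(x, ...) {
  half <- x$center_index[["row"]] - 1L
  org <- c(-half, -half) * x$resolution_mm / 10
  out <- grid_tidy(x$values, x$resolution_mm, org, "value")
  out$annulus <- annulus_index(
    out$row - x$center_index[["row"]], out$col - x$center_index[["col"]],
    x$resolution_mm, x$delta_r_mm
  )
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.of_kernel <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$x_cm, .data$y_cm, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "x (cm)", y = "y (cm)", fill = "OK",
      title = sprintf("Output kernel, %s @ SSD %g cm",
                      object$energy, object$ssd_cm)
    )
}
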