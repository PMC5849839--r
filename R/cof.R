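#' Compute the 2D cutout-output-factor map by convolution
#'
#' The cutout output factor at pixel (x, y) is the double sum of the output
#' kernel over the open part of the aperture,
#' `COF[x, y] = sum_{n1, n2} OK[n1, n2] * f[x - n1, y - n2]`,
#' with the kernel indexed symmetrically about its center and everything
#' outside the mask grid treated as blocked (zero). The default route
#' evaluates the sum by zero-padded 2D FFT; `method = "direct"` accumulates
#' the kernel-shifted mask explicitly and is bitwise-independent of the FFT
#' path, which tests exploit as a cross-check.
#'
#' @param kernel An [build_kernel()] result.
#' @param mask An [rasterize()] result at the same pixel pitch, padded by at
#'   least the kernel half-width so no open pixel sits closer to the grid
#'   border than the kernel support.
#' @param method `"fft"` (default) or `"direct"`.
#' @return A `cof_map` with the mask's geometry.
#' @export
compute_cof_map <- function(kernel, mask, method = c("fft", "direct")) {
  stopifnot(inherits(kernel, "of_kernel"), inherits(mask, "aperture_mask"))
  method <- match.arg(method)
  if (kernel$resolution_mm != mask$resolution_mm) {
    abort(sprintf("resolution mismatch: kernel %g mm vs mask %g mm.",
                  kernel$resolution_mm, mask$resolution_mm))
  }
  half <- kernel$center_index[["row"]] - 1L
  open_idx <- which(mask$values != 0L, arr.ind = TRUE)
  if (nrow(open_idx) > 0L) {
    margin <- min(open_idx[, 1] - 1L, nrow(mask$values) - open_idx[, 1],
                  open_idx[, 2] - 1L, ncol(mask$values) - open_idx[, 2])
    if (margin < half) {
      abort(sprintf(
        "insufficient mask padding: open pixels within %d px of the border; re-rasterize with padding_cm >= %g.",
        margin, half * kernel$resolution_mm / 10
      ))
    }
  }

  values <- switch(method,
    fft = conv2_same_fft(mask$values, kernel$values),
    direct = conv2_same_direct(mask$values, kernel$values)
  )
  if (method == "fft") {
    # FFT roundoff leaves |noise| ~ 1e-16 where the exact sum is zero
    values[abs(values) < 1e-12] <- 0
  }

  structure(
    list(values = values, resolution_mm = mask$resolution_mm,
         origin = mask$origin, energy = kernel$energy,
         ssd_cm = kernel$ssd_cm, label = mask$label),
    class = "cof_map"
  )
}

# "same"-size 2D convolution with zero boundary, FFT route; the kernel is
# odd-sized and centered, so the result aligns with the mask grid
conv2_same_fft <- function(f, k) {
  nf <- dim(f); nk <- dim(k)
  half <- (nk - 1L) %/% 2L
  n <- nf + nk - 1L
  fp <- matrix(0, n[1], n[2]); fp[seq_len(nf[1]), seq_len(nf[2])] <- f
  kp <- matrix(0, n[1], n[2]); kp[seq_len(nk[1]), seq_len(nk[2])] <- k
  full <- Re(fft(fft(fp) * fft(kp), inverse = TRUE)) / prod(n)
  full[half[1] + seq_len(nf[1]), half[2] + seq_len(nf[2])]
}

# the same double sum written out: for each kernel offset, add the shifted
# mask weighted by the kernel value (zero outside the grid)
conv2_same_direct <- function(f, k) {
  nf <- dim(f); nk <- dim(k)
  half <- (nk - 1L) %/% 2L
  out <- matrix(0, nf[1], nf[2])
  for (i in seq_len(nk[1])) {
    di <- i - 1L - half[1]
    r_dst <- max(1L, 1L + di):min(nf[1], nf[1] + di)
    if (length(r_dst) == 0L) next
    r_src <- r_dst - di
    for (j in seq_len(nk[2])) {
      v <- k[i, j]
      if (v == 0) next
      dj <- j - 1L - half[2]
      c_dst <- max(1L, 1L + dj):min(nf[2], nf[2] + dj)
      if (length(c_dst) == 0L) next
      out[r_dst, c_dst] <- out[r_dst, c_dst] + v * f[r_src, c_dst - dj]
    }
  }
  out
}

#' Query a COF map at a physical point
#'
#' @param map A `cof_map`.
#' @param x_cm,y_cm Point in cutout-plane cm coordinates; must lie inside the
#'   map extent.
#' @param method `"nearest"` (default; chamber positioning is ~1 mm anyway)
#'   or `"bilinear"`.
#' @return The cutout output factor at the point.
#' @export
cof_at_point <- function(map, x_cm, y_cm, method = c("nearest", "bilinear")) {
  stopifnot(inherits(map, "cof_map"))
  method <- match.arg(method)
  stop_if_not_number(x_cm, "x_cm"); stop_if_not_number(y_cm, "y_cm")
  res_cm <- map$resolution_mm / 10
  fx <- (x_cm - map$origin[["x_cm"]]) / res_cm # 0-based fractional col
  fy <- (y_cm - map$origin[["y_cm"]]) / res_cm # 0-based fractional row
  nr <- nrow(map$values); nc <- ncol(map$values)
  if (fx < -0.5 || fx > nc - 0.5 || fy < -0.5 || fy > nr - 0.5) {
    abort("point outside map extent.")
  }
  if (method == "nearest") {
    return(map$values[pmin(nr, round(fy) + 1), pmin(nc, round(fx) + 1)])
  }
  fx <- min(max(fx, 0), nc - 1); fy <- min(max(fy, 0), nr - 1)
  i0 <- floor(fy); j0 <- floor(fx)
  ti <- fy - i0; tj <- fx - j0
  i1 <- min(i0 + 1, nr - 1); j1 <- min(j0 + 1, nc - 1)
  (1 - ti) * ((1 - tj) * map$values[i0 + 1, j0 + 1] + tj * map$values[i0 + 1, j1 + 1]) +
    ti * ((1 - tj) * map$values[i1 + 1, j0 + 1] + tj * map$values[i1 + 1, j1 + 1])
}

#' Locate the convolution maximum (recommended measurement point)
#'
#' Chamber measurements of irregular cutouts are taken at the center of the
#' largest opening, where the dose peaks; the convolution maximum supplies
#' that point reproducibly. Ties are broken by the smallest row-major index;
#' all pixels within 0.1% of the maximum are returned as the plateau set, a
#' guide to how tightly the measurement point is determined.
#'
#' @param map A `cof_map` with at least one nonzero pixel.
#' @param plateau_tol Relative tolerance defining the plateau set.
#' @return A list with `x_cm`, `y_cm`, `cof`, and `plateau` (a tibble of
#'   near-maximal pixels).
#' @export
find_max_point <- function(map, plateau_tol = 0.001) {
  stopifnot(inherits(map, "cof_map"))
  v <- map$values
  if (all(v == 0)) abort("empty aperture: COF map is identically zero.")
  m <- max(v)
  # row-major scan order: row varies slowest
  hits <- which(t(v) == m)
  first <- hits[1]
  row <- (first - 1L) %/% ncol(v) + 1L
  col <- (first - 1L) %% ncol(v) + 1L
  res_cm <- map$resolution_mm / 10
  plat <- which(t(v) >= m * (1 - plateau_tol))
  prow <- (plat - 1L) %/% ncol(v) + 1L
  pcol <- (plat - 1L) %% ncol(v) + 1L
  list(
    x_cm = map$origin[["x_cm"]] + (col - 1L) * res_cm,
    y_cm = map$origin[["y_cm"]] + (row - 1L) * res_cm,
    cof = m,
    plateau = tibble::tibble(
      x_cm = map$origin[["x_cm"]] + (pcol - 1L) * res_cm,
      y_cm = map$origin[["y_cm"]] + (prow - 1L) * res_cm,
      cof = v[cbind(prow, pcol)]
    )
  )
}

#' @export
print.cof_map <- function(x, ...) {
  mx <- if (all(x$values == 0)) NULL else find_max_point(x)
  cat(sprintf("<cof_map> '%s' (%s @ SSD %g cm): %dx%d px @ %g mm\n",
              x$label, x$energy, x$ssd_cm, nrow(x$values), ncol(x$values),
              x$resolution_mm))
  if (!is.null(mx)) {
    cat(sprintf("  max COF %.4f at (%.1f, %.1f) cm, plateau of %d px\n",
                mx$cof, mx$x_cm, mx$y_cm, nrow(mx$plateau)))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cof_map <- function(x, ...) {
  grid_tidy(x$values, x$resolution_mm, x$origin, "cof")
}

#' @exportS3Method generics::glance
glance.cof_map <- function(x, ...) {
  mx <- find_max_point(x)
  tibble::tibble(
    label = x$label, energy = x$energy, ssd_cm = x$ssd_cm,
    n_row = nrow(x$values), n_col = ncol(x$values),
    resolution_mm = x$resolution_mm,
    max_cof = mx$cof, max_x_cm = mx$x_cm, max_y_cm = mx$y_cm,
    plateau_px = nrow(mx$plateau)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.cof_map <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$x_cm, .data$y_cm, fill = .data$cof)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)", fill = "COF",
                  title = sprintf("COF map, %s @ SSD %g cm",
                                  object$energy, object$ssd_cm))
}
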