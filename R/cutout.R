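#' Create a cutout aperture shape
#'
#' A cutout is the patient-specific insert that shapes an electron field
#' inside the applicator cone; its opening is modelled as a single simple
#' polygon in the cutout plane, in cm, y up, origin at the cone center. The
#' vertex list is implicitly closed (do not repeat the first vertex; a
#' repeated closing vertex is dropped).
#'
#' @param vertices Data frame with columns `x_cm`, `y_cm`, one vertex per row
#'   in order around the boundary; at least 3 distinct vertices.
#' @param label Optional shape label.
#' @return A `cutout_shape`.
#' @examples
#' sq <- cutout_shape(tibble::tibble(x_cm = c(0, 2, 2, 0),
#'                                   y_cm = c(0, 0, 2, 2)))
#' p2a(sq)
#' @export
cutout_shape <- function(vertices, label = "cutout") {
  if (!is.data.frame(vertices) ||
      !all(c("x_cm", "y_cm") %in% names(vertices))) {
    abort("`vertices` must have columns `x_cm` and `y_cm`.")
  }
  x <- as.numeric(vertices$x_cm)
  y <- as.numeric(vertices$y_cm)
  if (anyNA(x) || anyNA(y) || !all(is.finite(c(x, y)))) {
    abort("vertex coordinates must be finite.")
  }
  n <- length(x)
  if (n >= 4L && x[1] == x[n] && y[1] == y[n]) { # explicit closure
    x <- x[-n]; y <- y[-n]; n <- n - 1L
  }
  if (n < 3L) abort("degenerate polygon: need at least 3 vertices.")
  if (abs(shoelace_area(x, y)) <= 0) abort("degenerate polygon: zero area.")
  if (!polygon_is_simple(x, y)) {
    abort("polygon is self-intersecting; only simple (single-loop) apertures are supported.")
  }
  structure(
    list(vertices = tibble::tibble(x_cm = x, y_cm = y),
         label = as.character(label)[1]),
    class = "cutout_shape"
  )
}

shoelace_area <- function(x, y) {
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# proper pairwise segment-intersection test between non-adjacent edges
polygon_is_simple <- function(x, y) {
  n <- length(x)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cross <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  pairs <- which(
    outer(seq_len(n), seq_len(n), function(i, j) {
      j > i + 1L & !(i == 1L & j == n)
    }),
    arr.ind = TRUE
  )
  if (nrow(pairs) == 0L) return(TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  d1 <- cross(x[i], y[i], x2[i], y2[i], x[j], y[j])
  d2 <- cross(x[i], y[i], x2[i], y2[i], x2[j], y2[j])
  d3 <- cross(x[j], y[j], x2[j], y2[j], x[i], y[i])
  d4 <- cross(x[j], y[j], x2[j], y2[j], x2[i], y2[i])
  proper <- (sign(d1) * sign(d2) < 0) & (sign(d3) * sign(d4) < 0)
  # collinear overlap or endpoint touching also breaks simplicity
  touch <- (d1 == 0 & on_segment(x[i], y[i], x2[i], y2[i], x[j], y[j])) |
    (d2 == 0 & on_segment(x[i], y[i], x2[i], y2[i], x2[j], y2[j])) |
    (d3 == 0 & on_segment(x[j], y[j], x2[j], y2[j], x[i], y[i])) |
    (d4 == 0 & on_segment(x[j], y[j], x2[j], y2[j], x2[i], y2[i]))
  !any(proper | touch)
}

on_segment <- function(ax, ay, bx, by, px, py) {
  px >= pmin(ax, bx) & px <= pmax(ax, bx) &
    py >= pmin(ay, by) & py <= pmax(ay, by)
}

#' @export
print.cutout_shape <- function(x, ...) {
  bb <- c(range(x$vertices$x_cm), range(x$vertices$y_cm))
  cat(sprintf(
    "<cutout_shape> '%s': %d vertices, bbox [%.3g, %.3g] x [%.3g, %.3g] cm, P2A %.3g\n",
    x$label, nrow(x$vertices), bb[1], bb[2], bb[3], bb[4], p2a(x)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cutout_shape <- function(x, ...) {
  dplyr::mutate(x$vertices, label = x$label)
}

#' @exportS3Method generics::glance
glance.cutout_shape <- function(x, ...) {
  v <- x$vertices
  tibble::tibble(
    label = x$label, n_vertices = nrow(v),
    area_cm2 = abs(shoelace_area(v$x_cm, v$y_cm)),
    perimeter_cm = polygon_perimeter(v$x_cm, v$y_cm),
    p2a = p2a(x)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.cutout_shape <- function(object, ...) {
  ggplot2::ggplot(object$vertices, ggplot2::aes(.data$x_cm, .data$y_cm)) +
    ggplot2::geom_polygon(fill = "grey80", colour = "black") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)", title = object$label)
}

polygon_perimeter <- function(x, y) {
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

#' Shape complexity: perimeter squared over area (P2A)
#'
#' Dimensionless complexity measure of the aperture outline,
#' \eqn{P^2/A}: 16 for a square, \eqn{4\pi \approx 12.57} for a circle
#' (its minimum over all simple closed curves, by the isoperimetric
#' inequality), and large for narrow or ragged cutouts. Invariant under
#' rigid motions and uniform scaling.
#'
#' @param shape A [cutout_shape()] or a data frame of `x_cm`, `y_cm` vertices.
#' @return A single number `>= 4 * pi` (up to polygonal discretization).
#' @export
p2a <- function(shape) {
  if (!inherits(shape, "cutout_shape")) shape <- cutout_shape(shape)
  v <- shape$vertices
  polygon_perimeter(v$x_cm, v$y_cm)^2 / abs(shoelace_area(v$x_cm, v$y_cm))
}

#' Classify a cutout's relative-dosimetry reliability from its P2A
#'
#' Cutouts with complexity at or below the cutoff (default 30) are expected to
#' give accurate convolution-predicted relative output distributions
#' (gamma passing above typical clinical acceptance); more complex outlines
#' are flagged for caution because the shift-invariance assumption degrades
#' near ragged edges. The boundary is inclusive: `p2a == cutoff` is
#' `"reliable"`.
#'
#' @param p2a P2A value(s), each `>= 4 * pi`.
#' @param cutoff Reliability cutoff (default 30).
#' @return Character vector, `"reliable"` or `"caution"`.
#' @export
classify_complexity <- function(p2a, cutoff = 30) {
  stop_if_not_number(cutoff, "cutoff", positive = TRUE)
  if (!is.numeric(p2a) || anyNA(p2a) || any(!is.finite(p2a))) {
    abort("`p2a` must be finite.")
  }
  if (any(p2a < 4 * pi - 1e-9)) {
    abort("p2a below 4*pi is impossible for a simple polygon; check upstream computation.")
  }
  ifelse(p2a <= cutoff, "reliable", "caution")
}

#' Rasterize a cutout shape to a binary aperture mask
#'
#' Pixel centers lie on the `resolution_mm` lattice (integer multiples of the
#' pixel pitch in each coordinate); a pixel is open (1) iff its center is
#' inside the polygon by the even-odd rule, with the standard half-open
#' boundary convention (a center exactly on a left/bottom edge is inside, on a
#' right/top edge outside), so whole-pixel translations of the polygon
#' translate the mask identically. The grid covers the polygon bounding box
#' plus `padding_cm` of blocked margin on every side; pad by at least the
#' kernel support radius before [compute_cof_map()].
#'
#' @param shape A [cutout_shape()].
#' @param resolution_mm Pixel pitch in mm.
#' @param padding_cm Blocked margin around the bounding box, cm.
#' @return An `aperture_mask`: integer 0/1 matrix plus geometry. Rows index y
#'   (increasing), columns x; `origin` is the (x, y) of the center of pixel
#'   `[1, 1]` in cm.
#' @export
rasterize <- function(shape, resolution_mm = 1, padding_cm = 0) {
  stopifnot(inherits(shape, "cutout_shape"))
  stop_if_not_number(resolution_mm, "resolution_mm", positive = TRUE)
  stop_if_not_number(padding_cm, "padding_cm", nonneg = TRUE)
  res_cm <- resolution_mm / 10
  v <- shape$vertices

  ix0 <- floor((min(v$x_cm) - padding_cm) / res_cm)
  ix1 <- ceiling((max(v$x_cm) + padding_cm) / res_cm)
  iy0 <- floor((min(v$y_cm) - padding_cm) / res_cm)
  iy1 <- ceiling((max(v$y_cm) + padding_cm) / res_cm)
  xs <- (ix0:ix1) * res_cm
  ys <- (iy0:iy1) * res_cm

  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  inside <- point_in_polygon(px, py, v$x_cm, v$y_cm)
  values <- matrix(as.integer(inside), nrow = length(ys), ncol = length(xs))

  structure(
    list(values = values, resolution_mm = resolution_mm,
         origin = c(x_cm = xs[1], y_cm = ys[1]), label = shape$label),
    class = "aperture_mask"
  )
}

# even-odd crossing test, half-open rule: edges crossed when
# (y1 > p) != (y2 > p) and the point is strictly left of the intersection.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- (vy[i] > py) != (vy[j] > py)
    if (any(crosses)) {
      xint <- vx[i] + (py - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside
}

#' @export
print.aperture_mask <- function(x, ...) {
  cat(sprintf(
    "<aperture_mask> '%s': %dx%d px @ %g mm, %d open (%.3g cm^2), origin (%g, %g) cm\n",
    x$label, nrow(x$values), ncol(x$values), x$resolution_mm,
    sum(x$values), sum(x$values) * (x$resolution_mm / 10)^2,
    x$origin[1], x$origin[2]
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.aperture_mask <- function(x, ...) {
  grid_tidy(x$values, x$resolution_mm, x$origin, "open")
}

#' @exportS3Method generics::glance
glance.aperture_mask <- function(x, ...) {
  tibble::tibble(
    label = x$label, n_row = nrow(x$values), n_col = ncol(x$values),
    resolution_mm = x$resolution_mm, n_open = sum(x$values),
    open_area_cm2 = sum(x$values) * (x$resolution_mm / 10)^2
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.aperture_mask <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$x_cm, .data$y_cm,
                               fill = factor(.data$open))) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey20", `1` = "white")) +
    ggplot2::labs(x = "x (cm)", y = "y (cm)", fill = "open",
                  title = object$label)
}
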