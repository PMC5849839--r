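# All files share one plain-text dialect: `# key=value` header lines followed
# by CSV. Numbers are written with 17 significant digits so write -> read
# round-trips bit-exactly.

fmt_num <- function(x) sprintf("%.17g", x)

write_header <- function(con, keys) {
  for (k in names(keys)) writeLines(sprintf("# %s=%s", k, keys[[k]]), con)
}

read_keyed_file <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  keys <- list()
  for (h in lines[hdr_idx]) {
    body <- sub("^#\\s*", "", h)
    eq <- regexpr("=", body, fixed = TRUE)
    if (eq > 0) {
      keys[[substr(body, 1, eq - 1)]] <- substr(body, eq + 1, nchar(body))
    }
  }
  list(keys = keys, body = lines[setdiff(seq_along(lines), hdr_idx)])
}

key_num <- function(keys, name) {
  if (is.null(keys[[name]])) abort(sprintf("missing header key `%s`.", name))
  as.numeric(keys[[name]])
}

parse_csv_matrix <- function(body) {
  rows <- strsplit(body[nzchar(body)], ",", fixed = TRUE)
  n <- lengths(rows)
  if (length(unique(n)) != 1L) abort("ragged grid rows in file.")
  matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
}

#' Read and write output-factor curve files
#'
#' The curve file carries `# energy=...`, `# ssd_cm=...` header lines
#' followed by `radius_cm,output_factor` rows. The reader validates strictly
#' increasing radii via [of_curve()].
#'
#' @param curve An [of_curve()].
#' @param path File path.
#' @param interpolation Interpolant for the re-fitted curve; default taken
#'   from the file header (the writer records it).
#' @return `read_of_curve()` returns an [of_curve()]; `write_of_curve()`
#'   returns `path` invisibly.
#' @export
write_of_curve <- function(curve, path) {
  stopifnot(inherits(curve, "of_curve"))
  con <- file(path, "w"); on.exit(close(con))
  write_header(con, list(energy = curve$energy, ssd_cm = fmt_num(curve$ssd_cm),
                         interpolation = curve$interpolation))
  writeLines("radius_cm,output_factor", con)
  writeLines(paste(fmt_num(curve$samples$radius_cm),
                   fmt_num(curve$samples$output_factor), sep = ","), con)
  invisible(path)
}

#' @rdname write_of_curve
#' @export
read_of_curve <- function(path, interpolation = NULL) {
  f <- read_keyed_file(path)
  body <- f$body[nzchar(f$body)]
  if (!identical(body[1], "radius_cm,output_factor")) {
    abort("curve file must start with a `radius_cm,output_factor` column header.")
  }
  m <- parse_csv_matrix(body[-1])
  of_curve(
    tibble::tibble(radius_cm = m[, 1], output_factor = m[, 2]),
    energy = f$keys$energy %||% "beam",
    ssd_cm = key_num(f$keys, "ssd_cm"),
    interpolation = interpolation %||% f$keys$interpolation %||% "monotone_cubic"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write cutout shape (polygon) files
#'
#' One vertex per `x_cm,y_cm` row; closure is implicit; `#` lines are
#' comments (the writer records the label).
#'
#' @param shape A [cutout_shape()].
#' @param path File path.
#' @return `read_cutout_shape()` returns a [cutout_shape()].
#' @export
write_cutout_shape <- function(shape, path) {
  stopifnot(inherits(shape, "cutout_shape"))
  con <- file(path, "w"); on.exit(close(con))
  write_header(con, list(label = shape$label))
  writeLines("x_cm,y_cm", con)
  writeLines(paste(fmt_num(shape$vertices$x_cm),
                   fmt_num(shape$vertices$y_cm), sep = ","), con)
  invisible(path)
}

#' @rdname write_cutout_shape
#' @export
read_cutout_shape <- function(path) {
  f <- read_keyed_file(path)
  body <- f$body[nzchar(f$body)]
  if (identical(body[1], "x_cm,y_cm")) body <- body[-1]
  m <- parse_csv_matrix(body)
  cutout_shape(tibble::tibble(x_cm = m[, 1], y_cm = m[, 2]),
               label = f$keys$label %||% "cutout")
}

grid_keys <- function(type, obj, extra = list()) {
  c(list(type = type, resolution_mm = fmt_num(obj$resolution_mm)), extra)
}

write_grid_body <- function(con, values) {
  writeLines(apply(values, 1, function(r) paste(fmt_num(r), collapse = ",")),
             con)
}

#' Read and write grid files (kernel, aperture mask, COF map, planar field)
#'
#' Dense CSV grids preceded by `# key=value` geometry headers; one dialect
#' for all grid-valued objects, round-tripping bit-exactly.
#'
#' @param kernel,mask,map,dist The object to write.
#' @param path File path.
#' @return Readers return the corresponding object; writers return `path`
#'   invisibly.
#' @name grid_io
NULL

#' @rdname grid_io
#' @export
write_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "of_kernel"))
  con <- file(path, "w"); on.exit(close(con))
  write_header(con, grid_keys("kernel", kernel, list(
    delta_r_mm = fmt_num(kernel$delta_r_mm),
    center_row = kernel$center_index[["row"]],
    center_col = kernel$center_index[["col"]],
    max_radius_cm = fmt_num(kernel$max_radius_cm),
    energy = kernel$energy, ssd_cm = fmt_num(kernel$ssd_cm),
    negative_aof = tolower(isTRUE(kernel$negative_aof))
  )))
  write_grid_body(con, kernel$values)
  invisible(path)
}

#' @rdname grid_io
#' @export
read_kernel <- function(path) {
  f <- read_keyed_file(path)
  structure(
    list(
      values = parse_csv_matrix(f$body),
      resolution_mm = key_num(f$keys, "resolution_mm"),
      delta_r_mm = key_num(f$keys, "delta_r_mm"),
      center_index = c(row = as.integer(key_num(f$keys, "center_row")),
                       col = as.integer(key_num(f$keys, "center_col"))),
      max_radius_cm = key_num(f$keys, "max_radius_cm"),
      energy = f$keys$energy %||% "beam",
      ssd_cm = key_num(f$keys, "ssd_cm"),
      negative_aof = identical(f$keys$negative_aof, "true")
    ),
    class = "of_kernel"
  )
}

#' @rdname grid_io
#' @export
write_aperture_mask <- function(mask, path) {
  stopifnot(inherits(mask, "aperture_mask"))
  con <- file(path, "w"); on.exit(close(con))
  write_header(con, grid_keys("mask", mask, list(
    origin_x_cm = fmt_num(mask$origin[["x_cm"]]),
    origin_y_cm = fmt_num(mask$origin[["y_cm"]]),
    label = mask$label
  )))
  write_grid_body(con, mask$values)
  invisible(path)
}

#' @rdname grid_io
#' @export
read_aperture_mask <- function(path) {
  f <- read_keyed_file(path)
  v <- parse_csv_matrix(f$body)
  if (!all(v %in% c(0, 1))) abort("mask values must be 0/1.")
  storage.mode(v) <- "integer"
  structure(
    list(values = v, resolution_mm = key_num(f$keys, "resolution_mm"),
         origin = c(x_cm = key_num(f$keys, "origin_x_cm"),
                    y_cm = key_num(f$keys, "origin_y_cm")),
         label = f$keys$label %||% "cutout"),
    class = "aperture_mask"
  )
}

#' @rdname grid_io
#' @export
write_cof_map <- function(map, path) {
  stopifnot(inherits(map, "cof_map"))
  con <- file(path, "w"); on.exit(close(con))
  write_header(con, grid_keys("cof_map", map, list(
    origin_x_cm = fmt_num(map$origin[["x_cm"]]),
    origin_y_cm = fmt_num(map$origin[["y_cm"]]),
    energy = map$energy, ssd_cm = fmt_num(map$ssd_cm), label = map$label
  )))
  write_grid_body(con, map$values)
  invisible(path)
}

#' @rdname grid_io
#' @export
read_cof_map <- function(path) {
  f <- read_keyed_file(path)
  structure(
    list(values = parse_csv_matrix(f$body),
         resolution_mm = key_num(f$keys, "resolution_mm"),
         origin = c(x_cm = key_num(f$keys, "origin_x_cm"),
                    y_cm = key_num(f$keys, "origin_y_cm")),
         energy = f$keys$energy %||% "beam",
         ssd_cm = key_num(f$keys, "ssd_cm"),
         label = f$keys$label %||% "cutout"),
    class = "cof_map"
  )
}

#' @rdname grid_io
#' @export
write_planar_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "planar_distribution"))
  con <- file(path, "w"); on.exit(close(con))
  write_header(con, grid_keys("planar", dist, list(
    origin_x_cm = fmt_num(dist$origin[["x_cm"]]),
    origin_y_cm = fmt_num(dist$origin[["y_cm"]])
  )))
  write_grid_body(con, dist$values)
  invisible(path)
}

#' @rdname grid_io
#' @export
read_planar_distribution <- function(path) {
  f <- read_keyed_file(path)
  planar_distribution(
    parse_csv_matrix(f$body),
    resolution_mm = key_num(f$keys, "resolution_mm"),
    origin = c(x_cm = key_num(f$keys, "origin_x_cm"),
               y_cm = key_num(f$keys, "origin_y_cm"))
  )
}
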