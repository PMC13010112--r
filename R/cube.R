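#' Raster time-series cube
#'
#' The carrier object passed between every stage of the pipeline: a
#' `(time, y, x)` numeric array with an 8-day composite calendar and a
#' validity mask. Composite `i` of a year is nominally dated
#' `doy = 8 * (i - 1) + 1`, mirroring 8-day satellite composites (46 per
#' year).
#'
#' @param values numeric array of dimension `(time, ny, nx)`.
#' @param calendar data.frame with columns `year`, `composite`, `doy`, one
#'   row per time step, composites strictly increasing within each year.
#' @param mask logical array of the same dimension as `values`; `TRUE`
#'   marks a valid cell. Defaults to `is.finite(values)`.
#' @param variable name of the physical quantity held in the cube.
#' @param units unit string (e.g. `"K"`, `"mm"`, `""`).
#'
#' @return an object of class `raster_cube`.
#' @export
raster_cube <- function(values, calendar, mask = NULL, variable = "value",
                        units = "") {
  if (length(dim(values)) != 3L) {
    stop("`values` must be a 3-D (time, y, x) array", call. = FALSE)
  }
  calendar <- as.data.frame(calendar)
  req <- c("year", "composite", "doy")
  if (!all(req %in% names(calendar))) {
    stop("`calendar` needs columns year, composite, doy", call. = FALSE)
  }
  if (nrow(calendar) != dim(values)[1L]) {
    stop("calendar length (", nrow(calendar),
         ") does not match time dimension (", dim(values)[1L], ")",
         call. = FALSE)
  }
  by_year <- split(calendar$composite, calendar$year)
  if (any(vapply(by_year, function(x) any(diff(x) <= 0), logical(1L)))) {
    stop("composites must be strictly increasing within a year",
         call. = FALSE)
  }
  if (is.null(mask)) mask <- is.finite(values)
  stopifnot(identical(dim(mask), dim(values)))
  structure(
    list(values = values, calendar = calendar, mask = mask,
         variable = variable, units = units),
    class = "raster_cube"
  )
}

#' @export
print.raster_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<raster_cube> %s [%s]  time=%d (years %d-%d)  grid=%dx%d  valid=%.1f%%\n",
    x$variable, x$units, d[1L], min(x$calendar$year), max(x$calendar$year),
    d[2L], d[3L], 100 * mean(x$mask)))
  invisible(x)
}

#' @export
dim.raster_cube <- function(x) dim(x$values)

#' Build the nominal 8-day composite calendar
#'
#' @param years integer vector of calendar years.
#' @param composites_per_year composites per year (default 46).
#' @return data.frame with `year`, `composite`, `doy` columns.
#' @export
composite_calendar <- function(years, composites_per_year = 46L) {
  data.frame(
    year = rep(years, each = composites_per_year),
    composite = rep(seq_len(composites_per_year), times = length(years)),
    doy = rep(8L * (seq_len(composites_per_year) - 1L) + 1L,
              times = length(years))
  )
}

#' Values of a cube as a (time x pixel) matrix
#'
#' Pixels are ordered column-major over the `(y, x)` grid; masked cells are
#' returned as `NA`.
#'
#' @param cube a [raster_cube].
#' @return numeric matrix, one column per pixel.
#' @export
cube_matrix <- function(cube) {
  d <- dim(cube$values)
  m <- matrix(cube$values, nrow = d[1L])
  m[!matrix(cube$mask, nrow = d[1L])] <- NA_real_
  m
}

#' Rebuild a cube from a (time x pixel) matrix
#'
#' Inverse of [cube_matrix()]: `NA` entries become masked cells.
#'
#' @param m numeric matrix, time in rows, pixels in columns.
#' @param template a [raster_cube] supplying grid shape and calendar.
#' @param variable,units metadata for the new cube.
#' @return a [raster_cube].
#' @export
matrix_to_cube <- function(m, template, variable = template$variable,
                           units = template$units) {
  d <- dim(template$values)
  stopifnot(nrow(m) == d[1L], ncol(m) == d[2L] * d[3L])
  raster_cube(array(m, dim = d), template$calendar,
              mask = array(is.finite(m), dim = d),
              variable = variable, units = units)
}

#' Write a raster cube to a plain-text directory
#'
#' Serialises a cube losslessly as three text files under `path/`:
#' `values.csv` (long format `t,j,i,value`, full double precision, masked
#' cells omitted), `calendar.csv`, and `meta.yaml` (dimensions, variable,
#' units). The format round-trips bit-for-bit through
#' [read_raster_cube()].
#'
#' @param cube a [raster_cube].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_raster_cube <- function(cube, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(cube$values)
  idx <- which(cube$mask)
  ai <- arrayInd(idx, d)
  dt <- data.table::data.table(
    t = ai[, 1L], j = ai[, 2L], i = ai[, 3L],
    # 17 significant digits: doubles survive the text round trip exactly
    value = sprintf("%.17g", cube$values[idx])
  )
  data.table::fwrite(dt, file.path(path, "values.csv"))
  data.table::fwrite(cube$calendar, file.path(path, "calendar.csv"))
  yaml::write_yaml(
    list(ntime = d[1L], ny = d[2L], nx = d[3L],
         variable = cube$variable, units = cube$units),
    file.path(path, "meta.yaml"))
  invisible(path)
}

#' Read a raster cube written by [write_raster_cube()]
#'
#' @param path directory containing `values.csv`, `calendar.csv`,
#'   `meta.yaml`.
#' @return a [raster_cube].
#' @export
read_raster_cube <- function(path) {
  need <- file.path(path, c("values.csv", "calendar.csv", "meta.yaml"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stop("cube directory ", path, " is missing: ",
         paste(basename(missing), collapse = ", "), call. = FALSE)
  }
  meta <- yaml::read_yaml(need[3L])
  cal <- as.data.frame(data.table::fread(need[2L]))
  if (nrow(cal) != meta$ntime) {
    stop("calendar/shape mismatch in ", path, call. = FALSE)
  }
  if (is.unsorted(order(cal$year, cal$composite))) {
    # defensive; fread preserves row order so this only fires on edited files
    warning("calendar rows out of order; reordering")
  }
  dt <- data.table::fread(need[1L])
  d <- c(meta$ntime, meta$ny, meta$nx)
  vals <- array(NA_real_, dim = d)
  vals[cbind(dt$t, dt$j, dt$i)] <- dt$value
  raster_cube(vals, cal, mask = array(is.finite(vals), dim = d),
              variable = meta$variable, units = meta$units)
}

#' Yearly layer stack
#'
#' Lightweight container for one value per pixel per year (the output of
#' growing-season aggregation and phenology extraction): a
#' `(year, y, x)` array plus the year vector.
#'
#' @param values numeric array `(nyear, ny, nx)`.
#' @param years integer vector of years, one per layer.
#' @param variable,units metadata.
#' @return an object of class `year_stack`.
#' @export
year_stack <- function(values, years, variable = "value", units = "") {
  if (length(dim(values)) != 3L || dim(values)[1L] != length(years)) {
    stop("`values` must be (nyear, ny, nx) matching `years`", call. = FALSE)
  }
  structure(list(values = values, years = as.integer(years),
                 variable = variable, units = units),
            class = "year_stack")
}

#' @export
print.year_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<year_stack> %s [%s]  years %d-%d  grid=%dx%d\n",
              x$variable, x$units, min(x$years), max(x$years),
              d[2L], d[3L]))
  invisible(x)
}

#' Values of a year stack as a (year x pixel) matrix
#' @param ys a [year_stack].
#' @return numeric matrix, one column per pixel (column-major grid order).
#' @export
stack_matrix <- function(ys) matrix(ys$values, nrow = dim(ys$values)[1L])
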