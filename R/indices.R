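#' Enhanced vegetation index (EVI)
#'
#' `EVI = 2.5 (NIR - Red) / (NIR + 6 Red - 7.5 Blue + 1)`, computed from
#' reflectance bands 1 (red), 2 (NIR) and 3 (blue) and clipped to the
#' index's physical dynamic range `[-0.3, 0.9]`.
#'
#' @param bands named list of [raster_cube] with elements `b1`, `b2`, `b3`
#'   (red, NIR, blue reflectance in `[0, 1]`).
#' @return EVI [raster_cube].
#' @export
compute_evi <- function(bands) {
  need <- c("b1", "b2", "b3")
  if (!all(need %in% names(bands))) {
    stop("input error: bands b1 (red), b2 (NIR), b3 (blue) required",
         call. = FALSE)
  }
  red <- bands$b1$values; nir <- bands$b2$values; blue <- bands$b3$values
  evi <- 2.5 * (nir - red) / (nir + 6 * red - 7.5 * blue + 1)
  evi <- pmin(pmax(evi, -0.3), 0.9)
  mask <- bands$b1$mask & bands$b2$mask & bands$b3$mask & is.finite(evi)
  evi[!mask] <- NA_real_
  raster_cube(evi, bands$b1$calendar, mask = mask,
              variable = "EVI", units = "")
}

#' Modified soil-adjusted vegetation index (MSAVI)
#'
#' `MSAVI = (2 NIR + 1 - sqrt((2 NIR + 1)^2 - 8 (NIR - Red))) / 2`. The
#' discriminant is non-negative for reflectances in `[0, 1]`. Clipped to
#' `[-0.3, 0.9]` like EVI.
#'
#' @param bands named list of [raster_cube] with `b1` (red) and `b2` (NIR).
#' @return MSAVI [raster_cube].
#' @export
compute_msavi <- function(bands) {
  if (!all(c("b1", "b2") %in% names(bands))) {
    stop("input error: bands b1 (red) and b2 (NIR) required", call. = FALSE)
  }
  red <- bands$b1$values; nir <- bands$b2$values
  disc <- (2 * nir + 1)^2 - 8 * (nir - red)
  msavi <- (2 * nir + 1 - sqrt(pmax(disc, 0))) / 2
  msavi <- pmin(pmax(msavi, -0.3), 0.9)
  mask <- bands$b1$mask & bands$b2$mask & is.finite(msavi)
  msavi[!mask] <- NA_real_
  raster_cube(msavi, bands$b1$calendar, mask = mask,
              variable = "MSAVI", units = "")
}

#' Remove snow contamination from a vegetation-index cube
#'
#' Snow collapses winter index values far below the pixel's dormant-season
#' background. Per pixel, the background is a configurable percentile of
#' its winter composites; winter values below the background are raised to
#' it. Summer composites are never touched, and the operation is
#' idempotent.
#'
#' @param cube a vegetation-index [raster_cube].
#' @param winter_doy `c(last_spring_doy, first_autumn_doy)`: composites
#'   with nominal DOY `<=` the first or `>=` the second form the winter
#'   window (default `[1, 60]` and `[305, 366]`).
#' @param percentile background percentile of winter values (default 50).
#' @return corrected [raster_cube].
#' @export
remove_snow_contamination <- function(cube, winter_doy = c(60, 305),
                                      percentile = 50) {
  winter <- cube$calendar$doy <= winter_doy[1L] |
    cube$calendar$doy >= winter_doy[2L]
  if (!any(winter)) {
    stop("configuration error: empty winter window", call. = FALSE)
  }
  m <- cube_matrix(cube)
  w <- m[winter, , drop = FALSE]
  bg <- apply(w, 2L, stats::quantile, probs = percentile / 100,
              na.rm = TRUE, names = FALSE)
  # raise sub-background winter values to the background
  fix <- sweep(w, 2L, bg, `<`)
  w[which(fix)] <- rep(bg, each = nrow(w))[which(fix)]
  m[winter, ] <- w
  matrix_to_cube(m, cube)
}

# Central Savitzky-Golay coefficients (least-squares polynomial fit of
# order p over a window of n points, evaluated at the centre).
sg_center_coef <- function(n, p) {
  stopifnot(n %% 2L == 1L, p < n)
  h <- (n - 1L) %/% 2L
  A <- outer(-h:h, 0:p, `^`)
  (A %*% solve(crossprod(A), diag(p + 1L)[, 1L]))[, 1L]
}

#' Savitzky-Golay smoothing of a raster cube
#'
#' Per-pixel local least-squares polynomial smoothing along the time axis.
#' Edges are handled by mirror padding so the filter stays the central
#' (symmetric) one throughout. Gaps (masked composites) are linearly
#' interpolated before filtering and re-masked afterwards.
#'
#' @param cube a [raster_cube].
#' @param window odd window length in composites (default 7).
#' @param polyorder polynomial order, `< window` (default 2).
#' @return smoothed [raster_cube].
#' @export
savitzky_golay_smooth <- function(cube, window = 7L, polyorder = 2L) {
  nt <- dim(cube$values)[1L]
  if (window %% 2L != 1L) stop("input error: window must be odd",
                               call. = FALSE)
  if (polyorder >= window) stop("input error: polyorder must be < window",
                                call. = FALSE)
  if (window >= nt) stop("input error: window exceeds series length",
                         call. = FALSE)
  coef <- sg_center_coef(as.integer(window), as.integer(polyorder))
  h <- (window - 1L) %/% 2L
  m <- cube_matrix(cube)
  sm <- apply(m, 2L, function(x) {
    ok <- is.finite(x)
    if (sum(ok) < window) return(rep(NA_real_, nt))
    if (!all(ok)) {
      x <- stats::approx(which(ok), x[ok], xout = seq_len(nt),
                         rule = 2L)$y
    }
    xp <- c(x[(h + 1L):2L], x, x[(nt - 1L):(nt - h)])  # mirror padding
    out <- stats::filter(xp, coef, sides = 2L)
    as.numeric(out[(h + 1L):(h + nt)])
  })
  sm[!matrix(cube$mask, nt)] <- NA_real_  # masked cells stay masked
  matrix_to_cube(sm, cube)
}

# Composite selector for the May 1 - Oct 31 growing season (nominal DOY).
growing_season_composites <- function(calendar, doy_range = c(121, 304)) {
  calendar$doy >= doy_range[1L] & calendar$doy <= doy_range[2L]
}

#' Growing-season yearly mean of a cube
#'
#' One value per pixel per year: the mean over composites whose nominal
#' day-of-year falls in the May-October growing season (DOY 121-304, 23 of
#' 46 composites). A pixel-year with fewer than half of the window's
#' composites valid is masked.
#'
#' @param cube a [raster_cube].
#' @param doy_range growing-season DOY window (default `c(121, 304)`).
#' @param statistic `"mean"` (default) or `"sum"` (for fluxes such as
#'   precipitation).
#' @param min_valid_frac minimum fraction of valid in-window composites
#'   (default 0.5).
#' @return a [year_stack] of yearly values.
#' @export
growing_season_mean <- function(cube, doy_range = c(121, 304),
                                statistic = c("mean", "sum"),
                                min_valid_frac = 0.5) {
  statistic <- match.arg(statistic)
  inwin <- growing_season_composites(cube$calendar, doy_range)
  if (!any(inwin)) stop("calendar does not cover the growing-season window",
                        call. = FALSE)
  years <- sort(unique(cube$calendar$year))
  m <- cube_matrix(cube)
  d <- dim(cube$values)
  out <- matrix(NA_real_, length(years), d[2L] * d[3L])
  fun <- if (statistic == "mean") {
    function(x) mean(x, na.rm = TRUE)
  } else {
    function(x) sum(x, na.rm = TRUE)
  }
  for (k in seq_along(years)) {
    rows <- inwin & cube$calendar$year == years[k]
    sub <- m[rows, , drop = FALSE]
    nvalid <- colSums(is.finite(sub))
    v <- apply(sub, 2L, fun)
    v[nvalid < min_valid_frac * sum(rows)] <- NA_real_
    out[k, ] <- v
  }
  year_stack(array(out, dim = c(length(years), d[2L], d[3L])), years,
             variable = paste0("GS_", statistic, "_", cube$variable),
             units = cube$units)
}
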