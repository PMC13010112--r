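#' Growing-season effective moisture (GEM)
#'
#' `GEM = (GPRE - GET) / GPRE`, the fraction of growing-season
#' precipitation not returned by evapotranspiration. Values near 1 mean
#' good moisture conditions, near 0 poor ones. Pixels with zero
#' precipitation are masked; negative results (ET exceeding precipitation)
#' are clamped to 0 and flagged, keeping the index inside `[0, 1]` for the
#' downstream binned analyses.
#'
#' @param gpre growing-season precipitation [year_stack] (mm, `>= 0`).
#' @param get growing-season evapotranspiration [year_stack] (mm, `>= 0`).
#' @return a [year_stack] of GEM with attribute `clamped` (logical array
#'   marking clamped cells).
#' @export
compute_gem <- function(gpre, get) {
  if (!identical(dim(gpre$values), dim(get$values))) {
    stop("input error: GPRE and GET grids do not match", call. = FALSE)
  }
  p <- gpre$values; e <- get$values
  if (any(p < 0, na.rm = TRUE) || any(e < 0, na.rm = TRUE)) {
    stop("input error: GPRE and GET must be non-negative", call. = FALSE)
  }
  gem <- (p - e) / p
  gem[p == 0] <- NA_real_
  clamped <- !is.na(gem) & gem < 0
  gem[clamped] <- 0
  out <- year_stack(gem, gpre$years, variable = "GEM", units = "")
  attr(out, "clamped") <- clamped
  out
}

# fixed narrowband-to-broadband weights, bands 1-5 and 7
ALBEDO_COEF <- c(b1 = 0.160, b2 = 0.291, b3 = 0.243, b4 = 0.116,
                 b5 = 0.112, b7 = 0.081)
ALBEDO_OFFSET <- -0.0015

#' Shortwave broadband albedo from reflectance bands
#'
#' Narrowband-to-broadband conversion
#' `B_short = 0.160 B1 + 0.291 B2 + 0.243 B3 + 0.116 B4 + 0.112 B5 +
#' 0.081 B7 - 0.0015`, clamped to `[0, 1]` with out-of-range cells
#' flagged.
#'
#' @param bands named list of [raster_cube] containing `b1`-`b5` and `b7`
#'   (reflectance in `[0, 1]`).
#' @return albedo [raster_cube] with attribute `clamped`.
#' @export
compute_shortwave_albedo <- function(bands) {
  need <- names(ALBEDO_COEF)
  if (!all(need %in% names(bands))) {
    stop("input error: bands ", paste(setdiff(need, names(bands)),
                                      collapse = ", "),
         " missing", call. = FALSE)
  }
  alb <- ALBEDO_OFFSET
  for (b in need) alb <- alb + ALBEDO_COEF[[b]] * bands[[b]]$values
  clamped <- alb < 0 | alb > 1
  alb <- pmin(pmax(alb, 0), 1)
  mask <- Reduce(`&`, lapply(bands[need], `[[`, "mask")) & is.finite(alb)
  alb[!mask] <- NA_real_
  out <- raster_cube(alb, bands$b1$calendar, mask = mask,
                     variable = "shortwave_albedo", units = "")
  attr(out, "clamped") <- clamped & mask
  out
}

#' Growing-season aggregate of a driver cube
#'
#' Per-pixel yearly aggregate (mean by default, sum for fluxes) over
#' May-October composites; the generic step that produces GLST, GSA, GPRE,
#' GET and the growing-season means of any auxiliary driver (air
#' temperature, sunshine duration, wind speed, grazing intensity). For
#' land-surface temperature, day and night cubes are averaged cell-wise
#' first when both are supplied.
#'
#' @param cube a [raster_cube]; or the day-time LST cube when `night` is
#'   given.
#' @param night optional night-time companion cube, averaged with `cube`.
#' @param statistic `"mean"` or `"sum"`.
#' @param doy_range growing-season DOY window (default May 1 - Oct 31).
#' @return a [year_stack].
#' @export
growing_season_aggregate <- function(cube, night = NULL,
                                     statistic = c("mean", "sum"),
                                     doy_range = c(121, 304)) {
  statistic <- match.arg(statistic)
  if (!is.null(night)) {
    if (!identical(dim(night$values), dim(cube$values))) {
      stop("input error: day and night cubes do not match", call. = FALSE)
    }
    vals <- (cube$values + night$values) / 2
    cube <- raster_cube(vals, cube$calendar,
                        mask = cube$mask & night$mask,
                        variable = cube$variable, units = cube$units)
  }
  growing_season_mean(cube, doy_range = doy_range, statistic = statistic)
}
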