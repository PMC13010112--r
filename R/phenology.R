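#' Dynamic-threshold phenology extraction
#'
#' Per pixel and year, normalises the smoothed vegetation-index series to
#' its seasonal amplitude, `r(t) = (VI(t) - VI_min) / (VI_max - VI_min)`,
#' and finds the day the ratio crosses `theta`: the last upward crossing
#' before the seasonal maximum (SOS) or the first downward crossing after
#' it (EOS), linearly interpolated between composite nominal dates. Each
#' year's window carries a margin of composites from the adjacent years so
#' the min/max estimate is stable at year edges. Pixels with seasonal
#' amplitude below `amplitude_floor` (no real cycle, e.g. desert) or no
#' crossing are flagged undefined (`NA`).
#'
#' @param cube smoothed vegetation-index [raster_cube] (MSAVI for SOS,
#'   EVI for EOS).
#' @param theta threshold fraction in (0, 1); default 0.2, common
#'   land-surface-phenology practice.
#' @param limb `"sos"` (green-up) or `"eos"` (senescence).
#' @param amplitude_floor minimum seasonal amplitude (index units) to
#'   declare a cycle (default 0.05).
#' @param margin composites borrowed from each adjacent year (default 3).
#' @param min_valid_frac minimum fraction of valid composites in the
#'   window (default 0.8).
#' @return a [year_stack] of real-valued day-of-year (NA = undefined).
#' @export
extract_phenology <- function(cube, theta = 0.2, limb = c("sos", "eos"),
                              amplitude_floor = 0.05, margin = 3L,
                              min_valid_frac = 0.8) {
  limb <- match.arg(limb)
  if (theta <= 0 || theta >= 1) {
    stop("configuration error: theta must lie in (0, 1)", call. = FALSE)
  }
  cal <- cube$calendar
  years <- sort(unique(cal$year))
  m <- cube_matrix(cube)
  d <- dim(cube$values)
  npx <- d[2L] * d[3L]
  out <- matrix(NA_real_, length(years), npx)

  for (k in seq_along(years)) {
    yr <- years[k]
    in_year <- which(cal$year == yr)
    pre <- utils::tail(which(cal$year == yr - 1L), margin)
    post <- utils::head(which(cal$year == yr + 1L), margin)
    rows <- c(pre, in_year, post)
    day <- cal$doy[rows] + 365 * (cal$year[rows] - yr)
    v <- m[rows, , drop = FALSE]
    nwin <- length(rows)
    valid_frac <- colSums(is.finite(v)) / nwin
    vmin <- suppressWarnings(apply(v, 2L, min, na.rm = TRUE))
    vmax <- suppressWarnings(apply(v, 2L, max, na.rm = TRUE))
    amp <- vmax - vmin
    ok <- is.finite(amp) & amp >= amplitude_floor &
      valid_frac >= min_valid_frac
    if (!any(ok)) next
    r <- sweep(sweep(v, 2L, vmin, `-`), 2L, amp, `/`)
    ipk <- apply(r, 2L, function(x) {
      if (all(!is.finite(x))) NA_integer_ else which.max(x)
    })
    res <- rep(NA_real_, npx)
    for (j in which(ok)) {
      rj <- r[, j]
      p <- ipk[j]
      if (!is.finite(p)) next
      if (limb == "sos") {
        if (p < 2L) next
        i <- seq_len(p - 1L)
        cross <- i[rj[i] < theta & rj[i + 1L] >= theta &
                     is.finite(rj[i]) & is.finite(rj[i + 1L])]
        if (!length(cross)) next
        cidx <- cross[length(cross)]   # last upward crossing before peak
      } else {
        if (p > nwin - 1L) next
        i <- p:(nwin - 1L)
        cross <- i[rj[i] >= theta & rj[i + 1L] < theta &
                     is.finite(rj[i]) & is.finite(rj[i + 1L])]
        if (!length(cross)) next
        cidx <- cross[1L]              # first downward crossing after peak
      }
      frac <- (theta - rj[cidx]) / (rj[cidx + 1L] - rj[cidx])
      res[j] <- day[cidx] + frac * (day[cidx + 1L] - day[cidx])
    }
    res[!is.na(res) & (res < 1 | res > 366)] <- NA_real_
    out[k, ] <- res
  }
  year_stack(array(out, dim = c(length(years), d[2L], d[3L])), years,
             variable = toupper(limb), units = "DOY")
}

#' Start of growing season from MSAVI
#'
#' Convenience wrapper: [extract_phenology()] on the green-up limb.
#' @inheritParams extract_phenology
#' @param ... passed to [extract_phenology()].
#' @return a [year_stack] of SOS day-of-year.
#' @export
extract_sos <- function(cube, theta = 0.2, ...) {
  extract_phenology(cube, theta = theta, limb = "sos", ...)
}

#' End of growing season from EVI
#'
#' Convenience wrapper: [extract_phenology()] on the senescence limb.
#' @inheritParams extract_phenology
#' @param ... passed to [extract_phenology()].
#' @return a [year_stack] of EOS day-of-year.
#' @export
extract_eos <- function(cube, theta = 0.2, ...) {
  extract_phenology(cube, theta = theta, limb = "eos", ...)
}

#' Growing-season length
#'
#' `LOS = EOS - SOS`, per pixel per year; undefined wherever either input
#' is undefined.
#'
#' @param sos,eos [year_stack] objects on the same grid and years.
#' @return a [year_stack] of LOS in days.
#' @export
compute_los <- function(sos, eos) {
  if (!identical(dim(sos$values), dim(eos$values)) ||
      !identical(sos$years, eos$years)) {
    stop("input error: SOS and EOS grids/years do not match", call. = FALSE)
  }
  year_stack(eos$values - sos$values, sos$years,
             variable = "LOS", units = "days")
}

# month index (1-12) from day-of-year, non-leap convention, Jan 1 = 1
doy_to_month <- function(doy) {
  edges <- c(0, 31, 59, 90, 120, 151, 181, 212, 243, 273, 304, 334, 366)
  findInterval(doy, edges, left.open = TRUE, rightmost.closed = TRUE)
}

#' Area-share summary of a phenology metric
#'
#' Averages each pixel over years, bins the multi-year means, and reports
#' the percentage of defined pixels per bin: month bins for SOS/EOS
#' (day-of-year input) or day-interval bins for LOS. Optionally stratified
#' by a categorical raster (land cover or basin).
#'
#' @param ph a [year_stack] (SOS/EOS in DOY, or LOS in days).
#' @param class_edges numeric bin edges. Default: month boundaries for DOY
#'   variables; `c(0, 60, 90, 120, 150, 180, Inf)` for LOS.
#' @param labels optional bin labels (defaults to month names / interval
#'   strings).
#' @param zones optional `ny x nx` categorical matrix; shares are reported
#'   per zone.
#' @return data.frame with columns `zone` (if given), `bin`, `n`,
#'   `share_pct`; shares sum to 100 within each zone.
#' @export
phenology_summary <- function(ph, class_edges = NULL, labels = NULL,
                              zones = NULL) {
  if (dim(ph$values)[1L] < 1L) stop("empty input", call. = FALSE)
  mu <- colMeans(stack_matrix(ph), na.rm = TRUE)
  mu[!is.finite(mu)] <- NA_real_
  if (is.null(class_edges)) {
    if (identical(ph$variable, "LOS")) {
      class_edges <- c(0, 60, 90, 120, 150, 180, Inf)
    } else {
      class_edges <- c(0, 31, 59, 90, 120, 151, 181, 212, 243, 273, 304,
                       334, 366)
      if (is.null(labels)) labels <- month.abb
    }
  }
  if (is.null(labels)) {
    labels <- paste0("[", utils::head(class_edges, -1L), ",",
                     utils::tail(class_edges, -1L), ")")
  }
  bin <- findInterval(mu, class_edges, left.open = TRUE,
                      rightmost.closed = TRUE)
  zone <- if (is.null(zones)) rep("all", length(mu)) else as.character(zones)
  keep <- !is.na(mu)
  df <- do.call(rbind, lapply(split(bin[keep], zone[keep]), function(b) {
    tab <- tabulate(b, nbins = length(labels))
    data.frame(bin = labels, n = tab, share_pct = 100 * tab / sum(tab))
  }))
  df$zone <- rep(names(split(bin[keep], zone[keep])),
                 each = length(labels))
  rownames(df) <- NULL
  df[, c("zone", "bin", "n", "share_pct")]
}
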