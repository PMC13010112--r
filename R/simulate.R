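#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults mirror the
#' study conditions the pipeline is aimed at: a 20-year record of 8-day
#' composites (46 per year, 2001-2020), a double-logistic seasonal
#' vegetation cycle with green-up near DOY 150 and senescence near DOY 280,
#' and injected interannual trends of +0.2205 d/a on EOS, -0.1102 d/a on
#' SOS and +0.268 K/a on growing-season land-surface temperature.
#'
#' @param grid_shape integer `(ny, nx)` pixel grid.
#' @param years number of simulated years (> 1).
#' @param start_year first calendar year.
#' @param composites_per_year composites per year (46 = 8-day).
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @param phenology list: `sos`, `eos` (scalar or `ny x nx` matrix of true
#'   transition DOYs in year 1), `sos_trend`, `eos_trend` (d/a),
#'   `amplitude`, `baseline` (EVI units), `rate_spring`, `rate_autumn`
#'   (logistic rates, 1/day), `theta` (dynamic-threshold fraction the truth
#'   is anchored to).
#' @param trend list of injected yearly slopes: `lst` (K/a), `pre` (mm/a per
#'   composite), `et` (mm/a per composite).
#' @param noise list: `vi_sd` (index units), `lst_sd` (K), `pre_sd`,
#'   `et_sd` (mm), `snow_prob` (winter dropout probability per composite),
#'   `winter_doy` = `c(last_spring_doy, first_autumn_doy)` delimiting the
#'   winter window.
#' @param climate list: `lst_mean` (K), `lst_seasonal_amp` (K),
#'   `pre_peak` (mm per composite at mid-summer), `et_ratio`
#'   (ET/precipitation, < 1 keeps effective moisture inside (0,1)).
#' @param strata list: `W` strata, `between_sd`, `within_sd` for the
#'   stratified driver-response construction.
#' @param hurst list: `H` target exponent(s) for fractional-Gaussian-noise
#'   series.
#'
#' @return object of class `sim_config`.
#' @export
sim_config <- function(grid_shape = c(10L, 10L),
                       years = 20L,
                       start_year = 2001L,
                       composites_per_year = 46L,
                       seed = 42L,
                       phenology = list(),
                       trend = list(),
                       noise = list(),
                       climate = list(),
                       strata = list(),
                       hurst = list()) {
  if (length(grid_shape) != 2L || any(grid_shape < 1L)) {
    stop("configuration error: grid_shape must be two positive integers",
         call. = FALSE)
  }
  if (years <= 1L) {
    stop("configuration error: years must exceed 1", call. = FALSE)
  }
  if (composites_per_year < 4L) {
    stop("configuration error: composites_per_year too small", call. = FALSE)
  }
  phenology <- utils::modifyList(list(
    sos = 150, eos = 280, sos_trend = -0.1102, eos_trend = 0.2205,
    amplitude = 0.45, baseline = 0.08,
    rate_spring = 0.10, rate_autumn = 0.10, theta = 0.2), phenology)
  trend <- utils::modifyList(list(lst = 0.268, pre = 0, et = 0), trend)
  noise <- utils::modifyList(list(
    vi_sd = 0, lst_sd = 0, pre_sd = 0, et_sd = 0,
    snow_prob = 0, winter_doy = c(60, 305)), noise)
  climate <- utils::modifyList(list(
    lst_mean = 278, lst_seasonal_amp = 12, pre_peak = 25,
    et_ratio = 0.45, lst_grad_y = 0, pre_grad_x = 0), climate)
  strata <- utils::modifyList(list(
    W = 5L, between_sd = 1, within_sd = 0.5), strata)
  hurst <- utils::modifyList(list(H = 0.8), hurst)
  if (climate$pre_peak < 0) {
    stop("configuration error: negative precipitation scale", call. = FALSE)
  }
  if (phenology$theta <= 0 || phenology$theta >= 1) {
    stop("configuration error: theta must lie in (0, 1)", call. = FALSE)
  }
  structure(list(
    grid_shape = as.integer(grid_shape), years = as.integer(years),
    start_year = as.integer(start_year),
    composites_per_year = as.integer(composites_per_year),
    seed = as.integer(seed), phenology = phenology, trend = trend,
    noise = noise, climate = climate, strata = strata, hurst = hurst),
    class = "sim_config")
}

#' Double-logistic seasonal curve
#'
#' `f(t) = baseline + amplitude * (1/(1+exp(-rs*(t-ts))) +
#' 1/(1+exp(ra*(t-te))) - 1)`: flat winter baseline, logistic green-up
#' centred at `ts`, logistic senescence centred at `te`.
#'
#' @param t day of year (vectorised).
#' @param ts,te spring / autumn midpoints (DOY).
#' @param rate_spring,rate_autumn logistic rates (1/day).
#' @param baseline,amplitude winter level and seasonal amplitude.
#' @return numeric vector of curve values.
#' @export
double_logistic <- function(t, ts, te, rate_spring = 0.10,
                            rate_autumn = 0.10, baseline = 0, amplitude = 1) {
  baseline + amplitude *
    (stats::plogis(rate_spring * (t - ts)) +
       stats::plogis(-rate_autumn * (t - te)) - 1)
}

#' Analytic dynamic-threshold crossing of a continuous seasonal curve
#'
#' Root-finds the day at which the amplitude-normalised curve
#' `r(t) = (f(t) - min f) / (max f - min f)` crosses `theta`: the last
#' upward crossing before the seasonal maximum (`limb = "sos"`) or the
#' first downward crossing after it (`limb = "eos"`). Used as the
#' independent oracle for the discrete extraction chain.
#'
#' @param f vectorised function of day-of-year.
#' @param theta threshold fraction in (0, 1).
#' @param limb `"sos"` or `"eos"`.
#' @param t_range search interval in days (default one year).
#' @return crossing day (numeric scalar), or `NA` if the curve never
#'   crosses.
#' @export
curve_threshold_crossing <- function(f, theta, limb = c("sos", "eos"),
                                     t_range = c(1, 366)) {
  limb <- match.arg(limb)
  grid <- seq(t_range[1L], t_range[2L], by = 0.25)
  v <- f(grid)
  vmin <- min(v); vmax <- max(v)
  if (vmax - vmin <= 0) return(NA_real_)
  r <- (v - vmin) / (vmax - vmin)
  ipk <- which.max(r)
  g <- function(t) (f(t) - vmin) / (vmax - vmin) - theta
  if (limb == "sos") {
    pre <- r[seq_len(ipk)]
    cross <- which(pre[-length(pre)] < theta & pre[-1L] >= theta)
    if (!length(cross)) return(NA_real_)
    k <- cross[length(cross)]  # last upward crossing before the maximum
    stats::uniroot(g, c(grid[k], grid[k + 1L]), tol = 1e-10)$root
  } else {
    post <- r[ipk:length(r)]
    cross <- which(post[-length(post)] >= theta & post[-1L] < theta)
    if (!length(cross)) return(NA_real_)
    k <- ipk - 1L + cross[1L]  # first downward crossing after the maximum
    stats::uniroot(g, c(grid[k], grid[k + 1L]), tol = 1e-10)$root
  }
}

# Invert the EVI formula for NIR with red/blue held fixed.
evi_to_nir <- function(evi, red, blue) {
  cc <- 6 * red - 7.5 * blue + 1
  pmin(pmax((2.5 * red + evi * cc) / (2.5 - evi), 1e-3), 1)
}

msavi_of <- function(nir, red) {
  (2 * nir + 1 - sqrt((2 * nir + 1)^2 - 8 * (nir - red))) / 2
}

# Midpoint offsets such that the continuous MSAVI curve crosses theta at the
# requested SOS and the continuous EVI curve crosses theta at the requested
# EOS. Solved once for a reference (sos, eos) pair; time-shift equivariance
# of the curve carries the offsets to every pixel (amplitude/baseline/rates
# are config scalars).
solve_midpoint_offsets <- function(ph, red = 0.05, blue = 0.03) {
  sos0 <- 150; eos0 <- 280
  if (ph$amplitude <= 0) {
    return(list(sos_offset = 0, eos_offset = 0, red = red, blue = blue))
  }
  off_s <- log(1 / ph$theta - 1) / ph$rate_spring
  off_e <- log(1 / ph$theta - 1) / ph$rate_autumn
  ts <- sos0 + off_s; te <- eos0 - off_e
  evi_curve <- function(t, ts, te) {
    double_logistic(t, ts, te, ph$rate_spring, ph$rate_autumn,
                    ph$baseline, ph$amplitude)
  }
  msavi_curve <- function(t, ts, te) {
    msavi_of(evi_to_nir(evi_curve(t, ts, te), red, blue), red)
  }
  for (iter in 1:3) {
    s_hat <- curve_threshold_crossing(
      function(t) msavi_curve(t, ts, te), ph$theta, "sos")
    e_hat <- curve_threshold_crossing(
      function(t) evi_curve(t, ts, te), ph$theta, "eos")
    ts <- ts + (sos0 - s_hat)
    te <- te + (eos0 - e_hat)
  }
  list(sos_offset = ts - sos0, eos_offset = te - eos0,
       red = red, blue = blue)
}

#' Simulate a seven-band surface-reflectance cube with known phenology
#'
#' Generates reflectance bands 1-7 (band 1 red, band 2 NIR, band 3 blue)
#' whose EVI/MSAVI seasonal cycles are double-logistic with the configured
#' dynamic-threshold crossings: per pixel and year, the continuous MSAVI
#' curve crosses `theta` on the green-up limb at `true_sos` and the
#' continuous EVI curve crosses it on the senescence limb at `true_eos`.
#' Winter composites are snow-contaminated (bright visible, depressed
#' index) with probability `noise$snow_prob`.
#'
#' @param config a [sim_config()].
#' @return list with `bands` (named list `b1`..`b7` of [raster_cube]) and
#'   `truth` (list: `true_sos`, `true_eos`, `true_los` as
#'   `(year, ny, nx)` arrays, plus generator parameters).
#' @export
simulate_reflectance_cube <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ph <- config$phenology
  ny <- config$grid_shape[1L]; nx <- config$grid_shape[2L]
  npx <- ny * nx
  cal <- composite_calendar(
    config$start_year + seq_len(config$years) - 1L,
    config$composites_per_year)
  nt <- nrow(cal)

  as_mat <- function(x) {
    if (length(x) == 1L) matrix(x, ny, nx) else {
      stopifnot(identical(dim(x), c(ny, nx))); x
    }
  }
  sos0 <- as_mat(ph$sos); eos0 <- as_mat(ph$eos)
  yi <- seq_len(config$years) - 1L
  true_sos <- outer(yi, c(sos0), function(y, s) s + ph$sos_trend * y)
  true_eos <- outer(yi, c(eos0), function(y, e) e + ph$eos_trend * y)
  if (any(true_sos <= 0 | true_sos >= true_eos | true_eos > 366)) {
    stop("configuration error: need 0 < SOS < EOS <= 366 everywhere",
         call. = FALSE)
  }
  dim(true_sos) <- c(config$years, ny, nx)
  dim(true_eos) <- c(config$years, ny, nx)

  off <- solve_midpoint_offsets(ph)
  set.seed(config$seed)

  # EVI in (time x pixel) layout, built year by year
  evi <- matrix(NA_real_, nt, npx)
  for (y in seq_len(config$years)) {
    rows <- which(cal$year == config$start_year + y - 1L)
    doy <- cal$doy[rows]
    ts <- matrix(true_sos[y, , ], 1L, npx) + off$sos_offset
    te <- matrix(true_eos[y, , ], 1L, npx) + off$eos_offset
    # outer over composites x pixels
    evi[rows, ] <- ph$baseline + ph$amplitude *
      (stats::plogis(ph$rate_spring * outer(doy, c(ts), "-")) +
         stats::plogis(-ph$rate_autumn * outer(doy, c(te), "-")) - 1)
  }
  if (ph$amplitude > 0 && config$noise$vi_sd > 0) {
    evi <- evi + stats::rnorm(length(evi), 0, config$noise$vi_sd)
  }

  red <- matrix(off$red, nt, npx)
  blue <- matrix(off$blue, nt, npx)
  nir <- evi_to_nir(evi, red, blue)
  b4 <- matrix(0.06, nt, npx); b5 <- matrix(0.12, nt, npx)
  b6 <- matrix(0.10, nt, npx); b7 <- matrix(0.10, nt, npx)

  wdoy <- config$noise$winter_doy
  winter <- cal$doy <= wdoy[1L] | cal$doy >= wdoy[2L]
  if (config$noise$snow_prob > 0) {
    snow <- matrix(FALSE, nt, npx)
    snow[winter, ] <- stats::runif(sum(winter) * npx) < config$noise$snow_prob
    red[snow] <- 0.60; blue[snow] <- 0.60; nir[snow] <- 0.55
    b4[snow] <- 0.60; b5[snow] <- 0.30; b7[snow] <- 0.25
  }

  mk <- function(m, name) {
    raster_cube(array(m, dim = c(nt, ny, nx)), cal, variable = name,
                units = "reflectance")
  }
  bands <- list(b1 = mk(red, "band1_red"), b2 = mk(nir, "band2_nir"),
                b3 = mk(blue, "band3_blue"), b4 = mk(b4, "band4"),
                b5 = mk(b5, "band5"), b6 = mk(b6, "band6"),
                b7 = mk(b7, "band7"))
  truth <- list(true_sos = true_sos, true_eos = true_eos,
                true_los = true_eos - true_sos,
                theta = ph$theta, params = ph,
                midpoint_offsets = off)
  list(bands = bands, truth = truth)
}

#' Simulate land-surface temperature, precipitation and evapotranspiration
#' cubes
#'
#' Each variable is a seasonal baseline plus an injected per-year linear
#' trend plus Gaussian noise. Evapotranspiration tracks precipitation via
#' `climate$et_ratio` (< 1) so the growing-season effective-moisture index
#' stays inside (0, 1) on average. Optional fixed spatial gradients
#' (`climate$lst_grad_y`, total span in K along the y axis;
#' `climate$pre_grad_x`, span in mm per composite along x) give the
#' drivers stratified spatial structure for attribution analyses.
#'
#' @param config a [sim_config()].
#' @return list of [raster_cube]: `lst` (K), `pre` (mm per composite),
#'   `et` (mm per composite), plus `truth` with the injected slopes.
#' @export
simulate_climate_cubes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ny <- config$grid_shape[1L]; nx <- config$grid_shape[2L]
  npx <- ny * nx
  cal <- composite_calendar(
    config$start_year + seq_len(config$years) - 1L,
    config$composites_per_year)
  nt <- nrow(cal)
  yi <- cal$year - config$start_year
  cl <- config$climate

  set.seed(config$seed + 1L)
  lst_field <- rep(seq(-0.5, 0.5, length.out = ny) * cl$lst_grad_y,
                   times = nx)
  pre_field <- rep(seq(-0.5, 0.5, length.out = nx) * cl$pre_grad_x,
                   each = ny)
  lst_seas <- cl$lst_mean + cl$lst_seasonal_amp *
    cos(2 * pi * (cal$doy - 201) / 365.25)
  lst <- matrix(lst_seas + config$trend$lst * yi, nt, npx) +
    matrix(lst_field, nt, npx, byrow = TRUE)
  if (config$noise$lst_sd > 0) {
    lst <- lst + stats::rnorm(length(lst), 0, config$noise$lst_sd)
  }

  pre_seas <- cl$pre_peak * exp(-((cal$doy - 200) / 70)^2)
  pre <- matrix(pre_seas + config$trend$pre * yi, nt, npx) +
    matrix(pre_field, nt, npx, byrow = TRUE)
  if (config$noise$pre_sd > 0) {
    pre <- pre + stats::rnorm(length(pre), 0, config$noise$pre_sd)
  }
  pre <- pmax(pre, 0)

  et <- cl$et_ratio * matrix(pre_seas, nt, npx) +
    config$trend$et * yi
  if (config$noise$et_sd > 0) {
    et <- et + stats::rnorm(length(et), 0, config$noise$et_sd)
  }
  et <- pmax(et, 0)

  mk <- function(m, name, units) {
    raster_cube(array(m, dim = c(nt, ny, nx)), cal,
                variable = name, units = units)
  }
  list(lst = mk(lst, "lst", "K"), pre = mk(pre, "precipitation", "mm"),
       et = mk(et, "evapotranspiration", "mm"),
       truth = list(lst_slope = config$trend$lst,
                    pre_slope = config$trend$pre,
                    et_slope = config$trend$et))
}

#' Simulate a stratified driver and response with known Q
#'
#' Assigns pixels to `W` strata (contiguous column bands), draws a stratum
#' mean for each, and adds within-stratum Gaussian noise to form the
#' response. The returned `true_q` is computed from the *realised* sums of
#' squares — `1 - SSW/SST` over the generated sample — so the factor
#' detector must match it exactly, not just in expectation.
#'
#' @param config a [sim_config()]; uses `grid_shape`, `seed` and `strata`.
#' @return list: `strata` (`ny x nx` integer matrix), `response`
#'   (`ny x nx` numeric matrix), `true_q`.
#' @export
simulate_strata_response <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  st <- config$strata
  ny <- config$grid_shape[1L]; nx <- config$grid_shape[2L]
  npx <- ny * nx
  if (st$W < 1L) stop("configuration error: W must be >= 1", call. = FALSE)
  if (st$W > npx) {
    stop("configuration error: W exceeds pixel count", call. = FALSE)
  }
  if (st$between_sd < 0 || st$within_sd < 0) {
    stop("configuration error: variances must be >= 0", call. = FALSE)
  }
  set.seed(config$seed + 2L)
  lab <- if (st$W == 1L) matrix(1L, ny, nx) else
    matrix(as.integer(cut(seq_len(npx), breaks = st$W, labels = FALSE)),
           ny, nx)
  mu <- if (st$W == 1L) 0 else stats::rnorm(st$W, 0, st$between_sd)
  resp <- matrix(mu[lab] + stats::rnorm(npx, 0, st$within_sd), ny, nx)
  x <- c(resp); g <- c(lab)
  sst <- sum((x - mean(x))^2)
  ssw <- sum(vapply(split(x, g),
                    function(v) sum((v - mean(v))^2), numeric(1L)))
  true_q <- if (sst == 0) NA_real_ else 1 - ssw / sst
  list(strata = lab, response = resp, true_q = true_q)
}

#' Simulate fractional Gaussian noise with a known Hurst exponent
#'
#' Exact synthesis by Davies-Harte circulant embedding: the fGn
#' autocovariance `g(k) = 0.5 * ((k+1)^(2H) - 2 k^(2H) + |k-1|^(2H))` is
#' embedded in a circulant matrix whose eigenvalues (via FFT) scale complex
#' Gaussian draws, giving a stationary Gaussian sequence with exactly the
#' target autocovariance.
#'
#' @param n series length (>= 64).
#' @param H target Hurst exponent in (0, 1).
#' @param seed optional integer seed.
#' @return numeric vector of length `n`.
#' @export
simulate_fgn <- function(n, H, seed = NULL) {
  if (H <= 0 || H >= 1) {
    stop("domain error: H must lie in (0, 1)", call. = FALSE)
  }
  if (n < 64) stop("n must be at least 64", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  k <- 0:n
  g <- 0.5 * ((k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
  row <- c(g, rev(g[2:n]))           # circulant first row, length 2n
  lam <- Re(stats::fft(row))
  lam[lam < 0] <- 0                  # clip tiny negative eigenvalues
  m <- 2L * n
  z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
  z[1L] <- complex(real = sqrt(2) * Re(z[1L]), imaginary = 0)
  z[n + 1L] <- complex(real = sqrt(2) * Re(z[n + 1L]), imaginary = 0)
  z[(n + 2L):m] <- Conj(z[seq(n, 2L, by = -1L)])
  x <- Re(stats::fft(sqrt(lam / (2 * m)) * z))
  x[seq_len(n)]
}
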