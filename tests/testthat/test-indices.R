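make_band_cubes <- function(b, nt = 4L) {
  cal <- composite_calendar(2001L, nt)
  out <- lapply(b, function(v) {
    raster_cube(array(v, dim = c(nt, 1, 1)), cal, units = "reflectance")
  })
  names(out) <- names(b)
  out
}

test_that("EVI matches hand-computed values and handles degenerate input", {
  bands <- make_band_cubes(list(b1 = 0.1, b2 = 0.5, b3 = 0.05))
  evi <- compute_evi(bands)
  expect_equal(evi$values[1, 1, 1], 2.5 * 0.4 / 1.725, tolerance = 1e-12)

  zero <- make_band_cubes(list(b1 = 0, b2 = 0, b3 = 0))
  expect_equal(compute_evi(zero)$values[1, 1, 1], 0)

  same <- make_band_cubes(list(b1 = 0.3, b2 = 0.3, b3 = 0.1))
  expect_equal(compute_evi(same)$values[1, 1, 1], 0)

  expect_error(compute_evi(bands[c("b1", "b2")]), "input error")
})

test_that("MSAVI matches hand-computed values", {
  bands <- make_band_cubes(list(b1 = 0.1, b2 = 0.4))
  expect_equal(compute_msavi(bands)$values[1, 1, 1],
               (1.8 - sqrt(1.8^2 - 2.4)) / 2, tolerance = 1e-12)
  same <- make_band_cubes(list(b1 = 0.25, b2 = 0.25))
  expect_equal(compute_msavi(same)$values[1, 1, 1], 0)
  zero <- make_band_cubes(list(b1 = 0, b2 = 0))
  expect_equal(compute_msavi(zero)$values[1, 1, 1], 0)
  expect_error(compute_msavi(zero["b1"]), "input error")
})

test_that("index cubes respect the [-0.3, 0.9] dynamic range", {
  bands <- make_band_cubes(list(b1 = 0.9, b2 = 0.01, b3 = 0.4))
  expect_gte(min(compute_evi(bands)$values), -0.3)
  expect_lte(max(compute_evi(bands)$values), 0.9)
})

test_that("snow removal fixes winter dropouts, leaves summer alone, and is
           idempotent", {
  cal <- composite_calendar(2001L, 46L)
  x <- rep(0.1, 46)
  x[cal$doy >= 121 & cal$doy <= 304] <- 0.5   # summer plateau
  x[3] <- -0.2                                 # one winter dropout
  cube <- raster_cube(array(x, dim = c(46, 1, 1)), cal)
  fixed <- remove_snow_contamination(cube)
  expect_equal(fixed$values[3, 1, 1], 0.1)
  summer <- cal$doy > 60 & cal$doy < 305
  expect_identical(fixed$values[summer, 1, 1], cube$values[summer, 1, 1])
  twice <- remove_snow_contamination(fixed)
  expect_identical(twice$values, fixed$values)

  clean <- raster_cube(array(x - (x == -0.2) * (x - 0.1),
                             dim = c(46, 1, 1)), cal)  # dropout-free copy
  expect_identical(remove_snow_contamination(clean)$values[, 1, 1],
                   clean$values[, 1, 1])

  expect_error(remove_snow_contamination(cube, winter_doy = c(-5, 400)),
               "empty winter window")
})

test_that("Savitzky-Golay reproduces polynomials and denoises", {
  cal <- composite_calendar(2001:2002, 46L)
  t <- seq_len(92)
  cubic <- 1e-4 * t^3 - 0.01 * t^2 + 0.3 * t
  cube <- raster_cube(array(cubic, dim = c(92, 1, 1)), cal)
  sm <- savitzky_golay_smooth(cube, window = 7, polyorder = 3)
  interior <- 4:89  # mirror-padded edges are not polynomial-exact
  expect_equal(sm$values[interior, 1, 1], cubic[interior],
               tolerance = 1e-9)

  # interpolating filter: polyorder = window - 1 leaves the series alone
  noisy_vals <- sin(t / 5) + 0.3 * rnorm(92)
  ncube <- raster_cube(array(noisy_vals, dim = c(92, 1, 1)), cal)
  ident <- savitzky_golay_smooth(ncube, window = 5, polyorder = 4)
  expect_equal(ident$values[, 1, 1], noisy_vals, tolerance = 1e-9)

  # Monte-Carlo denoising: RMSE against the clean signal at least halved
  set.seed(42)
  clean <- sin(2 * pi * t / 46)
  rmse_raw <- rmse_sm <- numeric(20)
  for (r in 1:20) {
    noisy <- clean + rnorm(92, 0, 0.05)
    nc <- raster_cube(array(noisy, dim = c(92, 1, 1)), cal)
    smv <- savitzky_golay_smooth(nc, 7, 2)$values[, 1, 1]
    rmse_raw[r] <- sqrt(mean((noisy - clean)^2))
    rmse_sm[r] <- sqrt(mean((smv - clean)^2))
  }
  # the window-7 order-2 filter passes sqrt(147)/21 = 57.7% of white-noise
  # sd, so the achievable RMSE ratio is bounded below ~0.58 plus signal
  # distortion; assert a firm reduction consistent with that bound
  expect_lt(mean(rmse_sm), 0.7 * mean(rmse_raw))

  # long stationary series: mean preserved within 1%
  long_cal <- composite_calendar(2001:2010, 46L)
  set.seed(1)
  x <- 1 + 0.2 * rnorm(460)
  lc <- raster_cube(array(x, dim = c(460, 1, 1)), long_cal)
  expect_equal(mean(savitzky_golay_smooth(lc)$values), mean(x),
               tolerance = 0.01)

  expect_error(savitzky_golay_smooth(cube, window = 4), "odd")
  expect_error(savitzky_golay_smooth(cube, window = 7, polyorder = 7),
               "polyorder")
  small <- raster_cube(array(1:4, dim = c(4, 1, 1)),
                       composite_calendar(2001L, 4L))
  expect_error(savitzky_golay_smooth(small, window = 5), "exceeds")
})

test_that("growing-season mean equals the brute-force composite mean", {
  cal <- composite_calendar(2001L, 46L)
  cube <- raster_cube(array(7, dim = c(46, 1, 1)), cal)
  gs <- growing_season_mean(cube)
  expect_equal(gs$values[1, 1, 1], 7)

  idx <- raster_cube(array(seq_len(46), dim = c(46, 1, 1)), cal)
  inwin <- which(cal$doy >= 121 & cal$doy <= 304)
  expect_length(inwin, 23L)
  expect_equal(growing_season_mean(idx)$values[1, 1, 1], mean(inwin))

  # a fully-masked year comes out masked
  vals <- array(NA_real_, dim = c(46, 1, 1))
  masked <- raster_cube(vals, cal)
  expect_true(is.na(growing_season_mean(masked)$values[1, 1, 1]))
})

test_that("masked composites outside the window never change the mean", {
  cal <- composite_calendar(2001L, 46L)
  set.seed(2)
  x <- runif(46)
  full <- raster_cube(array(x, dim = c(46, 1, 1)), cal)
  x2 <- x; x2[1] <- NA  # winter composite
  holed <- raster_cube(array(x2, dim = c(46, 1, 1)), cal)
  expect_equal(growing_season_mean(full)$values,
               growing_season_mean(holed)$values)
})
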