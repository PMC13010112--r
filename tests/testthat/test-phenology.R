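smoothed_indices <- function(cfg) {
  sim <- simulate_reflectance_cube(cfg)
  list(evi = savitzky_golay_smooth(compute_evi(sim$bands)),
       msavi = savitzky_golay_smooth(compute_msavi(sim$bands)),
       truth = sim$truth)
}

test_that("noise-free extraction recovers the analytic crossings within
           half a composite interval", {
  idx <- smoothed_indices(noise_free_sim(grid = c(4, 4)))
  sos <- extract_sos(idx$msavi)
  eos <- extract_eos(idx$evi)
  es <- abs(stack_matrix(sos) - matrix(idx$truth$true_sos, 20))
  ee <- abs(stack_matrix(eos) - matrix(idx$truth$true_eos, 20))
  expect_true(all(is.finite(es)))
  expect_lt(max(es), 4)
  expect_lt(max(ee), 4)
})

test_that("a flat series and a monotone year are flagged undefined", {
  cal <- composite_calendar(2001L, 46L)
  flat <- raster_cube(array(0.2, dim = c(46, 1, 1)), cal)
  expect_true(is.na(extract_sos(flat)$values[1, 1, 1]))
  mono <- raster_cube(array(seq(0, 0.6, length.out = 46),
                            dim = c(46, 1, 1)), cal)
  expect_true(is.na(extract_eos(mono)$values[1, 1, 1]))
})

test_that("a step between composites brackets SOS between their dates", {
  cal <- composite_calendar(2001L, 46L)
  x <- c(rep(0, 17), rep(1, 12), rep(0, 17))   # step between 17 and 18
  cube <- raster_cube(array(x, dim = c(46, 1, 1)), cal)
  for (theta in c(0.1, 0.5, 0.9)) {
    s <- extract_sos(cube, theta = theta)$values[1, 1, 1]
    expect_gt(s, cal$doy[17])
    expect_lte(s, cal$doy[18])
  }
})

test_that("increasing theta never advances SOS nor delays EOS on a
           unimodal cycle", {
  idx <- smoothed_indices(noise_free_sim(grid = c(3, 3), years = 2))
  thetas <- c(0.1, 0.2, 0.35, 0.5)
  sos <- sapply(thetas, function(th)
    c(stack_matrix(extract_sos(idx$msavi, theta = th))))
  eos <- sapply(thetas, function(th)
    c(stack_matrix(extract_eos(idx$evi, theta = th))))
  expect_true(all(diff(t(sos)) >= 0))
  expect_true(all(diff(t(eos)) <= 0))
})

test_that("invalid theta is rejected", {
  cal <- composite_calendar(2001L, 46L)
  cube <- raster_cube(array(0.2, dim = c(46, 1, 1)), cal)
  expect_error(extract_sos(cube, theta = 0), "configuration error")
  expect_error(extract_eos(cube, theta = 1.5), "configuration error")
})

test_that("LOS equals EOS minus SOS and propagates undefined pixels", {
  yrs <- 2001:2004
  sosv <- array(c(131.10, 140, NA, 150), dim = c(1, 2, 2))
  eosv <- array(c(266.64, 250, 260, NA), dim = c(1, 2, 2))
  sos <- year_stack(sosv, 2001L, "SOS", "DOY")
  eos <- year_stack(eosv, 2001L, "EOS", "DOY")
  los <- compute_los(sos, eos)
  expect_equal(los$values[1, 1, 1], 135.54)
  expect_equal(los$values[1, 2, 1], 110)
  expect_true(is.na(los$values[1, 1, 2]))
  expect_true(is.na(los$values[1, 2, 2]))

  other <- year_stack(array(1, dim = c(1, 3, 3)), 2001L)
  expect_error(compute_los(sos, other), "input error")
})

test_that("LOS identity holds map-wide on extracted phenology", {
  idx <- smoothed_indices(noise_free_sim(grid = c(3, 3), years = 3))
  sos <- extract_sos(idx$msavi); eos <- extract_eos(idx$evi)
  los <- compute_los(sos, eos)
  expect_equal(los$values, eos$values - sos$values)
})

test_that("area-share summaries match exhaustive tallies", {
  allsame <- year_stack(array(152, dim = c(1, 5, 5)), 2001L, "SOS", "DOY")
  s1 <- phenology_summary(allsame)
  expect_equal(s1$share_pct[s1$bin == "Jun"], 100)

  two <- year_stack(array(rep(c(100, 200), each = 10), dim = c(1, 4, 5)),
                    2001L, "SOS", "DOY")
  s2 <- phenology_summary(two)
  expect_equal(s2$share_pct[s2$bin == "Apr"], 50)
  expect_equal(s2$share_pct[s2$bin == "Jul"], 50)

  set.seed(7)
  vals <- sample(30:330, 100, replace = TRUE)
  ys <- year_stack(array(vals, dim = c(1, 10, 10)), 2001L, "SOS", "DOY")
  s3 <- phenology_summary(ys)
  edges <- c(0, 31, 59, 90, 120, 151, 181, 212, 243, 273, 304, 334, 366)
  tally <- table(cut(vals, edges))
  expect_equal(s3$n, as.integer(tally))
  expect_equal(sum(s3$share_pct), 100)

  expect_error(phenology_summary(
    year_stack(array(1, dim = c(0, 1, 1)), integer(0))), "empty")
})
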