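test_that("3-sigma cleaning replaces spikes by interpolation", {
  set.seed(50)
  x <- rnorm(50)
  x[25] <- mean(x) + 5 * sd(x)
  y <- remove_outliers_3sigma(x)
  expect_equal(y[25], (x[24] + x[26]) / 2, tolerance = 1e-12)
  expect_identical(y[-25], x[-25])

  clean <- rnorm(30)
  clean <- (clean - mean(clean)) / sd(clean)  # guaranteed inside 3 sigma
  expect_identical(remove_outliers_3sigma(clean), clean)

  # two consecutive spikes interpolate across the pair
  z <- rep(c(-1, 1), 25)
  z[10:11] <- c(40, 45)
  w <- remove_outliers_3sigma(z)
  manual <- approx(c(9, 12), z[c(9, 12)], xout = 10:11)$y
  expect_equal(w[10:11], manual, tolerance = 1e-12)

  expect_identical(remove_outliers_3sigma(rep(2, 10)), rep(2, 10))
  expect_error(remove_outliers_3sigma(1:3), "input error")
  expect_length(remove_outliers_3sigma(x, mode = "delete"), 49L)
})

test_that("the rescaled-range statistic matches its full hand
           computation", {
  # mu = 2.5, Z = (-1.5, -2, -1.5, 0), R = 2, S = sqrt(1.25)
  expect_equal(rs_statistic(c(1, 2, 3, 4), 4), 2 / sqrt(1.25),
               tolerance = 1e-12)
  expect_equal(rs_statistic(c(1, 2, 3, 4), 4), 1.7889, tolerance = 1e-4)

  expect_warning(rs <- rs_statistic(rep(3, 16), 8), "zero standard")
  expect_true(is.na(rs))

  set.seed(51)
  x <- rnorm(100)
  expect_equal(rs_statistic(5 * x + 2, 10), rs_statistic(x, 10),
               tolerance = 1e-12)

  expect_error(rs_statistic(1:4, 8), "exceeds")
})

test_that("rs_statistic equals the literal loop transcription", {
  set.seed(52)
  for (r in 1:10) {
    x <- rnorm(sample(60:300, 1))
    p <- sample(c(5, 8, 10, 16), 1)
    expect_equal(rs_statistic(x, p), brute_rs(x, p), tolerance = 1e-12)
  }
})

test_that("the log-log fit behaves at the limits", {
  # a deterministic ramp is maximally persistent
  h_ramp <- hurst_exponent(seq_len(512) + rnorm(512, 0, 0.01),
                           clean = FALSE)
  expect_gt(h_ramp$h, 0.9)

  expect_error(hurst_exponent(rnorm(32)), "shorter than 64")
  expect_warning(hurst_exponent(rnorm(32), scales = 4:10), "fragile")
  expect_error(suppressWarnings(hurst_exponent(rep(1, 100))), "scales")
})

test_that("R/S recovery is monotone in the true Hurst exponent", {
  hs <- c(0.3, 0.5, 0.7)
  est <- sapply(seq_along(hs), function(i) {
    mean(vapply(1:8, function(s)
      hurst_exponent(simulate_fgn(1024, hs[i], seed = 100 * i + s))$h,
      numeric(1L)))
  })
  expect_true(all(diff(est) > 0))
  expect_lt(abs(est[2] - 0.5), 0.1)
})

test_that("future-trend classification covers the whole 3x3 grid", {
  cases <- list(
    list(-0.8, 0.3, "Increase"),  list(-0.8, 0.5, "Uncertain"),
    list(-0.8, 0.7, "Decrease"),
    list(0.2, 0.3, "Stable"), list(0.2, 0.5, "Stable"),
    list(0.2, 0.9, "Stable"),
    list(0.6, 0.3, "Decrease"), list(0.6, 0.5, "Uncertain"),
    list(0.6, 0.7, "Increase"))
  for (cs in cases) {
    expect_equal(as.character(classify_future_trend(cs[[1]], cs[[2]])),
                 cs[[3]])
  }
  # boundaries fall to the conservative cell
  expect_equal(as.character(classify_future_trend(0.5, 0.9)), "Stable")
  expect_equal(as.character(classify_future_trend(-0.5, 0.3)), "Stable")
  expect_equal(as.character(classify_future_trend(0.8, 0.4)), "Uncertain")
  expect_equal(as.character(classify_future_trend(0.8, 0.6)), "Uncertain")
  expect_true(is.na(classify_future_trend(NA, 0.5)))
})

test_that("area shares match exhaustive tallies", {
  uni <- matrix(0.7, 4, 4)
  sh <- hurst_area_shares(uni)
  expect_equal(sh$h_intervals$share_pct[sh$h_intervals$interval == "H>0.6"],
               100)

  thirds <- matrix(rep(c(0.3, 0.5, 0.7), each = 3), 3, 3)
  sh3 <- hurst_area_shares(thirds)
  expect_equal(sh3$h_intervals$share_pct, rep(100 / 3, 3))

  set.seed(53)
  h <- matrix(runif(100), 10, 10)
  cls <- matrix(as.character(classify_future_trend(
    runif(100, -1, 1), c(h))), 10, 10)
  sh4 <- hurst_area_shares(h, cls)
  expect_equal(sum(sh4$h_intervals$n), 100L)
  expect_equal(sh4$h_intervals$n[1], sum(h < 0.4))
  expect_equal(sum(sh4$classes$share_pct), 100)

  expect_error(hurst_area_shares(matrix(NA_real_, 2, 2)), "masked")
})
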