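test_that("Theil-Sen slope equals the brute-force pairwise median", {
  expect_equal(theil_sen_slope(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(theil_sen_slope(c(3, 1, 2), c(1, 2, 3)),
               median(c(-2, -0.5, 1)))
  expect_equal(theil_sen_slope(rep(5, 8)), 0)
  expect_true(is.na(theil_sen_slope(c(1, NA, NA))))

  set.seed(10)
  for (n in c(5, 13, 50)) {
    x <- rnorm(n)
    expect_equal(theil_sen_slope(x), brute_theil_sen(x), tolerance = 1e-13)
  }
})

test_that("Mann-Kendall statistics match the defining formulas", {
  mk <- mann_kendall(c(1, 2, 3, 4))
  expect_identical(mk$s, 6L)
  expect_equal(mk$variance, 4 * 3 * 13 / 18)
  expect_equal(mk$z, 5 / sqrt(4 * 3 * 13 / 18), tolerance = 1e-12)
  expect_equal(mk$z, 1.6984, tolerance = 1e-4)

  expect_equal(mann_kendall(rep(2, 10))$z, 0)
  expect_true(is.na(mann_kendall(c(1, 2, 3))$z))

  set.seed(11)
  x <- rnorm(20)
  expect_identical(mann_kendall(x)$s, as.integer(brute_mk_s(x)))
  # antisymmetry under time reversal
  expect_equal(mann_kendall(rev(x))$z, -mann_kendall(x)$z)
})

test_that("significance stratification reproduces every class rule", {
  expect_equal(as.character(classify_significance(-0.1, -2.5)),
               "significant decrease")
  expect_equal(as.character(classify_significance(0.2, 1.7)),
               "slightly increase")
  expect_equal(as.character(classify_significance(0.1, 0.5)),
               "no significant change")
  expect_equal(as.character(classify_significance(-0.3, -1.7)),
               "slightly decrease")
  expect_equal(as.character(classify_significance(0.4, 2.2)),
               "significant increase")
  # boundary behaviour at the printed critical values
  expect_equal(as.character(classify_significance(1, 1.64)),
               "slightly increase")
  expect_equal(as.character(classify_significance(1, 1.96)),
               "slightly increase")
  expect_equal(as.character(classify_significance(1, 1.9601)),
               "significant increase")
  expect_equal(as.character(classify_significance(1, 1.6399)),
               "no significant change")
  # zero slope is never a trend
  expect_equal(as.character(classify_significance(0, 0.3)),
               "no significant change")
  expect_equal(as.character(suppressWarnings(classify_significance(0, 2.5))),
               "no significant change")
  expect_true(is.na(classify_significance(NaN, 1)))
})

test_that("classification is total over a slope x z grid", {
  grid <- expand.grid(slope = c(-2, -0.1, 0, 0.1, 2),
                      z = c(-3, -1.96, -1.8, -1.64, -1, 0, 1, 1.64, 1.8,
                            1.96, 3))
  cls <- suppressWarnings(classify_significance(grid$slope, grid$z))
  expect_false(any(is.na(cls)))
})

test_that("trend maps recover noise-free injected slopes and zonal
           structure", {
  yrs <- 2001:2020
  line <- outer(yrs - 2001, rep(0.268, 9)) + 270
  ys <- year_stack(array(line, dim = c(20, 3, 3)), yrs, "GLST", "K")
  tm <- trend_map(ys)
  expect_equal(max(abs(tm$slope - 0.268)), 0, tolerance = 1e-9)
  expect_true(all(tm$class == "significant increase"))

  zones <- matrix(rep(c("a", "b"), c(3, 6)), 3, 3)
  mixed <- array(NA_real_, dim = c(20, 3, 3))
  mixed[, , 1] <- outer(yrs - 2001, rep(-0.5, 3))
  mixed[, , 2:3] <- outer(yrs - 2001, rep(0.25, 6))
  tz <- trend_map(year_stack(mixed, yrs), zones = zones)
  expect_equal(tz$summary$mean_slope[tz$summary$zone == "a"], -0.5,
               tolerance = 1e-9)
  expect_equal(tz$summary$mean_slope[tz$summary$zone == "b"], 0.25,
               tolerance = 1e-9)

  expect_error(trend_map(year_stack(array(1, dim = c(3, 1, 1)),
                                    2001:2003)), "4 years")
})

test_that("white-noise type-I error at |Z| > 1.96 is nominal", {
  set.seed(20)
  n_rep <- 4000L
  x <- matrix(rnorm(20 * n_rep), nrow = 20)
  z <- apply(x, 2L, function(s) mann_kendall(s)$z)
  rate <- mean(abs(z) > 1.96)
  expect_gt(rate, 0.035)
  expect_lt(rate, 0.065)
})

test_that("contribution shares split the LOS change by rate magnitude", {
  sh <- contribution_shares(-0.1102, 0.2205)
  expect_equal(unname(sh["share_eos"]), 66.67, tolerance = 0.05)
  expect_equal(unname(sh["share_sos"]), 33.33, tolerance = 0.05)
  expect_equal(unname(contribution_shares(-0.2, 0.2)),
               c(50, 50))
  expect_equal(unname(contribution_shares(0, 0.3)), c(0, 100))
  expect_true(all(is.na(contribution_shares(0, 0))))
})
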