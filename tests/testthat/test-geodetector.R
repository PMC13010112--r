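test_that("quantile discretization balances strata and handles ties", {
  lab <- quantile_discretize(1:1000, 5L)
  expect_equal(as.integer(table(lab)), rep(200L, 5))

  expect_warning(one <- quantile_discretize(rep(3, 50), 5L), "collapsed")
  expect_equal(attr(one, "W"), 1L)

  set.seed(30)
  u <- runif(10000)
  labs <- quantile_discretize(u, 5L)
  shares <- as.integer(table(labs)) / 10000
  expect_true(all(abs(shares - 0.2) < 0.01))
})

test_that("factor detector Q equals the sums-of-squares oracle", {
  q1 <- factor_q(c(0, 0, 0, 1, 1, 1), rep(1:2, each = 3))
  expect_equal(q1$q, 1)

  q0 <- factor_q(rnorm(30), rep(1L, 30))
  expect_equal(q0$q, 0, tolerance = 1e-14)

  q <- factor_q(c(1, 2, 3, 4, 5, 6), rep(1:2, each = 3))
  expect_equal(q$q, 1 - 4 / 17.5, tolerance = 1e-14)

  set.seed(31)
  for (r in 1:25) {
    n <- sample(20:200, 1)
    w <- sample(2:6, 1)
    x <- rnorm(n)
    g <- sample(w, n, replace = TRUE)
    expect_equal(factor_q(x, g)$q, brute_q(x, g), tolerance = 1e-12)
  }

  # zero total variance is undefined
  expect_true(is.na(factor_q(rep(1, 10), rep(1:2, 5))$q))
})

test_that("Q matches the generator's realised true_q exactly", {
  cfg <- sim_config(grid_shape = c(12, 12), seed = 13,
                    strata = list(W = 5, between_sd = 1.5, within_sd = 0.8))
  sr <- simulate_strata_response(cfg)
  expect_equal(factor_q(sr$response, sr$strata)$q, sr$true_q,
               tolerance = 1e-14)
})

test_that("strength labels respect the printed thresholds at the
           boundaries", {
  expect_equal(q_strength(0.55), "moderate")
  expect_equal(q_strength(0.35), "moderate")
  expect_equal(q_strength(0.56), "strong")
  expect_equal(q_strength(0.34), "weak")
  expect_true(is.na(q_strength(NA)))
  # and factor_q attaches the same labels
  q <- factor_q(c(0, 0, 1, 1), c(1, 1, 2, 2))
  expect_equal(q$strength, q_strength(q$q))
})

test_that("splitting a stratum never decreases Q", {
  set.seed(32)
  for (r in 1:10) {
    x <- rnorm(120)
    g <- sample(3, 120, replace = TRUE)
    g2 <- g
    split_px <- g == 2 & seq_along(g) %% 2 == 0
    g2[split_px] <- 4L
    expect_gte(factor_q(x, g2)$q, factor_q(x, g)$q - 1e-12)
  }
})

test_that("permutation significance separates signal from null", {
  set.seed(33)
  sig <- rep(c(0, 5), each = 50) + rnorm(100, 0, 0.5)
  qs <- q_significance(sig, rep(1:2, each = 50), n_perm = 999, seed = 1)
  expect_lte(qs$p_value, 0.001)

  # null calibration: p roughly uniform under random labels
  ps <- replicate(120, {
    x <- rnorm(60)
    g <- sample(3, 60, replace = TRUE)
    q_significance(x, g, n_perm = 99)$p_value
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_lt(mean(ps < 0.05), 0.15)

  expect_true(is.na(q_significance(rnorm(20), rep(1L, 20))$p_value))
  expect_error(q_significance(rnorm(20), rep(1:2, 10), n_perm = 10),
               "configuration error")
})

test_that("the F-based test agrees qualitatively with permutation", {
  set.seed(34)
  sig <- rep(c(0, 3), each = 40) + rnorm(80)
  null <- rnorm(80)
  g <- rep(1:2, each = 40)
  expect_lt(q_significance(sig, g, method = "f")$p_value, 0.01)
  expect_gt(q_significance(null, sample(g), method = "f")$p_value, 0.01)
})

test_that("interaction detection follows overlay algebra", {
  set.seed(35)
  x <- rnorm(200)
  a <- sample(4, 200, replace = TRUE)

  same <- interaction_q(x, a, a)
  expect_equal(same$q_ab$q, same$q_a, tolerance = 1e-12)

  b <- sample(3, 200, replace = TRUE)
  ind <- interaction_q(x, a, b)
  expect_gte(ind$q_ab$q, ind$q_a - 1e-12)  # refinement never decreases Q

  # additive stepwise response with no noise: overlay explains everything
  fa <- c(-1, 0, 2, 5)[a]; gb <- c(10, 0, -3)[b]
  add <- interaction_q(fa + gb, a, b)
  expect_equal(add$q_ab$q, 1, tolerance = 1e-12)
  expect_equal(add$relation, "nonlinear-enhance")
})

test_that("the detector suite ranks the constructed driver first", {
  set.seed(36)
  ny <- 12; nx <- 12; npx <- ny * nx
  yrs <- 2001:2020
  # driver layer with 5-level spatial structure, constant over years
  drv <- matrix(rep(seq_len(5), length.out = npx), ny, nx)
  resp_px <- c(-2, -1, 0, 1, 2)[drv] * 1.0 + rnorm(npx, 0, 0.68)
  resp <- year_stack(array(rep(resp_px, each = 20), dim = c(20, ny, nx)),
                     yrs, "EOS")
  drivers <- list(
    GEM = year_stack(array(rep(c(drv) + rnorm(npx, 0, 0.05), each = 20),
                           dim = c(20, ny, nx)), yrs),
    NOISE1 = year_stack(array(rnorm(20 * npx), dim = c(20, ny, nx)), yrs),
    NOISE2 = year_stack(array(rnorm(20 * npx), dim = c(20, ny, nx)), yrs))
  det <- run_detector_suite(resp, drivers,
                            windows = list(c(2001, 2020)))
  fac <- det$factors
  expect_equal(fac$driver[which.max(fac$q)], "GEM")
  expect_true(all(fac$q[fac$driver != "GEM"] < 0.35))
  expect_equal(nrow(det$interactions), 3L)
})
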