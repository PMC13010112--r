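# Independent brute-force oracles used across the suite. Each is a literal
# transcription of the defining formula, kept free of any package internals
# so it can disagree with the implementation.

brute_theil_sen <- function(x, t = seq_along(x)) {
  sl <- c()
  for (i in seq_along(x)) {
    for (j in seq_along(x)) {
      if (i < j) sl <- c(sl, (x[j] - x[i]) / (t[j] - t[i]))
    }
  }
  median(sl)
}

brute_mk_s <- function(x) {
  s <- 0L
  k <- length(x)
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) s <- s + sign(x[j] - x[i])
  }
  s
}

brute_q <- function(x, g) {
  sst <- sum((x - mean(x))^2)
  ssw <- 0
  for (u in unique(g)) {
    v <- x[g == u]
    ssw <- ssw + sum((v - mean(v))^2)
  }
  1 - ssw / sst
}

# literal loop transcription of the rescaled-range recipe: subset means,
# cumulative deviations, range, population sd, per-subset ratio, mean
brute_rs <- function(x, p) {
  n <- length(x)
  nk <- floor(n / p)
  ratios <- c()
  for (k in 1:nk) {
    y <- x[((k - 1) * p + 1):(k * p)]
    mu <- (1 / p) * sum(y)
    z <- numeric(p)
    for (m in 1:p) z[m] <- sum(y[1:m] - mu)
    r <- max(z) - min(z)
    s <- sqrt((1 / p) * sum((y - mu)^2))
    if (s > 0) ratios <- c(ratios, r / s)
  }
  mean(ratios)
}

# partial correlation via the regression-residual definition
residual_partial_corr <- function(v, l, m) {
  rv <- residuals(lm(v ~ m))
  rl <- residuals(lm(l ~ m))
  cor(rv, rl)
}

# tiny noise-free simulation shared by several tests
noise_free_sim <- function(grid = c(4, 4), years = 20, seed = 5, ...) {
  sim_config(grid_shape = grid, years = years, seed = seed,
             noise = list(vi_sd = 0, snow_prob = 0), ...)
}
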