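#' Theil-Sen slope
#'
#' Median of all pairwise slopes `(x[j] - x[i]) / (t[j] - t[i])` over
#' `i < j`; with an even pair count the median is the mean of the two
#' central values. Robust to outliers and free of distributional
#' assumptions. Missing values are dropped pairwise.
#'
#' @param x numeric series.
#' @param t time index (default calendar positions `seq_along(x)`); slopes
#'   are in units of `x` per unit of `t`.
#' @return slope (scalar), `NA` if fewer than 2 valid points.
#' @export
theil_sen_slope <- function(x, t = seq_along(x)) {
  ok <- is.finite(x) & is.finite(t)
  x <- x[ok]; t <- t[ok]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  dx <- outer(x, x, `-`); dt <- outer(t, t, `-`)
  stats::median(dx[lower.tri(dx)] / dt[lower.tri(dt)])
}

#' Mann-Kendall trend test
#'
#' Sign-concordance statistic `S = sum_{i<j} sgn(x[j] - x[i])`, its
#' variance `Var(S) = K (K - 1) (2 K + 5) / 18` (no tie correction), and
#' the standardised statistic with continuity shift:
#' `Z = (S - 1)/sqrt(Var)` for `S > 0`, `0` for `S = 0`,
#' `(S + 1)/sqrt(Var)` for `S < 0`.
#'
#' @param x numeric series (>= 4 valid points).
#' @return list with `s` (integer S), `variance`, `z`, `n` (valid length);
#'   all `NA` for a too-short series.
#' @export
mann_kendall <- function(x) {
  x <- x[is.finite(x)]
  k <- length(x)
  if (k < 4L) {
    return(list(s = NA_integer_, variance = NA_real_, z = NA_real_, n = k))
  }
  d <- sign(outer(x, x, `-`))
  s <- sum(d[lower.tri(d)])  # lower triangle holds x[later]-x[earlier]
  v <- k * (k - 1) * (2 * k + 5) / 18
  z <- if (s > 0) (s - 1) / sqrt(v) else if (s < 0) (s + 1) / sqrt(v) else 0
  list(s = as.integer(s), variance = v, z = z, n = k)
}

TREND_CLASSES <- c("significant decrease", "slightly decrease",
                   "no significant change", "slightly increase",
                   "significant increase")

#' Five-class trend significance stratification
#'
#' Combines the Theil-Sen slope with the Mann-Kendall Z statistic into
#' five classes using the two-sided normal critical values 1.96 (95%
#' confidence) and 1.64 (90% confidence):
#'
#' * slope < 0 and |Z| > 1.96 — significant decrease
#' * slope < 0 and 1.64 <= |Z| <= 1.96 — slightly decrease
#' * |Z| < 1.64 (any non-zero slope) — no significant change
#' * slope > 0 and 1.64 <= |Z| <= 1.96 — slightly increase
#' * slope > 0 and |Z| > 1.96 — significant increase
#'
#' A zero slope is always classed "no significant change". A warning is
#' emitted when `sign(z) != sign(slope)` (the scheme pairs slope sign with
#' |Z| bands; the two statistics nearly always agree in sign, so the
#' ambiguity is rarely exercised).
#'
#' @param slope Theil-Sen slope (vectorised).
#' @param z Mann-Kendall Z (vectorised).
#' @return factor with the five class levels from "significant decrease"
#'   to "significant increase"; `NA` for non-finite input.
#' @export
classify_significance <- function(slope, z) {
  n <- max(length(slope), length(z))
  slope <- rep_len(slope, n); z <- rep_len(z, n)
  out <- rep(NA_character_, n)
  ok <- is.finite(slope) & is.finite(z)
  az <- abs(z)
  disagree <- ok & slope != 0 & z != 0 & sign(z) != sign(slope)
  if (any(disagree)) {
    warning(sum(disagree),
            " pixel(s) with sign(Z) != sign(slope); classified by slope",
            " sign and |Z| band as printed")
  }
  out[ok & slope < 0 & az > 1.96] <- TREND_CLASSES[1L]
  out[ok & slope < 0 & az >= 1.64 & az <= 1.96] <- TREND_CLASSES[2L]
  out[ok & az < 1.64] <- TREND_CLASSES[3L]
  out[ok & slope == 0] <- TREND_CLASSES[3L]
  out[ok & slope > 0 & az >= 1.64 & az <= 1.96] <- TREND_CLASSES[4L]
  out[ok & slope > 0 & az > 1.96] <- TREND_CLASSES[5L]
  factor(out, levels = TREND_CLASSES)
}

#' Per-pixel trend map with significance stratification
#'
#' Applies [theil_sen_slope()], [mann_kendall()] and
#' [classify_significance()] to every pixel of a yearly raster series, and
#' summarises mean slope and class shares, optionally per zone (basin or
#' land-cover raster).
#'
#' @param ys a [year_stack] (>= 4 years).
#' @param zones optional `ny x nx` categorical matrix for zonal summaries.
#' @return list: `slope`, `z` (`ny x nx` matrices), `class` (factor matrix
#'   as character), `summary` (data.frame: zone, mean slope, class share
#'   percentages).
#' @export
trend_map <- function(ys, zones = NULL) {
  m <- stack_matrix(ys)
  if (nrow(m) < 4L) stop("need at least 4 years", call. = FALSE)
  t <- ys$years
  slope <- apply(m, 2L, theil_sen_slope, t = t)
  z <- apply(m, 2L, function(x) mann_kendall(x)$z)
  cls <- classify_significance(slope, z)
  d <- dim(ys$values)[2:3]
  zone <- if (is.null(zones)) rep("all", length(slope)) else
    as.character(zones)
  ok <- is.finite(slope)
  summ <- do.call(rbind, lapply(split(seq_along(slope)[ok], zone[ok]),
    function(idx) {
      sh <- 100 * table(cls[idx]) / length(idx)
      cbind(data.frame(n = length(idx), mean_slope = mean(slope[idx])),
            as.data.frame.matrix(t(as.matrix(sh))))
    }))
  summ <- cbind(zone = rownames(summ), summ)
  rownames(summ) <- NULL
  list(slope = matrix(slope, d[1L], d[2L]),
       z = matrix(z, d[1L], d[2L]),
       class = matrix(as.character(cls), d[1L], d[2L]),
       summary = summ)
}

#' Contribution shares of SOS advance and EOS delay to LOS change
#'
#' Splits a growing-season lengthening between its two margins by relative
#' rate magnitude: `share_eos = |rate_eos| / (|rate_sos| + |rate_eos|) *
#' 100`, `share_sos = 100 - share_eos`.
#'
#' @param rate_sos SOS trend rate (d/a; negative = advance).
#' @param rate_eos EOS trend rate (d/a; positive = delay).
#' @return named numeric vector `c(share_sos, share_eos)` in percent.
#' @export
contribution_shares <- function(rate_sos, rate_eos) {
  tot <- abs(rate_sos) + abs(rate_eos)
  if (tot == 0) {
    return(c(share_sos = NA_real_, share_eos = NA_real_))
  }
  eos <- 100 * abs(rate_eos) / tot
  c(share_sos = 100 - eos, share_eos = eos)
}
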