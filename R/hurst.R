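#' Replace 3-sigma outliers by linear interpolation
#'
#' Values beyond `mean +/- 3 sd` are replaced by linear interpolation of
#' the neighbouring in-range values (end points by the nearest in-range
#' value), keeping the series equally spaced for rescaled-range analysis.
#' A deletion mode is available for callers that prefer dropping points.
#'
#' @param x numeric series (n >= 4).
#' @param mode `"interpolate"` (default) or `"delete"`.
#' @return cleaned numeric series (shorter when `mode = "delete"`).
#' @export
remove_outliers_3sigma <- function(x, mode = c("interpolate", "delete")) {
  mode <- match.arg(mode)
  if (length(x) < 4L) stop("input error: n must be >= 4", call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(x)
  bad <- abs(x - mean(x)) > 3 * s
  if (!any(bad)) return(x)
  if (mode == "delete") return(x[!bad])
  idx <- which(!bad)
  x[bad] <- stats::approx(idx, x[idx], xout = which(bad), rule = 2L)$y
  x
}

#' Rescaled-range statistic at one scale
#'
#' Partitions the series into `floor(n/p)` non-overlapping subsets of
#' length `p` from the start (any leftover tail discarded). For each
#' subset: mean, cumulative deviations from the mean, range of the
#' cumulative deviations, and the population standard deviation; the
#' subset statistic is range / sd, and the returned value is the mean over
#' subsets. Subsets with zero standard deviation are skipped with a
#' warning.
#'
#' @param x numeric series.
#' @param p subset length (scale), `1 < p <= length(x)`.
#' @return mean rescaled range `(R/S)_p`, or `NA` if no subset is usable.
#' @export
rs_statistic <- function(x, p) {
  n <- length(x)
  if (p > n) stop("input error: scale p exceeds series length",
                  call. = FALSE)
  if (p < 2L) stop("input error: scale p must be at least 2", call. = FALSE)
  nk <- n %/% p
  ratios <- numeric(0L)
  skipped <- 0L
  for (k in seq_len(nk)) {
    y <- x[((k - 1L) * p + 1L):(k * p)]
    mu <- mean(y)
    z <- cumsum(y - mu)
    r <- max(z) - min(z)
    s <- sqrt(mean((y - mu)^2))        # population (1/p) form
    if (s == 0) { skipped <- skipped + 1L; next }
    ratios <- c(ratios, r / s)
  }
  if (skipped > 0L) {
    warning(skipped, " subset(s) with zero standard deviation skipped")
  }
  if (!length(ratios)) return(NA_real_)
  mean(ratios)
}

#' Hurst exponent by rescaled-range analysis
#'
#' OLS slope of `log((R/S)_p)` on `log(p)` over a set of scales. The
#' default scale set is powers of two from `max(8, n/32)` up to `n/4`:
#' rescaled ranges at very small subset lengths are biased upward
#' (the classical small-sample R/S bias), so for long series the default
#' drops them. Passing an explicit `scales` vector overrides the length
#' guard (with a fragility warning below 64 points — R/S estimates on
#' short records are noisy and small-sample biased).
#'
#' @param x numeric series.
#' @param scales integer vector of subset lengths; `NULL` (default) uses
#'   powers of two from `max(8, length(x)/32)` to `length(x)/4`.
#' @param clean apply [remove_outliers_3sigma()] first (default TRUE).
#' @return object of class `hurst_result`: list with `h`, `intercept`,
#'   `fit_r2`, `scales_used`, `rs_values`, `n_effective`.
#' @export
hurst_exponent <- function(x, scales = NULL, clean = TRUE) {
  x <- x[is.finite(x)]
  if (is.null(scales)) {
    if (length(x) < 64L) {
      stop("input error: series shorter than 64; supply explicit `scales`",
           call. = FALSE)
    }
    lo <- max(3, floor(log2(length(x) / 32)))
    scales <- 2^(lo:floor(log2(length(x) / 4)))
  } else if (length(x) < 64L) {
    warning("R/S Hurst estimate on a short series (n = ", length(x),
            ") is statistically fragile")
  }
  if (clean && length(x) >= 4L) x <- remove_outliers_3sigma(x)
  scales <- scales[scales <= length(x)]
  rs <- vapply(scales, function(p) rs_statistic(x, p), numeric(1L))
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 4L) {
    stop("fewer than 4 usable scales; R/S fit failed", call. = FALSE)
  }
  lx <- log(scales[ok]); ly <- log(rs[ok])
  fit <- stats::lm.fit(cbind(1, lx), ly)
  res <- fit$residuals
  r2 <- 1 - sum(res^2) / sum((ly - mean(ly))^2)
  structure(list(h = unname(fit$coefficients[2L]),
                 intercept = unname(fit$coefficients[1L]),
                 fit_r2 = r2, scales_used = scales[ok],
                 rs_values = rs[ok], n_effective = length(x)),
            class = "hurst_result")
}

#' @export
print.hurst_result <- function(x, ...) {
  cat(sprintf("<hurst_result> H = %.3f (r2 = %.3f, %d scales, n = %d)\n",
              x$h, x$fit_r2, length(x$scales_used), x$n_effective))
  invisible(x)
}

FUTURE_TREND_CLASSES <- c("Increase", "Decrease", "Stable", "Uncertain")

#' Future-trend classification from Hurst exponent and trend slope
#'
#' Combines the historical EOS Theil-Sen slope (d/a) with the Hurst
#' exponent's persistence bands (H > 0.6 continuation, H < 0.4 reversal,
#' 0.4 < H < 0.6 uncertain) into the 3x3 grid:
#'
#' * |slope| < 0.5 — Stable, whatever H
#' * slope > 0.5: H > 0.6 Increase, H < 0.4 Decrease, else Uncertain
#' * slope < -0.5: H > 0.6 Decrease, H < 0.4 Increase, else Uncertain
#'
#' Boundary values (slope exactly +/-0.5, H exactly 0.4 or 0.6) fall in
#' the adjacent Stable/Uncertain cell — the conservative choice, since the
#' scheme is written with strict inequalities.
#'
#' @param slope_eos Theil-Sen slope of EOS (d/a), vectorised.
#' @param h Hurst exponent, vectorised.
#' @return factor with levels Increase, Decrease, Stable, Uncertain; `NA`
#'   for non-finite input.
#' @export
classify_future_trend <- function(slope_eos, h) {
  n <- max(length(slope_eos), length(h))
  slope_eos <- rep_len(slope_eos, n); h <- rep_len(h, n)
  out <- rep(NA_character_, n)
  ok <- is.finite(slope_eos) & is.finite(h)
  out[ok & abs(slope_eos) <= 0.5] <- "Stable"
  up <- ok & slope_eos > 0.5
  dn <- ok & slope_eos < -0.5
  out[up & h > 0.6] <- "Increase"
  out[up & h < 0.4] <- "Decrease"
  out[up & h >= 0.4 & h <= 0.6] <- "Uncertain"
  out[dn & h > 0.6] <- "Decrease"
  out[dn & h < 0.4] <- "Increase"
  out[dn & h >= 0.4 & h <= 0.6] <- "Uncertain"
  factor(out, levels = FUTURE_TREND_CLASSES)
}

#' Area shares of Hurst intervals and future-trend classes
#'
#' Percentages of defined pixels in the persistence bands
#' `H < 0.4`, `0.4 - 0.6`, `> 0.6`, and per future-trend class; each
#' table's shares sum to 100 over defined pixels.
#'
#' @param h_map numeric matrix of Hurst exponents.
#' @param class_map aligned factor/character matrix from
#'   [classify_future_trend()] (optional).
#' @return list of data.frames `h_intervals` and (if `class_map` given)
#'   `classes`.
#' @export
hurst_area_shares <- function(h_map, class_map = NULL) {
  h <- c(h_map)
  ok <- is.finite(h)
  if (!any(ok)) stop("all pixels masked", call. = FALSE)
  bands <- cut(h[ok], breaks = c(-Inf, 0.4, 0.6, Inf),
               labels = c("H<0.4", "0.4-0.6", "H>0.6"))
  tab <- table(bands)
  out <- list(h_intervals = data.frame(
    interval = names(tab), n = as.integer(tab),
    share_pct = 100 * as.integer(tab) / sum(tab)))
  if (!is.null(class_map)) {
    cl <- factor(c(as.character(class_map)), levels = FUTURE_TREND_CLASSES)
    cl <- cl[!is.na(cl)]
    ct <- table(cl)
    out$classes <- data.frame(
      class = names(ct), n = as.integer(ct),
      share_pct = 100 * as.integer(ct) / sum(ct))
  }
  out
}
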