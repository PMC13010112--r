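#' Pearson product-moment correlation
#'
#' Thin wrapper over [stats::cor()] with pairwise-complete handling and
#' the degenerate-input policy the pipeline needs (zero variance ->
#' `NA`).
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @return correlation coefficient, or `NA` if undefined.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])
}

#' First-order partial correlation from three pairwise correlations
#'
#' `R(VL|M) = (R_VL - R_VM R_LM) / sqrt((1 - R_VM^2) (1 - R_LM^2))`: the
#' correlation between V and L with M held fixed. The counterpart
#' `R(VM|L)` is obtained by swapping the roles of `r_vm` and `r_vl` (and
#' conditioning on L).
#'
#' @param r_vl correlation between target pair (e.g. EOS and GLST).
#' @param r_vm correlation between V and the controlled variable.
#' @param r_lm correlation between L and the controlled variable.
#' @return partial correlation in `[-1, 1]`; `NA` when a denominator term
#'   vanishes (`|r_vm|` or `|r_lm|` = 1).
#' @export
partial_correlation <- function(r_vl, r_vm, r_lm) {
  denom <- sqrt((1 - r_vm^2) * (1 - r_lm^2))
  out <- (r_vl - r_vm * r_lm) / denom
  out[denom == 0] <- NA_real_
  out
}

#' Significance of a first-order partial correlation
#'
#' Student-t transform with `n - 3` degrees of freedom (one fewer than the
#' plain correlation, accounting for the controlled variable):
#' `t = r sqrt((n - 3) / (1 - r^2))`, two-sided.
#'
#' @param r partial correlation coefficient.
#' @param n sample size (>= 4).
#' @return two-sided p value.
#' @export
partial_corr_significance <- function(r, n) {
  if (n < 4L) stop("input error: n must be >= 4", call. = FALSE)
  p <- rep(NA_real_, length(r))
  lim <- is.finite(r) & abs(r) >= 1
  p[lim] <- 0
  ok <- is.finite(r) & abs(r) < 1
  tval <- r[ok] * sqrt((n - 3) / (1 - r[ok]^2))
  p[ok] <- 2 * stats::pt(abs(tval), df = n - 3, lower.tail = FALSE)
  p
}

#' Partial correlation between two series controlling a third
#'
#' Convenience composition: computes the three pairwise Pearson
#' correlations on complete cases and plugs them into
#' [partial_correlation()], with the t-based p value.
#'
#' @param v,l,m numeric vectors (target pair `v`, `l`; control `m`).
#' @return list: `r_partial`, `n`, `p_value`, plus the three pairwise
#'   correlations.
#' @export
partial_corr_series <- function(v, l, m) {
  ok <- is.finite(v) & is.finite(l) & is.finite(m)
  v <- v[ok]; l <- l[ok]; m <- m[ok]
  n <- length(v)
  if (n < 4L) {
    return(list(r_partial = NA_real_, n = n, p_value = NA_real_))
  }
  r_vl <- pearson_r(v, l); r_vm <- pearson_r(v, m); r_lm <- pearson_r(l, m)
  rp <- partial_correlation(r_vl, r_vm, r_lm)
  list(r_partial = rp, n = n,
       p_value = if (is.na(rp)) NA_real_ else
         partial_corr_significance(rp, n),
       r_vl = r_vl, r_vm = r_vm, r_lm = r_lm)
}

#' Binned partial-correlation response profiles
#'
#' Splits pooled pixel-year samples into bins of a conditioning variable
#' and, within each bin, computes both first-order partial correlations:
#' response ~ temperature controlling moisture, and response ~ moisture
#' controlling temperature. This is how the temperature-dependence of the
#' EOS response is profiled (e.g. GLST bins below 270 K, 270-280 K,
#' 280-295 K, above 295 K).
#'
#' @param eos response samples (e.g. EOS in DOY).
#' @param glst temperature samples (K), aligned with `eos`.
#' @param gem moisture samples, aligned with `eos`.
#' @param bin_by which variable defines the bins: `"glst"` (default) or
#'   `"gem"`.
#' @param bin_edges inner bin edges; defaults `c(270, 280, 295)` K for
#'   GLST and `c(0.20, 0.60, 0.70)` for GEM.
#' @param min_n bins with fewer samples are reported as undefined
#'   (default 10).
#' @return data.frame: bin label, n, `r_eos_glst` (controlling GEM),
#'   `p_eos_glst`, `r_eos_gem` (controlling GLST), `p_eos_gem`.
#' @export
binned_partial_profiles <- function(eos, glst, gem,
                                    bin_by = c("glst", "gem"),
                                    bin_edges = NULL, min_n = 10L) {
  bin_by <- match.arg(bin_by)
  if (is.null(bin_edges)) {
    bin_edges <- if (bin_by == "glst") c(270, 280, 295) else
      c(0.20, 0.60, 0.70)
  }
  cond <- if (bin_by == "glst") glst else gem
  edges <- c(-Inf, bin_edges, Inf)
  labels <- paste0("(", utils::head(edges, -1L), ",",
                   utils::tail(edges, -1L), "]")
  bin <- findInterval(cond, bin_edges, left.open = TRUE) + 1L
  rows <- lapply(seq_along(labels), function(b) {
    idx <- which(bin == b & is.finite(eos) & is.finite(glst) &
                   is.finite(gem))
    if (length(idx) < min_n) {
      return(data.frame(bin = labels[b], n = length(idx),
                        r_eos_glst = NA_real_, p_eos_glst = NA_real_,
                        r_eos_gem = NA_real_, p_eos_gem = NA_real_))
    }
    a <- partial_corr_series(eos[idx], glst[idx], gem[idx])
    d <- partial_corr_series(eos[idx], gem[idx], glst[idx])
    data.frame(bin = labels[b], n = length(idx),
               r_eos_glst = a$r_partial, p_eos_glst = a$p_value,
               r_eos_gem = d$r_partial, p_eos_gem = d$p_value)
  })
  do.call(rbind, rows)
}
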