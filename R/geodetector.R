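#' Quantile discretization of a continuous driver
#'
#' Cuts a continuous variable at its empirical `k / n_strata` quantiles
#' (k = 1..n_strata-1) so each stratum holds approximately 20% of the
#' sample for the default five strata. Ties at a boundary go to the lower
#' stratum. With fewer distinct values than strata the effective stratum
#' count collapses, with a warning.
#'
#' @param values numeric vector or matrix (NA allowed).
#' @param n_strata number of strata (default 5).
#' @return integer labels (1..W) with the shape of `values`; attribute
#'   `W` gives the effective stratum count.
#' @export
quantile_discretize <- function(values, n_strata = 5L) {
  v <- c(values)
  ok <- is.finite(v)
  qs <- stats::quantile(v[ok], probs = seq_len(n_strata - 1L) / n_strata,
                        names = FALSE, type = 7)
  qs <- unique(qs)
  if (length(qs) < n_strata - 1L) {
    warning("fewer distinct values than strata; collapsed to ",
            length(qs) + 1L, " strata")
  }
  lab <- rep(NA_integer_, length(v))
  # ties at a boundary fall in the lower stratum (right-closed intervals)
  lab[ok] <- findInterval(v[ok], qs, left.open = TRUE) + 1L
  lab <- as.integer(factor(lab))  # re-index in case a stratum emptied
  out <- if (is.null(dim(values))) lab else array(lab, dim = dim(values))
  attr(out, "W") <- max(lab, na.rm = TRUE)
  out
}

#' Explanatory-strength label for a Q value
#'
#' Strong for `Q > 0.55`, moderate for `0.35 <= Q <= 0.55`, weak for
#' `Q < 0.35` (both boundary values are moderate).
#'
#' @param q Q statistic in `[0, 1]` (vectorised).
#' @return character vector of labels.
#' @export
q_strength <- function(q) {
  ifelse(!is.finite(q), NA_character_,
         ifelse(q > 0.55, "strong", ifelse(q >= 0.35, "moderate", "weak")))
}

#' Geodetector factor detector (Q statistic)
#'
#' Spatial-stratified-heterogeneity statistic
#' `Q = 1 - sum_U D_U * var_U / (D * var) = 1 - SSW / SST`: the share of
#' the response's variance explained by a categorical stratification.
#' Within- and total variances use the same (population) convention so the
#' ratio is exactly the sum-of-squares ratio. Q lies in `[0, 1]`;
#' explanatory strength is labelled strong (`Q > 0.55`), moderate
#' (`0.35 <= Q <= 0.55`) or weak (`Q < 0.35`).
#'
#' @param response numeric vector/matrix of the dependent variable.
#' @param strata integer labels aligned with `response`.
#' @return object of class `q_result`: list with `q`, `strength`,
#'   `n_total`, `strata` (per-stratum n, mean, sum of squared deviations),
#'   `ssw`, `sst`.
#' @export
factor_q <- function(response, strata) {
  x <- c(response); g <- c(strata)
  if (length(x) != length(g)) {
    stop("input error: response and strata are not aligned", call. = FALSE)
  }
  ok <- is.finite(x) & !is.na(g)
  x <- x[ok]; g <- g[ok]
  n <- length(x)
  if (n < 2L) stop("input error: fewer than 2 valid samples", call. = FALSE)
  sst <- sum((x - mean(x))^2)
  if (sst == 0) {
    return(structure(list(q = NA_real_, strength = NA_character_,
                          n_total = n, strata = NULL, ssw = 0, sst = 0),
                     class = "q_result"))
  }
  sp <- split(x, g)
  tab <- data.frame(
    stratum = names(sp),
    n = vapply(sp, length, integer(1L)),
    mean = vapply(sp, mean, numeric(1L)),
    ss = vapply(sp, function(v) sum((v - mean(v))^2), numeric(1L)),
    row.names = NULL)
  ssw <- sum(tab$ss)
  q <- 1 - ssw / sst
  structure(list(q = q, strength = q_strength(q), n_total = n, strata = tab,
                 ssw = ssw, sst = sst),
            class = "q_result")
}

#' @export
print.q_result <- function(x, ...) {
  cat(sprintf("<q_result> Q = %.4f (%s), W = %d strata, n = %d\n",
              x$q, x$strength, NROW(x$strata), x$n_total))
  invisible(x)
}

#' Significance of a Q statistic
#'
#' Default: permutation test — the stratum labels are reshuffled
#' `n_perm` times and the p value is the rank of the observed Q among the
#' permuted ones, `p = (1 + #(Q_perm >= Q_obs)) / (n_perm + 1)`. The
#' `"f"` method is the noncentral-F approximation from the geodetector
#' methodology literature (an external formula, not part of this
#' pipeline's own derivation): `F = (D - W)/(W - 1) * Q/(1 - Q)` with
#' noncentrality `lambda = (sum_U mean_U^2 - (sum_U sqrt(D_U) mean_U)^2 /
#' D) / (SST / D)`, referred to `F(W-1, D-W; lambda)`.
#'
#' @param response,strata as in [factor_q()].
#' @param method `"permutation"` (default) or `"f"`.
#' @param n_perm permutations (>= 99).
#' @param seed optional seed for the permutation test.
#' @return the [factor_q()] result with `p_value` and `p_method` added.
#' @export
q_significance <- function(response, strata, method = c("permutation", "f"),
                           n_perm = 999L, seed = NULL) {
  method <- match.arg(method)
  qr <- factor_q(response, strata)
  if (!is.finite(qr$q) || NROW(qr$strata) < 2L) {
    qr$p_value <- NA_real_
    qr$p_method <- method
    return(qr)
  }
  x <- c(response); g <- c(strata)
  ok <- is.finite(x) & !is.na(g)
  x <- x[ok]; g <- g[ok]
  if (method == "permutation") {
    if (n_perm < 99L) {
      stop("configuration error: n_perm must be >= 99", call. = FALSE)
    }
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (factor_q(x, sample(g))$q >= qr$q) hits <- hits + 1L
    }
    qr$p_value <- (1 + hits) / (n_perm + 1)
  } else {
    tab <- qr$strata
    d <- qr$n_total; w <- NROW(tab)
    f <- (d - w) / (w - 1) * qr$q / (1 - qr$q)
    lambda <- (sum(tab$mean^2) -
                 sum(sqrt(tab$n) * tab$mean)^2 / d) / (qr$sst / d)
    qr$p_value <- stats::pf(f, w - 1, d - w, ncp = lambda,
                            lower.tail = FALSE)
  }
  qr$p_method <- method
  qr
}

#' Geodetector interaction detector
#'
#' Overlays two stratifications (distinct label pairs become strata),
#' computes Q on the overlay, and labels the interaction by comparing
#' `Q(A intersect B)` with `Q(A)`, `Q(B)` and `Q(A) + Q(B)` using the
#' standard five-category scheme: nonlinear-weaken, single-nonlinear-weaken,
#' bivariate-enhance, independent, nonlinear-enhance.
#'
#' @param response numeric response.
#' @param strata_a,strata_b aligned integer stratifications.
#' @return list: `q_ab` ([factor_q()] result on the overlay), `q_a`, `q_b`
#'   (scalars), `relation` (character).
#' @export
interaction_q <- function(response, strata_a, strata_b) {
  ga <- c(strata_a); gb <- c(strata_b)
  if (length(ga) != length(gb)) {
    stop("input error: strata maps are not aligned", call. = FALSE)
  }
  overlay <- interaction(ga, gb, drop = TRUE)
  q_ab <- factor_q(response, as.integer(overlay))
  qa <- factor_q(response, ga)$q
  qb <- factor_q(response, gb)$q
  q <- q_ab$q
  relation <-
    if (q < min(qa, qb)) "nonlinear-weaken"
    else if (q < max(qa, qb)) "single-nonlinear-weaken"
    else if (q < qa + qb) "bivariate-enhance"
    else if (q == qa + qb) "independent"
    else "nonlinear-enhance"
  list(q_ab = q_ab, q_a = qa, q_b = qb, relation = relation)
}

#' Run the full detector suite over period windows
#'
#' For each period window (e.g. 2001-2005, ..., 2016-2020): average the
#' response and each driver layer over the window's years, discretize each
#' driver into quantile strata, and compute every single-factor Q and
#' every pairwise interaction Q.
#'
#' @param response a [year_stack] (e.g. SOS, EOS or LOS).
#' @param drivers named list of [year_stack] driver layers (e.g. GEM,
#'   GLST, GSA, GPRE, GAT, GSD, GWS, GRA).
#' @param windows list of `c(first_year, last_year)` pairs (inclusive);
#'   default: consecutive 5-year blocks covering the response years.
#' @param n_strata strata per driver (default 5).
#' @return list of data.frames: `factors` (window, driver, q, strength),
#'   `interactions` (window, driver_a, driver_b, q, relation).
#' @export
run_detector_suite <- function(response, drivers, windows = NULL,
                               n_strata = 5L) {
  yrs <- response$years
  if (is.null(windows)) {
    starts <- seq(min(yrs), max(yrs), by = 5L)
    windows <- lapply(starts, function(s) c(s, min(s + 4L, max(yrs))))
  }
  window_mean <- function(ys, win) {
    keep <- ys$years >= win[1L] & ys$years <= win[2L]
    if (!any(keep)) return(NULL)
    colMeans(stack_matrix(ys)[keep, , drop = FALSE], na.rm = TRUE)
  }
  fac <- list(); inter <- list()
  for (w in seq_along(windows)) {
    win <- windows[[w]]
    wname <- paste0(win[1L], "-", win[2L])
    resp <- window_mean(response, win)
    strat <- list()
    for (dn in names(drivers)) {
      dv <- window_mean(drivers[[dn]], win)
      if (is.null(dv)) {
        warning("driver ", dn, " missing in window ", wname, "; skipped")
        next
      }
      strat[[dn]] <- quantile_discretize(dv, n_strata)
      qr <- factor_q(resp, strat[[dn]])
      fac[[length(fac) + 1L]] <- data.frame(
        window = wname, driver = dn, q = qr$q, strength = qr$strength)
    }
    dns <- names(strat)
    if (length(dns) >= 2L) {
      pairs <- utils::combn(dns, 2L)
      for (p in seq_len(ncol(pairs))) {
        a <- pairs[1L, p]; b <- pairs[2L, p]
        iq <- interaction_q(resp, strat[[a]], strat[[b]])
        inter[[length(inter) + 1L]] <- data.frame(
          window = wname, driver_a = a, driver_b = b,
          q = iq$q_ab$q, q_a = iq$q_a, q_b = iq$q_b,
          relation = iq$relation)
      }
    }
  }
  list(factors = do.call(rbind, fac), interactions = do.call(rbind, inter))
}
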