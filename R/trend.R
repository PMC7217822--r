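# Progression statistics: ordinary and weighted least-squares trend
# analysis of the mTD, future-value prediction, pointwise linear regression
# and the binomial whole-field test, each available with
# inverse-reconstruction-error weights.

# closed-form weighted simple linear regression with the classical t-test
# on the slope; the fast path shared by every fit in the package
.wls <- function(t, y, w) {
  keep <- w > 0
  n_pos <- sum(keep)
  if (n_pos < 2 || length(unique(t[keep])) < 2)
    stop("degenerate design: need positive weight at >= 2 distinct times")
  sw <- sum(w)
  tbar <- sum(w * t) / sw
  ybar <- sum(w * y) / sw
  sxx <- sum(w * (t - tbar)^2)
  slope <- sum(w * (t - tbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * tbar
  n <- length(t)
  df <- n - 2L
  if (df > 0) {
    rss <- sum(w * (y - intercept - slope * t)^2)
    se <- sqrt(rss / df / sxx)
    if (se == 0) {
      tstat <- if (slope == 0) 0 else sign(slope) * Inf
    } else {
      tstat <- slope / se
    }
    p_two <- 2 * stats::pt(-abs(tstat), df)
    p_less <- stats::pt(tstat, df)
  } else {
    se <- NA_real_; tstat <- NA_real_; p_two <- NA_real_; p_less <- NA_real_
  }
  list(slope = slope, intercept = intercept, slope_se = se, t_stat = tstat,
       slope_p = p_two, p_less = p_less, n = n, df = df)
}

.as_trend_fit <- function(fit, t, y, w) {
  structure(list(slope = fit$slope, intercept = fit$intercept,
                 slope_se = fit$slope_se, slope_p = fit$slope_p,
                 p_deterioration = fit$p_less, n = fit$n,
                 t = t, y = y, weights = w),
            class = "trend_fit")
}

#' Ordinary least-squares linear trend
#'
#' Fits `y = intercept + slope * t` by minimising the sum of squared
#' residuals; the two-sided p-value of the slope comes from the t
#' distribution on n - 2 degrees of freedom.
#'
#' @param t Times in years.
#' @param y Response (e.g. mTD), dB.
#' @return An object of class `trend_fit` with `slope`, `intercept`,
#'   `slope_se`, `slope_p` (two-sided), `p_deterioration` (one-sided,
#'   slope < 0), `n` and the unit `weights` used.
#' @examples
#' ols_fit(0:2, c(0, -1, -2))$slope  # -1
#' @export
ols_fit <- function(t, y) {
  stopifnot(length(t) == length(y), all(is.finite(t)), all(is.finite(y)))
  w <- rep(1, length(t))
  .as_trend_fit(.wls(t, y, w), t, y, w)
}

#' Weighted least-squares linear trend
#'
#' Minimises the sum of squared weighted residuals
#' `sum(w * (y - intercept - slope * t)^2)`. Equal weights of any positive
#' value reproduce [ols_fit()] exactly; rescaling all weights leaves the
#' fit unchanged.
#'
#' @inheritParams ols_fit
#' @param w Nonnegative weights, one per observation; at least two strictly
#'   positive weights at distinct times are required.
#' @return A `trend_fit` (see [ols_fit()]).
#' @export
weighted_fit <- function(t, y, w) {
  stopifnot(length(t) == length(y), length(w) == length(y),
            all(is.finite(t)), all(is.finite(y)), all(is.finite(w)))
  if (any(w < 0)) stop("weights must be nonnegative")
  .as_trend_fit(.wls(t, y, w), t, y, w)
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> slope %.3f dB/y (SE %.3f, p %.4g), n = %d\n",
              x$slope, x$slope_se, x$slope_p, x$n))
  invisible(x)
}

#' Weighting scheme for trend analysis
#'
#' `"unweighted"` uses unit weights. `"vae_mtd"` weights each exam by the
#' reciprocal of the absolute difference between its mTD and the mTD of the
#' VAE reconstruction. `"vae_pointwise"` weights each (exam, point) pair by
#' the reciprocal of the absolute TD reconstruction error at that point,
#' for pointwise regressions. The absolute difference is floored at
#' `epsilon` so weights stay finite when the reconstruction is exact; the
#' floor also caps the dynamic range of the weights, which matters because
#' the reconstruction error only estimates the measurement error - a very
#' small floor would let weight ratios of 100:1 arise from estimation noise
#' alone.
#'
#' @param mode One of `"unweighted"`, `"vae_mtd"`, `"vae_pointwise"`.
#' @param epsilon Floor on the absolute difference, dB (default 0.5).
#' @return An object of class `weight_scheme`.
#' @export
weight_scheme <- function(mode = c("unweighted", "vae_mtd", "vae_pointwise"),
                          epsilon = 0.5) {
  mode <- match.arg(mode)
  if (epsilon <= 0) stop("`epsilon` must be positive")
  structure(list(mode = mode, epsilon = epsilon), class = "weight_scheme")
}

#' Inverse-reconstruction-error weights for a series
#'
#' Implements the reciprocal-difference weights: per exam
#' `w_i = 1 / max(epsilon, |mTD_i - mTD_VAE_i|)` in `"vae_mtd"` mode, or
#' per exam and point `w_ij = 1 / max(epsilon, |TD_ij - TD_VAE_ij|)` in
#' `"vae_pointwise"` mode. `"unweighted"` gives unit weights.
#'
#' @param series A [vf_series()] of measured fields.
#' @param recon The VAE reconstruction of the same series
#'   ([vae_reconstruct()]), aligned exam-for-exam; may be `NULL` in
#'   unweighted mode.
#' @param scheme A [weight_scheme()].
#' @return A vector of per-exam weights (`unweighted`, `vae_mtd`) or an
#'   n x 52 matrix (`vae_pointwise`).
#' @export
vae_weights <- function(series, recon = NULL,
                        scheme = weight_scheme("vae_mtd")) {
  n <- length(series)
  if (scheme$mode == "unweighted") return(rep(1, n))
  if (is.null(recon)) stop("`recon` is required for VAE weighting")
  if (length(recon) != n || any(abs(recon$t - series$t) > 1e-9))
    stop("series and reconstruction are not aligned exam-for-exam")
  if (scheme$mode == "vae_mtd") {
    d <- abs(compute_mtd(series) - compute_mtd(recon))
    1 / pmax(d, scheme$epsilon)
  } else {
    d <- abs(series$td - recon$td)   # data first so the matrix shape survives
    1 / pmax(d, scheme$epsilon)
  }
}

#' mTD trend analysis of one series
#'
#' Regresses the per-exam mTD on time, optionally with
#' inverse-reconstruction-error weights, and classifies the series as
#' significantly progressing when the slope is negative with two-sided
#' p below `sig_p`.
#'
#' @param series A [vf_series()] with at least 2 exams (3 for a p-value).
#' @param scheme A [weight_scheme()]; `"vae_pointwise"` is reduced to
#'   per-exam weights by the exam mean of the pointwise weights.
#' @param recon VAE reconstruction of `series` (needed for VAE modes).
#' @param sig_p Two-sided significance threshold on the slope, default 0.05.
#' @return A `trend_fit` with an extra logical element `significant`.
#' @export
mtd_trend <- function(series, scheme = weight_scheme("unweighted"),
                      recon = NULL, sig_p = 0.05) {
  w <- vae_weights(series, recon, scheme)
  if (is.matrix(w)) w <- rowMeans(w)
  fit <- weighted_fit(series$t, compute_mtd(series), w)
  fit$significant <- is.finite(fit$slope_p) &&
    fit$slope < 0 && fit$slope_p < sig_p
  fit
}

#' Predict a future mTD from a truncated series
#'
#' Fits the (weighted) mTD trend on the first `k` exams and extrapolates
#' the regression line to `t_target`.
#'
#' @param series A [vf_series()].
#' @param k Number of leading exams to use (>= 2).
#' @param t_target Time at which to predict, years.
#' @inheritParams mtd_trend
#' @return Predicted mTD at `t_target`, dB.
#' @export
predict_future_mtd <- function(series, k, t_target,
                               scheme = weight_scheme("unweighted"),
                               recon = NULL) {
  if (k < 2) stop("`k` must be at least 2")
  s <- vf_truncate(series, k)
  r <- if (!is.null(recon)) vf_truncate(recon, k) else NULL
  fit <- mtd_trend(s, scheme, r)
  fit$intercept + fit$slope * t_target
}

#' Pointwise linear regression (PLR)
#'
#' Regresses the TD of each of the 52 test points on time, optionally with
#' per-point inverse-reconstruction-error weights, and returns a one-sided
#' deterioration p-value per point: the probability under the null
#' hypothesis of zero slope of a slope t-statistic at least as negative as
#' observed. Under the null these p-values are uniform, which is what the
#' binomial whole-field test requires. A point with zero residual variance
#' gets p = 0.5 / 0 / 1 for slope = 0 / < 0 / > 0 (the limit of the t-test).
#'
#' @param series A [vf_series()] with at least 3 exams.
#' @param scheme A [weight_scheme()]; `"vae_mtd"` applies the same per-exam
#'   weight to every point, `"vae_pointwise"` uses each point's own weights.
#' @param recon VAE reconstruction of `series` (for VAE modes).
#' @param alternative `"less"` (deterioration, default) or `"two.sided"`.
#' @return A data frame with one row per point: `point`, `slope`, `se`,
#'   `p`.
#' @export
pointwise_plr <- function(series, scheme = weight_scheme("unweighted"),
                          recon = NULL, alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(series) < 3) stop("PLR needs at least 3 exams")
  w <- vae_weights(series, recon, scheme)
  if (!is.matrix(w)) w <- matrix(w, length(series), N_POINTS)
  t <- series$t
  out <- matrix(NA_real_, N_POINTS, 3)
  for (j in seq_len(N_POINTS)) {
    fit <- .wls(t, series$td[, j], w[, j])
    out[j, ] <- c(fit$slope, fit$slope_se,
                  if (alternative == "less") fit$p_less else fit$slope_p)
  }
  data.frame(point = seq_len(N_POINTS), slope = out[, 1], se = out[, 2],
             p = out[, 3])
}

#' Binomial whole-field test on PLR p-values
#'
#' If no point truly deteriorates, the 52 one-sided PLR p-values are
#' uniform, so the number below a cutoff `c` is Binomial(52, c). For each
#' cutoff in (0.025, 0.05, 0.075, 0.1) the upper tail probability
#' `P(X >= k)` of the observed count `k` (strict inequality `p < c`) is
#' computed exactly; the representative `median_p` is the mean of the two
#' middle values of the four tail probabilities, and the series is called
#' significant when `median_p < 0.025`.
#'
#' @param per_point_p Numeric vector of exactly 52 p-values in [0, 1]
#'   (e.g. column `p` of [pointwise_plr()]).
#' @param sig_level Threshold on `median_p` for the significance call,
#'   default 0.025.
#' @return An object of class `binomial_plr` with `cutoffs`,
#'   `counts_below`, `binom_p`, `median_p`, `significant`.
#' @export
binomial_plr <- function(per_point_p, sig_level = 0.025) {
  if (length(per_point_p) != N_POINTS)
    stop("`per_point_p` must contain exactly 52 p-values")
  if (any(!is.finite(per_point_p)) || any(per_point_p < 0) ||
      any(per_point_p > 1))
    stop("p-values must lie in [0, 1]")
  cutoffs <- c(0.025, 0.05, 0.075, 0.1)
  k <- vapply(cutoffs, function(c) sum(per_point_p < c), numeric(1))
  binom_p <- stats::pbinom(k - 1, N_POINTS, cutoffs, lower.tail = FALSE)
  median_p <- mean(sort(binom_p)[2:3])
  structure(list(cutoffs = cutoffs, counts_below = as.integer(k),
                 binom_p = binom_p, median_p = median_p,
                 significant = median_p < sig_level),
            class = "binomial_plr")
}

#' Binomial PLR of a series
#'
#' Convenience wrapper chaining [pointwise_plr()] and [binomial_plr()].
#'
#' @inheritParams pointwise_plr
#' @param sig_level Passed to [binomial_plr()].
#' @return A `binomial_plr` object.
#' @export
binomial_plr_series <- function(series, scheme = weight_scheme("unweighted"),
                                recon = NULL, sig_level = 0.025) {
  binomial_plr(pointwise_plr(series, scheme, recon)$p, sig_level)
}

#' @export
print.binomial_plr <- function(x, ...) {
  cat(sprintf("<binomial_plr> counts %s at cutoffs %s; median p %.4g (%s)\n",
              paste(x$counts_below, collapse = "/"),
              paste(x$cutoffs, collapse = "/"), x$median_p,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}
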