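#' Regression reliability metrics
#'
#' Variance-calibration, coverage and proper-scoring metrics for Gaussian
#' and interval prediction sets, plus the binned tables behind variance
#' reliability diagrams and the error-versus-uncertainty bivariate
#' histogram.
#'
#' @name regression-metrics
#' @keywords internal
NULL

#' Variance reliability bin table
#'
#' Bins examples by predicted standard deviation (equal-mass by default,
#' robust to heavy-tailed spread distributions) and reports per bin the
#' root mean predicted variance (RMV) and the root mean squared residual
#' (RMSE) — the two axes of an ENCE reliability diagram.
#'
#' @param gps a [gaussian_predictions()] set.
#' @param n_bins number of bins (default 10).
#' @param scheme `"equal-mass"` (default) or `"equal-width"` over the
#'   predicted-sigma range.
#' @return data frame with `bin_id`, `sigma_lo`, `sigma_hi`, `count`,
#'   `rmv`, `rmse` for each nonempty bin.
#' @export
bin_table_reg <- function(gps, n_bins = 10,
                          scheme = c("equal-mass", "equal-width")) {
  validate_predictions(gps)
  scheme <- match.arg(scheme)
  if (n_examples(gps) < n_bins)
    stop("need at least n_bins examples")
  s <- sqrt(gps$var)
  ba <- bin_assign(s, n_bins, scheme, range(s))
  res2 <- (gps$y_true - gps$mu)^2
  ids <- sort(unique(ba$bin))
  data.frame(
    bin_id = ids,
    sigma_lo = vapply(ids, function(b) min(s[ba$bin == b]), numeric(1)),
    sigma_hi = vapply(ids, function(b) max(s[ba$bin == b]), numeric(1)),
    count = vapply(ids, function(b) sum(ba$bin == b), numeric(1)),
    rmv = vapply(ids, function(b) sqrt(mean(gps$var[ba$bin == b])), numeric(1)),
    rmse = vapply(ids, function(b) sqrt(mean(res2[ba$bin == b])), numeric(1))
  )
}

#' Expected normalized calibration error (ENCE)
#'
#' Per-bin discrepancy between predicted and realised spread:
#' `sum_m w_m |RMV_m - RMSE_m| / RMV_m` over sigma bins, zero when
#' residual magnitudes match predicted standard deviations in every bin.
#' The default is the normalized (divide by RMV) and count-weighted
#' (`w_m = n_m / N`) form; both are exposed as flags, with
#' `weighted = FALSE` averaging bins uniformly and `normalized = FALSE`
#' leaving the discrepancy in target units.
#'
#' @inheritParams bin_table_reg
#' @param normalized divide each bin's discrepancy by its RMV (default
#'   `TRUE`).
#' @param weighted weight bins by their example count (default `TRUE`).
#' @return nonnegative scalar.
#' @export
ence <- function(gps, n_bins = 10, normalized = TRUE, weighted = TRUE,
                 scheme = c("equal-mass", "equal-width")) {
  tab <- bin_table_reg(gps, n_bins, match.arg(scheme))
  if (any(tab$rmv == 0)) stop("bin with zero root mean variance")
  d <- abs(tab$rmv - tab$rmse)
  if (normalized) d <- d / tab$rmv
  w <- if (weighted) tab$count / sum(tab$count) else rep(1 / nrow(tab), nrow(tab))
  sum(w * d)
}

#' Continuous ranked probability score for Gaussian predictions
#'
#' The closed form
#' `CRPS = sigma (z (2 Phi(z) - 1) + 2 phi(z) - 1/sqrt(pi))` with
#' `z = (y - mu)/sigma`, equal to the integrated squared difference
#' between the predictive CDF and the observation's step CDF. Reported in
#' target units; lower is better, and for a point mass it reduces to the
#' absolute error.
#'
#' @param gps a [gaussian_predictions()] set.
#' @param pointwise return the per-example scores instead of their mean.
#' @return nonnegative scalar (or vector when `pointwise`).
#' @export
crps_gaussian <- function(gps, pointwise = FALSE) {
  validate_predictions(gps)
  s <- sqrt(gps$var)
  z <- (gps$y_true - gps$mu) / s
  out <- s * (z * (2 * stats::pnorm(z) - 1) + 2 * stats::dnorm(z) -
                1 / sqrt(pi))
  if (pointwise) out else mean(out)
}

#' Prediction interval coverage probability ratio (PICP)
#'
#' The fraction of observations falling inside their prediction interval,
#' divided by the interval's nominal central coverage. The optimal value
#' is 1; values above 1 indicate over-wide (conservative) intervals,
#' values below 1 under-coverage.
#'
#' @param ips an [interval_predictions()] set, or a
#'   [gaussian_predictions()] set together with `n_sigma` to convert via
#'   [gaussian_to_interval()].
#' @param n_sigma interval halfwidth in predicted sigmas when `ips` is
#'   Gaussian (default 1).
#' @return positive scalar ratio.
#' @export
picp <- function(ips, n_sigma = 1) {
  if (inherits(ips, "gaussian_predictions"))
    ips <- gaussian_to_interval(ips, n_sigma)
  validate_predictions(ips)
  mean(ips$y_true >= ips$lo & ips$y_true <= ips$hi) / ips$nominal_level
}

#' Coverage calibration error (CCE) and coverage curve
#'
#' For each central coverage level `c` in `levels`, the Gaussian central
#' interval `mu +/- qnorm((1 + c)/2) sigma` is formed and its empirical
#' coverage `e_c` measured; `CCE = mean_c (c - e_c)^2`. The observed curve
#' is attached as attribute `"curve"` (and returned directly by
#' `coverage_curve()`), giving the coverage-versus-nominal plot.
#'
#' @param gps a [gaussian_predictions()] set.
#' @param levels ascending central coverage levels in (0,1); default the
#'   19-point grid `seq(0.05, 0.95, by = 0.05)`.
#' @return `cce()`: nonnegative scalar with attribute `"curve"`;
#'   `coverage_curve()`: data frame `level`, `empirical`.
#' @export
cce <- function(gps, levels = seq(0.05, 0.95, by = 0.05)) {
  curve <- coverage_curve(gps, levels)
  out <- mean((curve$level - curve$empirical)^2)
  attr(out, "curve") <- curve
  out
}

#' @rdname cce
#' @export
coverage_curve <- function(gps, levels = seq(0.05, 0.95, by = 0.05)) {
  validate_predictions(gps)
  stopifnot(all(levels > 0), all(levels < 1), !is.unsorted(levels))
  s <- sqrt(gps$var)
  emp <- vapply(levels, function(cl) {
    half <- stats::qnorm((1 + cl) / 2) * s
    mean(abs(gps$y_true - gps$mu) <= half)
  }, numeric(1))
  data.frame(level = levels, empirical = emp)
}

#' Gaussian negative log-likelihood
#'
#' Mean over examples of `0.5 (ln(2 pi var) + (y - mu)^2 / var)`, the
#' proper scoring rule minimised (over a constant variance factor) exactly
#' at the mean squared standardised residual used by
#' [fit_variance_scale_reg()].
#'
#' @param gps a [gaussian_predictions()] set.
#' @return scalar (natural-log units).
#' @export
nll_gaussian <- function(gps) {
  validate_predictions(gps)
  mean(0.5 * (log(2 * pi * gps$var) + (gps$y_true - gps$mu)^2 / gps$var))
}

#' Mean absolute error and its median-scaled form (MASE)
#'
#' `MAE = mean |y - mu|`; `MASE = MAE / mean |y - baseline|`, where the
#' baseline is the constant training-split median of the target. A MASE
#' below 1 means the model beats always predicting the training median.
#' For interval or quantile outputs the point prediction is the interval
#' midpoint, not the median prediction.
#'
#' @param pred a [gaussian_predictions()] set (the predicted mean is
#'   scored) or a bare numeric vector of point predictions.
#' @param baseline_median the training-split median of the target.
#' @param y_true observed targets; required when `pred` is a bare vector.
#' @return list with elements `mae` and `mase`.
#' @examples
#' mae_mase(gaussian_predictions(14.91, 4.38, 1), baseline_median = 0)
#' @export
mae_mase <- function(pred, baseline_median, y_true = NULL) {
  if (inherits(pred, "gaussian_predictions")) {
    y <- pred$y_true; mu <- pred$mu
  } else {
    if (is.null(y_true)) stop("y_true required for bare point predictions")
    y <- as.numeric(y_true); mu <- as.numeric(pred)
  }
  base_mae <- mean(abs(y - baseline_median))
  if (base_mae == 0) stop("baseline MAE is zero; MASE undefined")
  mae <- mean(abs(y - mu))
  list(mae = mae, mase = mae / base_mae)
}

#' Bivariate histogram of prediction error against predicted uncertainty
#'
#' Counts over a rectangular grid of (predicted sigma, absolute residual).
#' For small-scale-reliable predictions the mass concentrates around the
#' diagonal where the error magnitude tracks the predicted spread; the
#' diagonal reference line is attached as attribute `"reference"`.
#'
#' @param gps a [gaussian_predictions()] set.
#' @param n_bins_x,n_bins_y grid resolution along sigma and `|y - mu|`.
#' @return integer matrix of counts (rows = sigma bins, columns = error
#'   bins) with attributes `"x_breaks"`, `"y_breaks"`, `"reference"`.
#' @export
bivariate_error_histogram <- function(gps, n_bins_x = 20, n_bins_y = 20) {
  validate_predictions(gps)
  s <- sqrt(gps$var)
  err <- abs(gps$y_true - gps$mu)
  xb <- seq(min(s), max(s), length.out = n_bins_x + 1)
  yb <- seq(min(err), max(err), length.out = n_bins_y + 1)
  if (xb[1] == xb[n_bins_x + 1]) xb <- xb + seq(0, 1e-9, length.out = n_bins_x + 1)
  if (yb[1] == yb[n_bins_y + 1]) yb <- yb + seq(0, 1e-9, length.out = n_bins_y + 1)
  ix <- findInterval(s, xb, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(err, yb, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, n_bins_x, n_bins_y)
  for (k in seq_along(ix))
    counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  structure(counts, x_breaks = xb, y_breaks = yb,
            reference = "error = sigma diagonal")
}
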