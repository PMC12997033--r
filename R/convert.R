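#' Conversions between probabilistic output types
#'
#' Every uncertainty-quantification technique emits one output type
#' (Gaussian parameters, quantile pairs, or intervals); these conversions
#' let any metric score any technique under a Gaussian assumption on the
#' predictive distribution.
#'
#' `quantiles_to_gaussian()` accepts exactly two quantile levels symmetric
#' about 0.5 (levels `l` and `1 - l`, e.g. the one-standard-deviation band
#' 0.1587/0.8413 or the two-standard-deviation band 0.0228/0.9772). The
#' mean is the midpoint of the two quantiles — not the median prediction —
#' and the standard deviation is the halfwidth divided by the exact
#' standard-normal quantile of the upper level (`qnorm(0.8413)` is 0.99982,
#' not snapped to 1; the difference is below 0.02%). Asymmetric level pairs
#' are rejected rather than heuristically symmetrised.
#'
#' @param qps a [quantile_predictions()] set with two symmetric levels.
#' @param gps a [gaussian_predictions()] set.
#' @param ips an [interval_predictions()] set.
#' @param n_sigma positive interval halfwidth in predicted standard
#'   deviations; the nominal central coverage is `2 * pnorm(n_sigma) - 1`
#'   (0.6827 at one sigma, 0.9545 at two).
#' @param tol tolerance for the symmetry check on quantile levels.
#' @return A prediction set of the target type; `pit_values()` returns a
#'   numeric vector.
#' @examples
#' qps <- quantile_predictions(0, matrix(c(-1, 1), 1),
#'                             levels = c(0.1587, 0.8413))
#' quantiles_to_gaussian(qps) # mu = 0, sigma = 1
#' @export
quantiles_to_gaussian <- function(qps, tol = 1e-9) {
  validate_predictions(qps)
  if (length(qps$levels) != 2)
    stop("conversion requires exactly two quantile levels")
  if (abs(qps$levels[1] + qps$levels[2] - 1) > tol)
    stop("quantile levels must be symmetric about 0.5 (l and 1-l)")
  z <- stats::qnorm(qps$levels[2])
  lo <- qps$q[, 1]; hi <- qps$q[, 2]
  if (any(hi == lo))
    fail_at("degenerate quantile pair gives zero variance", which(hi == lo)[1])
  sigma <- (hi - lo) / (2 * z)
  gaussian_predictions(qps$y_true, mu = (lo + hi) / 2, var = sigma^2)
}

#' @rdname quantiles_to_gaussian
#' @export
gaussian_to_interval <- function(gps, n_sigma = 1) {
  validate_predictions(gps)
  if (n_sigma <= 0) stop("n_sigma must be positive")
  s <- sqrt(gps$var)
  interval_predictions(gps$y_true, lo = gps$mu - n_sigma * s,
                       hi = gps$mu + n_sigma * s,
                       nominal_level = 2 * stats::pnorm(n_sigma) - 1)
}

#' @rdname quantiles_to_gaussian
#' @export
interval_to_gaussian <- function(ips) {
  validate_predictions(ips)
  if (any(ips$hi == ips$lo))
    fail_at("degenerate interval gives zero variance",
            which(ips$hi == ips$lo)[1])
  z <- stats::qnorm((1 + ips$nominal_level) / 2)
  sigma <- (ips$hi - ips$lo) / (2 * z)
  gaussian_predictions(ips$y_true, mu = (ips$lo + ips$hi) / 2, var = sigma^2)
}

#' Probability integral transform of a Gaussian prediction set
#'
#' Evaluates each example's predictive CDF at its observed target:
#' `PIT_i = pnorm((y_i - mu_i) / sigma_i)`. Under perfect probabilistic
#' calibration the PIT values are uniform on (0,1); departures from
#' uniformity drive the isotonic regression recalibration of
#' [fit_isotonic_reg()].
#'
#' @param gps a [gaussian_predictions()] set.
#' @return numeric vector of PIT values in (0,1).
#' @export
pit_values <- function(gps) {
  validate_predictions(gps)
  stats::pnorm((gps$y_true - gps$mu) / sqrt(gps$var))
}

#' Extract symmetric quantiles from a Gaussian prediction set
#'
#' The inverse view of [quantiles_to_gaussian()]: predicted quantiles of
#' each example's Gaussian at a symmetric pair of levels.
#'
#' @param gps a [gaussian_predictions()] set.
#' @param levels two symmetric probabilities (default the one-sigma band).
#' @return a [quantile_predictions()] set.
#' @export
gaussian_to_quantiles <- function(gps, levels = c(0.1587, 0.8413)) {
  validate_predictions(gps)
  s <- sqrt(gps$var)
  q <- vapply(levels, function(l) gps$mu + stats::qnorm(l) * s,
              numeric(n_examples(gps)))
  quantile_predictions(gps$y_true, matrix(q, ncol = length(levels)),
                       levels = levels)
}
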