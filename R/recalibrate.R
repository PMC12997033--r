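#' Post-hoc recalibration of prediction sets
#'
#' All recalibration and conformal methods follow the same split protocol:
#' parameters are fitted on a held-out calibration set and then applied to
#' a disjoint test set. The calibration and test sets are passed as two
#' prediction sets of matching type; keeping them disjoint is the caller's
#' responsibility.
#'
#' @name recalibration
#' @keywords internal
NULL

PROB_EPS <- 1e-6

clip_prob <- function(p, eps = PROB_EPS) pmin(pmax(p, eps), 1 - eps)

check_both_classes <- function(ps) {
  if (length(unique(ps$y_true)) < 2)
    stop("calibration set must contain both classes")
}

#' Temperature scaling for binary classifiers
#'
#' Fits a single temperature `T > 0` minimising the mean negative
#' log-likelihood of the calibration labels under
#' `p(T) = plogis(qlogis(p1) / T)`, by bounded scalar search on
#' `T in [0.05, 20]`, and divides the test logits by the fitted
#' temperature. `T > 1` softens overconfident probabilities towards 0.5;
#' `T < 1` sharpens underconfident ones. Temperature is fitted on the
#' aggregated (post-ensemble) probability, not per member.
#'
#' @param calib,test [binary_predictions()] sets; `calib` must contain
#'   both classes.
#' @return list with `temperature` (fitted scalar), `test` (transformed
#'   test set) and `calib_nll` (mean NLL at the optimum).
#' @export
fit_temperature_cls <- function(calib, test) {
  validate_predictions(calib); validate_predictions(test)
  check_both_classes(calib)
  z <- stats::qlogis(clip_prob(calib$p1))
  y <- calib$y_true
  nll <- function(Tm) {
    p <- clip_prob(stats::plogis(z / Tm))
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  opt <- stats::optimize(nll, interval = c(0.05, 20), tol = 1e-8)
  Tm <- opt$minimum
  p_new <- clip_prob(stats::plogis(stats::qlogis(clip_prob(test$p1)) / Tm))
  out <- binary_predictions(test$y_true, p_new,
                            logit_mu = if (!is.null(test$logit_mu))
                              test$logit_mu / Tm,
                            logit_var = if (!is.null(test$logit_var))
                              test$logit_var / Tm^2)
  list(temperature = Tm, test = out, calib_nll = opt$objective)
}

#' Variance scaling for Gaussian regression predictions
#'
#' The regression analogue of temperature scaling: a single multiplicative
#' factor `s` on the predicted variances, with the closed-form Gaussian
#' negative-log-likelihood minimiser `s = mean((y - mu)^2 / var)` on the
#' calibration set. Means are left unchanged. A degenerate calibration set
#' with zero residuals yields `s` clamped to a floor of `1e-6` with a
#' warning.
#'
#' @param calib,test [gaussian_predictions()] sets.
#' @return list with `scale` (fitted variance factor) and `test`
#'   (test set with `var * scale`).
#' @export
fit_variance_scale_reg <- function(calib, test) {
  validate_predictions(calib); validate_predictions(test)
  s <- mean((calib$y_true - calib$mu)^2 / calib$var)
  if (s < 1e-6) {
    warning("degenerate calibration residuals; variance scale clamped to 1e-6")
    s <- 1e-6
  }
  list(scale = s,
       test = gaussian_predictions(test$y_true, test$mu, test$var * s))
}

#' Isotonic regression calibration for binary classifiers
#'
#' Nondecreasing least-squares fit of the calibration labels on the
#' predicted probabilities (pool-adjacent-violators); test probabilities
#' are mapped through the fitted right-continuous step function and
#' clipped to `[1e-6, 1 - 1e-6]` so downstream log-likelihoods stay
#' finite.
#'
#' @param calib,test [binary_predictions()] sets; `calib` must contain
#'   both classes.
#' @return list with `map` (the [isotonic_fit()]) and `test` (transformed
#'   test set).
#' @export
fit_isotonic_cls <- function(calib, test) {
  validate_predictions(calib); validate_predictions(test)
  check_both_classes(calib)
  fit <- isotonic_fit(calib$p1, calib$y_true)
  p_new <- clip_prob(fit$predict(test$p1))
  list(map = fit,
       test = binary_predictions(test$y_true, p_new,
                                 logit_mu = test$logit_mu,
                                 logit_var = test$logit_var))
}

#' Isotonic (quantile) recalibration for Gaussian regression predictions
#'
#' Recalibrates the predictive CDFs through their probability integral
#' transform: the empirical CDF of the calibration PIT values, fitted
#' isotonically against the nominal level, defines a monotone map `R` such
#' that the recalibrated quantile at level `l` is the predictive quantile
#' at `R^{-1}(l)`. The recalibrated one-sigma quantiles
#' (levels 0.1587/0.8413) of each test distribution are then refitted to a
#' Gaussian. The predicted means are deliberately left unchanged — only the
#' spread is recalibrated, so point predictions and MAE are identical
#' before and after, mirroring interval recalibration under the midpoint
#' convention. Under a purely multiplicative variance miscalibration the
#' method recovers the true predictive spread.
#'
#' @param calib,test [gaussian_predictions()] sets; `calib` needs at least
#'   20 examples.
#' @param levels symmetric quantile pair used for the Gaussian refit.
#' @return list with `pit_map` (the fitted isotonic CDF map) and `test`
#'   (recalibrated Gaussian test set).
#' @export
fit_isotonic_reg <- function(calib, test, levels = c(0.1587, 0.8413)) {
  validate_predictions(calib); validate_predictions(test)
  if (n_examples(calib) < 20)
    stop("isotonic regression recalibration needs a calibration set of >= 20")
  pit <- sort(pit_values(calib))
  n <- length(pit)
  # isotonic fit of the empirical CDF against PIT (already monotone, so the
  # PAV step is a formality that also pools ties)
  map <- isotonic_fit(pit, seq_len(n) / n)
  # R is a step CDF, so R^{-1}(l) is the type-1 empirical quantile of the PIT
  p_lo <- stats::quantile(pit, probs = levels[1], type = 1, names = FALSE)
  p_hi <- stats::quantile(pit, probs = levels[2], type = 1, names = FALSE)
  if (p_hi <= p_lo)
    warning("degenerate PIT spread; recalibrated variances collapse")
  p_lo <- min(max(p_lo, PROB_EPS), 1 - PROB_EPS)
  p_hi <- min(max(p_hi, PROB_EPS), 1 - PROB_EPS)
  if (p_hi <= p_lo) p_hi <- min(p_lo + PROB_EPS, 1 - PROB_EPS / 2)
  # recalibrated band halfwidth in reported sigmas; mean kept fixed
  scale <- (stats::qnorm(p_hi) - stats::qnorm(p_lo)) /
    (2 * stats::qnorm(levels[2]))
  list(pit_map = map,
       test = gaussian_predictions(test$y_true, test$mu,
                                   test$var * scale^2))
}

conformal_quantile <- function(scores, alpha) {
  n <- length(scores)
  rank <- ceiling((n + 1) * (1 - alpha))
  if (rank > n)
    stop("calibration set too small for requested coverage")
  sort(scores)[rank]
}

#' Split conformal prediction intervals
#'
#' `conformalize_gaussian()` (conformalized MAP) uses the standardised
#' absolute residual `|y - mu| / sigma` as nonconformity score on the
#' calibration set and returns test intervals `mu +/- q_hat * sigma`, where
#' `q_hat` is the `ceil((n + 1) (1 - alpha))`-th smallest calibration
#' score — the finite-sample-valid split-conformal order statistic.
#' `conformalize_quantiles()` (conformalized quantile regression) scores
#' `max(q_lo - y, y - q_hi)` on the calibration set and widens (or, when
#' `q_hat < 0`, shrinks) the test quantile band by `q_hat` on both sides.
#' Both carry the marginal coverage guarantee
#' `P(y in interval) >= 1 - alpha` under exchangeability of calibration
#' and test examples.
#'
#' @param calib,test prediction sets of the matching type
#'   ([gaussian_predictions()] or [quantile_predictions()] with two
#'   symmetric levels).
#' @param alpha miscoverage level in (0,1); the returned intervals have
#'   `nominal_level = 1 - alpha`.
#' @return list with `q_hat` (the conformal correction) and `test`
#'   (an [interval_predictions()] set).
#' @export
conformalize_gaussian <- function(calib, test, alpha) {
  validate_predictions(calib); validate_predictions(test)
  stopifnot(alpha > 0, alpha < 1)
  s_cal <- abs(calib$y_true - calib$mu) / sqrt(calib$var)
  q_hat <- conformal_quantile(s_cal, alpha)
  sig <- sqrt(test$var)
  list(q_hat = q_hat,
       test = interval_predictions(test$y_true,
                                   lo = test$mu - q_hat * sig,
                                   hi = test$mu + q_hat * sig,
                                   nominal_level = 1 - alpha))
}

#' @rdname conformalize_gaussian
#' @export
conformalize_quantiles <- function(calib, test, alpha) {
  validate_predictions(calib); validate_predictions(test)
  stopifnot(alpha > 0, alpha < 1)
  if (length(calib$levels) != 2 || length(test$levels) != 2)
    stop("conformalized quantile regression requires two quantile levels")
  s_cal <- pmax(calib$q[, 1] - calib$y_true, calib$y_true - calib$q[, 2])
  q_hat <- conformal_quantile(s_cal, alpha)
  lo <- test$q[, 1] - q_hat
  hi <- test$q[, 2] + q_hat
  if (any(lo > hi)) { # large negative correction can invert a narrow band
    mid <- (lo + hi) / 2
    bad <- lo > hi
    lo[bad] <- mid[bad]; hi[bad] <- mid[bad]
  }
  list(q_hat = q_hat,
       test = interval_predictions(test$y_true, lo, hi,
                                   nominal_level = 1 - alpha))
}

#' Venn-ABERS probability intervals
#'
#' For each test example with score `s`, two isotonic regressions are
#' fitted on the calibration scores augmented with the hypothetical
#' example `(s, 0)` and `(s, 1)` respectively; evaluating each fit at `s`
#' yields the probability interval `(p0, p1)` with `p0 <= p1` bracketing
#' the class-1 probability, and the merged point prediction
#' `p = p1 / (1 - p0 + p1)` (the log-loss-optimal combination). The
#' underlying score defaults to the predicted probability `p1`; the raw
#' logit mean can be used instead when present.
#'
#' @param calib,test [binary_predictions()] sets; `calib` must contain
#'   both classes.
#' @param score `"p1"` or `"logit_mu"`, the scalar score per example.
#' @return list with `intervals` (data frame `p0`, `p1`, `p` per test
#'   example) and `test` (a [binary_predictions()] set carrying the merged
#'   probability).
#' @export
venn_abers_predict <- function(calib, test, score = c("p1", "logit_mu")) {
  validate_predictions(calib); validate_predictions(test)
  if (n_examples(calib) < 1) stop("empty calibration set")
  check_both_classes(calib)
  score <- match.arg(score)
  if (score == "logit_mu" &&
      (is.null(calib$logit_mu) || is.null(test$logit_mu)))
    stop("logit_mu score requested but logit fields are absent")
  s_cal <- calib[[score]]; y_cal <- calib$y_true
  s_tst <- test[[score]]
  one <- function(s, label) {
    fit <- isotonic_fit(c(s_cal, s), c(y_cal, label))
    fit$predict(s)
  }
  p0 <- vapply(s_tst, one, numeric(1), label = 0)
  p1 <- vapply(s_tst, one, numeric(1), label = 1)
  p <- p1 / (1 - p0 + p1)
  list(intervals = data.frame(p0 = p0, p1 = p1, p = p),
       test = binary_predictions(test$y_true, clip_prob(p)))
}
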