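#' Synthetic prediction sets with known calibration defects
#'
#' Generators emulating the statistical shape of clinical model outputs so
#' that every metric and recalibration method can be exercised against a
#' known ground truth. Regression defaults mimic a systolic blood-pressure
#' task (target mean 115.48, SD 18.92 mmHg); classification defaults mimic
#' an imbalanced atrial-fibrillation screen (positive ratio 0.38).
#' Miscalibration is injected multiplicatively — a factor `c` on the true
#' predictive sigma, a temperature `T_true` on the true logits — precisely
#' the defects variance scaling and temperature scaling can undo, which
#' makes parameter-recovery tests possible. The generators are pure
#' functions of their arguments: the same configuration and seed always
#' produce the identical set.
#'
#' @param n number of examples.
#' @param mu_center,mu_sd distribution of predicted means (target units).
#' @param sigma_log_mean,sigma_log_sd lognormal parameters of the true
#'   per-example predictive sigma (defaults give a median spread of
#'   12 target units with moderate heteroscedasticity).
#' @param c variance miscalibration factor: reported sigma equals
#'   `c * true sigma`; `c = 1` is perfectly calibrated, `c < 1`
#'   overconfident.
#' @param seed integer seed.
#' @return `simulate_regression()`: a [gaussian_predictions()] set with
#'   the generating sigmas attached as attribute `"true_sigma"`.
#' @examples
#' gps <- simulate_regression(1000, seed = 7)
#' picp(gps, n_sigma = 1) # close to 1
#' @export
simulate_regression <- function(n, mu_center = 115.48, mu_sd = 18.92,
                                sigma_log_mean = log(12), sigma_log_sd = 0.3,
                                c = 1, seed = 1) {
  stopifnot(n >= 1, c > 0)
  set.seed(seed)
  mu <- stats::rnorm(n, mu_center, mu_sd)
  true_sigma <- stats::rlnorm(n, sigma_log_mean, sigma_log_sd)
  y <- stats::rnorm(n, mu, true_sigma)
  out <- gaussian_predictions(y, mu, (c * true_sigma)^2)
  attr(out, "true_sigma") <- true_sigma
  out
}

#' @rdname simulate_regression
#' @param pos_ratio expected positive-class fraction (default 0.38).
#' @param T_true logit temperature distortion of the reported
#'   probabilities, `p1 = plogis(T_true * qlogis(pi))`; `T_true = 1` is
#'   calibrated, `T_true > 1` inflates logits (overconfident), `T_true < 1`
#'   deflates them (underconfident). Because [fit_temperature_cls()]
#'   divides logits by its fitted temperature, that fit recovers `T_true`.
#' @param logit_var_scale mean of the exponential draw of per-example
#'   logit variances.
#' @param concentration Beta concentration of the true class-probability
#'   distribution (`shape1 + shape2`); small values give confident,
#'   well-spread probabilities.
#' @return `simulate_classification()`: a [binary_predictions()] set with
#'   logit fields and the true probabilities attached as attribute
#'   `"true_p"`.
#' @export
simulate_classification <- function(n, pos_ratio = 0.38, T_true = 1,
                                    logit_var_scale = 0.25,
                                    concentration = 2, seed = 1) {
  stopifnot(n >= 1, pos_ratio > 0, pos_ratio < 1, T_true > 0,
            logit_var_scale >= 0, concentration > 0)
  set.seed(seed)
  pi_true <- stats::rbeta(n, pos_ratio * concentration,
                          (1 - pos_ratio) * concentration)
  pi_true <- pmin(pmax(pi_true, 1e-6), 1 - 1e-6)
  y <- stats::rbinom(n, 1, pi_true)
  p1 <- stats::plogis(T_true * stats::qlogis(pi_true))
  logit_var <- if (logit_var_scale > 0)
    stats::rexp(n, rate = 1 / logit_var_scale) else rep(0, n)
  out <- binary_predictions(y, p1, logit_mu = stats::qlogis(p1),
                            logit_var = logit_var)
  attr(out, "true_p") <- pi_true
  out
}

#' @rdname simulate_regression
#' @param K number of ensemble members.
#' @param jitter standard deviation of the member means around the base
#'   mean (the between-member, epistemic spread).
#' @return `simulate_ensemble()`: an [ensemble_stack()] (regression) whose
#'   aggregation recovers total variance = within-member variance +
#'   `jitter^2` in expectation.
#' @export
simulate_ensemble <- function(n, K, jitter = 0, mu_center = 115.48,
                              mu_sd = 18.92, sigma_log_mean = log(12),
                              sigma_log_sd = 0.3, seed = 1) {
  stopifnot(n >= 1, K >= 1, jitter >= 0)
  set.seed(seed)
  base_mu <- stats::rnorm(n, mu_center, mu_sd)
  within_sigma <- stats::rlnorm(n, sigma_log_mean, sigma_log_sd)
  y <- stats::rnorm(n, base_mu, within_sigma)
  mu <- base_mu + matrix(stats::rnorm(n * K, 0, jitter), n, K)
  if (jitter == 0) mu <- matrix(base_mu, n, K)
  var <- matrix(within_sigma^2, n, K)
  ensemble_stack("regression", y, mu = mu, var = var)
}
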