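#' Aggregate ensemble member outputs into one predictive distribution
#'
#' Combines the K member outputs of an [ensemble_stack()] (deep-ensemble
#' members or Monte-Carlo-dropout passes) into a single predictive
#' distribution per example.
#'
#' For regression the law of total variance is applied: the aggregated mean
#' is the mean of member means, and the aggregated variance is the mean of
#' member variances (within-member, aleatoric) plus the population variance
#' of the member means (between-member, epistemic). The population (divide
#' by K) variance is used because the members *are* the whole ensemble, not
#' a sample from a larger one.
#'
#' For classification, each member's logit-scale Gaussian is propagated
#' through the logistic function by Monte Carlo: `n_logit_samples` draws
#' `z ~ N(logit_mu_k, logit_var_k)` per member are mapped through
#' `plogis()` and all samples from all members are averaged into the
#' aggregated positive-class probability (noise-corrupted class
#' probabilities). The returned set also carries the aggregated logit mean
#' (mean of member logit means) and logit variance (law of total variance
#' on the logit scale). The draw is seeded and reproducible.
#'
#' @param stack an [ensemble_stack()].
#' @param n_logit_samples Monte-Carlo draws per member and example used for
#'   classification aggregation (default 100).
#' @param seed integer seed for the logit draws (classification only).
#' @return A [gaussian_predictions()] set (regression) or a
#'   [binary_predictions()] set with logit fields (classification).
#' @examples
#' st <- ensemble_stack("regression", y_true = 0,
#'                      mu = matrix(c(1, 3), 1), var = matrix(c(1, 1), 1))
#' aggregate_members(st) # mu = 2, var = 1 + 1 = 2
#' @export
aggregate_members <- function(stack, n_logit_samples = 100L, seed = 1L) {
  validate_predictions(stack)
  if (stack$task == "regression") {
    mu_star <- rowMeans(stack$mu)
    # law of total variance; population (K-denominator) spread of member means
    var_star <- rowMeans(stack$var) + rowMeans(stack$mu^2) - mu_star^2
    gaussian_predictions(stack$y_true, mu_star, pmax(var_star, .Machine$double.eps))
  } else {
    if (n_logit_samples < 1) stop("n_logit_samples must be >= 1")
    n <- n_examples(stack); K <- n_members(stack)
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    acc <- numeric(n)
    for (k in seq_len(K)) {
      z <- matrix(stats::rnorm(n * n_logit_samples, mean = stack$logit_mu[, k],
                               sd = sqrt(stack$logit_var[, k])),
                  nrow = n)
      acc <- acc + rowMeans(stats::plogis(z))
    }
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    lm_star <- rowMeans(stack$logit_mu)
    lv_star <- rowMeans(stack$logit_var) +
      rowMeans(stack$logit_mu^2) - lm_star^2
    binary_predictions(stack$y_true, p1 = pmin(pmax(acc / K, 0), 1),
                       logit_mu = lm_star, logit_var = pmax(lv_star, 0))
  }
}

#' Predictive entropy of binary class probabilities
#'
#' Shannon entropy `H = -p log p - (1 - p) log(1 - p)` of each example's
#' predicted class distribution, with `H(0) = H(1) = 0` by continuity.
#' Base-2 entropies (the default) lie in `[0, 1]` for binary problems and
#' are therefore unit-compatible with error rates.
#'
#' @param ps a [binary_predictions()] set, or a bare numeric vector of
#'   probabilities.
#' @param base logarithm base, `2` (default) or `exp(1)`.
#' @return numeric vector of per-example entropies.
#' @export
predictive_entropy <- function(ps, base = 2) {
  p <- if (inherits(ps, "binary_predictions")) ps$p1 else as.numeric(ps)
  term <- function(x) ifelse(x <= 0 | x >= 1, 0, -x * log(x, base = base))
  term(p) + term(1 - p)
}
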