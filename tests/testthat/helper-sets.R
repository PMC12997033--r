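# fixture builders used across test files

rand_gaussian_set <- function(n, seed = 1, calibrated = TRUE, c = 1) {
  set.seed(seed)
  mu <- rnorm(n, 100, 15)
  sigma <- exp(rnorm(n, log(10), 0.4))
  y <- rnorm(n, mu, sigma)
  gaussian_predictions(y, mu, (c * sigma)^2)
}

rand_binary_set <- function(n, seed = 1, with_logits = FALSE) {
  set.seed(seed)
  p <- rbeta(n, 2, 2)
  y <- rbinom(n, 1, p)
  if (with_logits)
    binary_predictions(y, p, logit_mu = qlogis(p), logit_var = rexp(n, 4))
  else binary_predictions(y, p)
}

# globally calibrated but anti-calibrated within each ground-truth class:
# every example carries confidence 0.7 and exactly 70% are positives
split_calibrated_set <- function(n = 1000) {
  n_pos <- round(0.7 * n)
  binary_predictions(c(rep(1, n_pos), rep(0, n - n_pos)), rep(0.7, n))
}
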