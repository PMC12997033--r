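#' Classification reliability metrics
#'
#' Binned and smoothed calibration errors, proper scoring rules and ranking
#' metrics for binary prediction sets. Confidence means the probability of
#' the *predicted* class, `max(p1, 1 - p1)`, so it lives in `[0.5, 1]`; the
#' predicted class is 1 when `p1 >= 0.5`. Entropies are base 2 by default
#' so they share the `[0, 1]` scale with error rates. Squared per-bin
#' discrepancies are the default for ECE/ACE/UCE/VCE, with absolute
#' discrepancy available for cross-literature comparison.
#'
#' @name classification-metrics
#' @keywords internal
NULL

confidence_of <- function(ps) pmax(ps$p1, 1 - ps$p1)
correct_of <- function(ps) as.numeric((ps$p1 >= 0.5) == (ps$y_true == 1))

bin_assign <- function(x, n_bins, scheme, range) {
  if (scheme == "equal-width") {
    edges <- seq(range[1], range[2], length.out = n_bins + 1)
    bin <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  } else { # equal-mass: sort and split into near-equal counts
    edges <- NULL
    bin <- integer(length(x))
    bin[order(x)] <- ceiling(seq_along(x) * n_bins / length(x))
  }
  list(bin = bin, edges = edges)
}

#' Reliability bin table for binary predictions
#'
#' Partitions the examples along the confidence or predictive-entropy axis
#' and tabulates per-bin counts, mean axis value, empirical accuracy and
#' error rate — the table behind a reliability diagram. Equal-width bins
#' partition the theoretical axis range (`[0.5, 1]` for confidence,
#' `[0, 1]` for base-2 entropy); equal-mass (adaptive) bins sort the
#' examples and split them into bins of near-equal count.
#'
#' @param ps a [binary_predictions()] set.
#' @param axis `"confidence"` or `"entropy"`.
#' @param scheme `"equal-width"` or `"equal-mass"`.
#' @param n_bins number of bins (default 10).
#' @return data frame with one row per nonempty bin: `bin_id`, `lower`,
#'   `upper` (axis interval; NA for equal-mass), `count`, `mean_value`
#'   (mean confidence or entropy), `accuracy`, `error_rate`.
#' @export
bin_table_cls <- function(ps, axis = c("confidence", "entropy"),
                          scheme = c("equal-width", "equal-mass"),
                          n_bins = 10) {
  validate_predictions(ps)
  axis <- match.arg(axis); scheme <- match.arg(scheme)
  stopifnot(n_bins >= 1)
  x <- if (axis == "confidence") confidence_of(ps)
       else predictive_entropy(ps, base = 2)
  rng <- if (axis == "confidence") c(0.5, 1) else c(0, 1)
  ba <- bin_assign(x, n_bins, scheme, rng)
  correct <- correct_of(ps)
  ids <- sort(unique(ba$bin))
  tab <- data.frame(
    bin_id = ids,
    lower = if (is.null(ba$edges)) NA_real_ else ba$edges[ids],
    upper = if (is.null(ba$edges)) NA_real_ else ba$edges[ids + 1],
    count = vapply(ids, function(b) sum(ba$bin == b), numeric(1)),
    mean_value = vapply(ids, function(b) mean(x[ba$bin == b]), numeric(1)),
    accuracy = vapply(ids, function(b) mean(correct[ba$bin == b]), numeric(1))
  )
  tab$error_rate <- 1 - tab$accuracy
  tab
}

weighted_bin_error <- function(tab, n, target, value, mode) {
  d <- if (mode == "squared") (tab[[value]] - tab[[target]])^2
       else abs(tab[[value]] - tab[[target]])
  sum(tab$count / n * d)
}

#' Expected calibration error (ECE) and adaptive variant (ACE)
#'
#' Weighted average over confidence bins of the discrepancy between mean
#' confidence and empirical accuracy,
#' `sum_m (n_m / N) d(acc_m, conf_m)`, with squared discrepancy by default
#' and absolute as an option. `ece()` uses equal-width confidence bins;
#' `ace()` uses equal-mass (adaptive) bins, which keeps bin counts balanced
#' under sparse or skewed confidence distributions.
#'
#' @param ps a [binary_predictions()] set.
#' @param n_bins number of bins (default 10).
#' @param mode `"squared"` (default) or `"absolute"` per-bin discrepancy.
#' @return nonnegative scalar.
#' @examples
#' ps <- binary_predictions(c(1, 1, 1, 0), c(0.9, 0.9, 0.6, 0.6))
#' ece(ps)                    # 0.01
#' ece(ps, mode = "absolute") # 0.1
#' @export
ece <- function(ps, n_bins = 10, mode = c("squared", "absolute")) {
  mode <- match.arg(mode)
  tab <- bin_table_cls(ps, "confidence", "equal-width", n_bins)
  weighted_bin_error(tab, n_examples(ps), "accuracy", "mean_value", mode)
}

#' @rdname ece
#' @export
ace <- function(ps, n_bins = 10, mode = c("squared", "absolute")) {
  mode <- match.arg(mode)
  if (n_examples(ps) < n_bins)
    stop("adaptive binning needs at least n_bins examples")
  tab <- bin_table_cls(ps, "confidence", "equal-mass", n_bins)
  weighted_bin_error(tab, n_examples(ps), "accuracy", "mean_value", mode)
}

#' Smooth expected calibration error (smECE)
#'
#' A binning-free calibration error: the per-example residuals
#' `correct_i - conf_i` are smoothed along the confidence axis with a
#' Gaussian kernel reflected at both ends of `[0, 1]`, and
#' `smECE(sigma) = (1/n) integral |sum_i K_sigma(t, conf_i) r_i| dt`.
#' The bandwidth is chosen self-consistently by the fixed-point rule
#' `sigma* = smECE(sigma*)`, solved by bisection on `[1e-4, 1]`; when the
#' smoothed error at the floor bandwidth is already below the floor the
#' floor value is returned. Computation uses a fine grid (nearest-node
#' assignment of examples, trapezoidal quadrature).
#'
#' @param ps a [binary_predictions()] set with at least 2 examples.
#' @param grid_size number of grid nodes on `[0, 1]`.
#' @param max_iter bisection iteration cap.
#' @return nonnegative scalar; the solved bandwidth is attached as
#'   attribute `"bandwidth"`.
#' @export
smece <- function(ps, grid_size = 1001, max_iter = 100) {
  validate_predictions(ps)
  n <- n_examples(ps)
  if (n < 2) stop("smECE needs at least 2 examples")
  conf <- confidence_of(ps)
  r <- correct_of(ps) - conf
  grid <- seq(0, 1, length.out = grid_size)
  h <- grid[2] - grid[1]
  # accumulate residual mass at nearest grid node
  idx <- pmin(pmax(round(conf / h) + 1, 1), grid_size)
  rmass <- numeric(grid_size)
  agg <- tapply(r, idx, sum)
  rmass[as.integer(names(agg))] <- agg
  nz <- which(rmass != 0)
  # reflected Gaussian kernel: images at -c and 2 - c keep mass on [0,1]
  D1 <- outer(grid, grid[nz], "-")
  D2 <- outer(grid, grid[nz], "+")
  smece_at <- function(sigma) {
    if (!length(nz)) return(0)
    K <- stats::dnorm(D1, sd = sigma) + stats::dnorm(D2, sd = sigma) +
      stats::dnorm(D2 - 2, sd = sigma)
    sm <- as.vector(K %*% rmass[nz])
    sum(abs(sm)) * h / n - (abs(sm[1]) + abs(sm[grid_size])) * h / (2 * n)
  }
  lo <- 1e-4; hi <- 1
  f_lo <- smece_at(lo) - lo
  if (f_lo <= 0) {
    out <- smece_at(lo)
    attr(out, "bandwidth") <- lo
    return(out)
  }
  f_hi <- smece_at(hi) - hi
  if (f_hi > 0) stop("smECE bandwidth fixed point not bracketed on [1e-4, 1]")
  it <- 0
  while (hi - lo > 1e-6) {
    it <- it + 1
    if (it > max_iter)
      stop(sprintf("smECE fixed point did not converge in %d iterations (bracket [%g, %g])",
                   max_iter, lo, hi))
    mid <- (lo + hi) / 2
    if (smece_at(mid) - mid > 0) lo <- mid else hi <- mid
  }
  sigma <- (lo + hi) / 2
  out <- smece_at(sigma)
  attr(out, "bandwidth") <- sigma
  out
}

#' Entropy-binned calibration errors (UCE and VCE)
#'
#' Both metrics bin examples by base-2 predictive entropy over equal-width
#' bins of `[0, 1]`. The uncertainty calibration error `uce()` compares the
#' mean predicted entropy in each bin with the bin's misclassification
#' rate, `sum_m (n_m / N) (H_m - err_m)^2`; note the two quantities are
#' not on a like-for-like scale, a known quirk of the metric. The
#' variation calibration error `vce()` instead compares the mean predicted
#' entropy with the *observed variation expressed as an entropy* — the
#' binary entropy of the bin's empirical accuracy:
#' `sum_m (n_m / N) (H_m - H2(acc_m))^2`.
#'
#' @inheritParams ece
#' @return nonnegative scalar.
#' @export
uce <- function(ps, n_bins = 10, mode = c("squared", "absolute")) {
  mode <- match.arg(mode)
  tab <- bin_table_cls(ps, "entropy", "equal-width", n_bins)
  weighted_bin_error(tab, n_examples(ps), "error_rate", "mean_value", mode)
}

#' @rdname uce
#' @export
vce <- function(ps, n_bins = 10, mode = c("squared", "absolute")) {
  mode <- match.arg(mode)
  tab <- bin_table_cls(ps, "entropy", "equal-width", n_bins)
  tab$observed_entropy <- predictive_entropy(tab$accuracy, base = 2)
  weighted_bin_error(tab, n_examples(ps), "observed_entropy", "mean_value",
                     mode)
}

#' Negative log-likelihood of binary predictions
#'
#' Mean over examples of `-ln p(target class)`, a proper scoring rule
#' capturing both calibration and sharpness. Probabilities are clipped to
#' `[1e-6, 1 - 1e-6]` before the logarithm.
#'
#' @param ps a [binary_predictions()] set.
#' @return nonnegative scalar (natural-log units).
#' @export
nll_cls <- function(ps) {
  validate_predictions(ps)
  p_target <- clip_prob(ifelse(ps$y_true == 1, ps$p1, 1 - ps$p1))
  mean(-log(p_target))
}

#' Area under the ROC curve
#'
#' The Mann-Whitney form: the probability that a randomly selected
#' positive example receives a higher predicted probability than a
#' randomly selected negative one, with ties counted one half. Computed
#' from midranks in O(n log n).
#'
#' @param ps a [binary_predictions()] set containing both classes.
#' @return scalar in `[0, 1]`.
#' @export
auc <- function(ps) {
  validate_predictions(ps)
  check_both_classes(ps)
  pos <- ps$y_true == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(ps$p1) # midranks give ties credit 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Balanced accuracy at a probability threshold
#'
#' Mean of sensitivity (true-positive rate) and specificity (true-negative
#' rate) of the thresholded classifier; class 1 is predicted when
#' `p1 >= threshold`.
#'
#' @param ps a [binary_predictions()] set containing both classes.
#' @param threshold decision threshold (default 0.5).
#' @return scalar in `[0, 1]`.
#' @export
balanced_accuracy <- function(ps, threshold = 0.5) {
  validate_predictions(ps)
  check_both_classes(ps)
  pred <- ps$p1 >= threshold
  sens <- mean(pred[ps$y_true == 1])
  spec <- mean(!pred[ps$y_true == 0])
  (sens + spec) / 2
}
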