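#' Prediction-set containers
#'
#' A prediction set pairs per-example ground truth with one probabilistic
#' output type produced by an uncertainty-quantification method:
#'
#' * `gaussian_predictions()` — a Gaussian predictive distribution per
#'   example, parameterised by mean `mu` and variance `var` (regression).
#' * `binary_predictions()` — a positive-class probability `p1` per example,
#'   optionally with a logit-scale mean and variance (classification).
#' * `quantile_predictions()` — predicted quantiles at fixed nominal levels
#'   (quantile regression output).
#' * `interval_predictions()` — central prediction intervals at one nominal
#'   coverage level (conformal prediction output).
#'
#' Variance, not standard deviation, is the canonical spread field; standard
#' deviations are always derived on demand. Optional logit fields are either
#' both present or both absent. Example indices in error messages are
#' 0-based.
#'
#' @param y_true numeric vector of observed targets (labels in `{0,1}` for
#'   `binary_predictions`).
#' @param mu numeric vector of predicted means, same length as `y_true`.
#' @param var numeric vector of predicted variances, strictly positive.
#' @param p1 numeric vector of positive-class probabilities in `[0,1]`.
#' @param logit_mu,logit_var optional logit-scale mean and variance per
#'   example (`logit_var >= 0`); supply both or neither.
#' @param q numeric matrix of predicted quantiles, one row per example and
#'   one column per level; rows must be nondecreasing across levels.
#' @param levels strictly increasing probabilities in (0,1) naming the
#'   columns of `q`. Defaults to the central one-standard-deviation band
#'   `c(0.1587, 0.8413)`.
#' @param lo,hi numeric interval bounds per example with `lo <= hi`.
#' @param nominal_level target central coverage of the intervals, in (0,1).
#' @return A validated object of class `"prediction_set"` with subclass
#'   `"gaussian_predictions"`, `"binary_predictions"`,
#'   `"quantile_predictions"` or `"interval_predictions"`.
#' @examples
#' gaussian_predictions(y_true = c(1, 2), mu = c(0.9, 2.2), var = c(1, 2))
#' binary_predictions(y_true = c(0, 1), p1 = c(0.2, 0.8))
#' @export
gaussian_predictions <- function(y_true, mu, var) {
  ps <- structure(
    list(y_true = as.numeric(y_true), mu = as.numeric(mu),
         var = as.numeric(var)),
    class = c("gaussian_predictions", "prediction_set"))
  validate_predictions(ps)
}

#' @rdname gaussian_predictions
#' @export
binary_predictions <- function(y_true, p1, logit_mu = NULL, logit_var = NULL) {
  ps <- structure(
    list(y_true = as.numeric(y_true), p1 = as.numeric(p1),
         logit_mu = if (!is.null(logit_mu)) as.numeric(logit_mu),
         logit_var = if (!is.null(logit_var)) as.numeric(logit_var)),
    class = c("binary_predictions", "prediction_set"))
  validate_predictions(ps)
}

#' @rdname gaussian_predictions
#' @export
quantile_predictions <- function(y_true, q, levels = c(0.1587, 0.8413)) {
  q <- as.matrix(q)
  ps <- structure(
    list(y_true = as.numeric(y_true), q = q, levels = as.numeric(levels)),
    class = c("quantile_predictions", "prediction_set"))
  validate_predictions(ps)
}

#' @rdname gaussian_predictions
#' @export
interval_predictions <- function(y_true, lo, hi, nominal_level) {
  ps <- structure(
    list(y_true = as.numeric(y_true), lo = as.numeric(lo),
         hi = as.numeric(hi), nominal_level = as.numeric(nominal_level)),
    class = c("interval_predictions", "prediction_set"))
  validate_predictions(ps)
}

#' Ensemble member outputs prior to aggregation
#'
#' Holds the raw outputs of K ensemble members (or Monte-Carlo-dropout
#' passes) over a shared set of examples, before they are combined into a
#' single predictive distribution per example by [aggregate_members()].
#'
#' @param task `"regression"` (members emit Gaussian `mu`, `var`) or
#'   `"classification"` (members emit logit-scale `logit_mu`, `logit_var`).
#' @param y_true shared ground truth, length n.
#' @param mu,var n-by-K numeric matrices of member means and variances
#'   (regression; `var > 0`).
#' @param logit_mu,logit_var n-by-K matrices of member logit means and
#'   variances (classification; `logit_var >= 0`).
#' @return An object of class `"ensemble_stack"`.
#' @export
ensemble_stack <- function(task = c("regression", "classification"), y_true,
                           mu = NULL, var = NULL,
                           logit_mu = NULL, logit_var = NULL) {
  task <- match.arg(task)
  y_true <- as.numeric(y_true)
  st <- structure(list(task = task, y_true = y_true), class = "ensemble_stack")
  if (task == "regression") {
    st$mu <- as.matrix(mu); st$var <- as.matrix(var)
  } else {
    st$logit_mu <- as.matrix(logit_mu); st$logit_var <- as.matrix(logit_var)
  }
  validate_predictions(st)
}

#' Number of examples in a prediction set
#' @param ps a prediction set or ensemble stack.
#' @return integer example count.
#' @export
n_examples <- function(ps) length(ps$y_true)

#' Number of members in an ensemble stack
#' @param stack an [ensemble_stack()].
#' @return integer member count K.
#' @export
n_members <- function(stack) {
  stopifnot(inherits(stack, "ensemble_stack"))
  ncol(if (stack$task == "regression") stack$mu else stack$logit_mu)
}

#' Predicted standard deviations of a Gaussian prediction set
#' @param gps a [gaussian_predictions()] set.
#' @return numeric vector `sqrt(var)`.
#' @export
pred_sigma <- function(gps) {
  stopifnot(inherits(gps, "gaussian_predictions"))
  sqrt(gps$var)
}

# ---- validation -----------------------------------------------------------

fail_at <- function(what, idx) {
  stop(sprintf("%s (example %d)", what, idx - 1L), call. = FALSE)
}

check_finite <- function(x, name) {
  bad <- which(!is.finite(x))
  if (length(bad)) fail_at(sprintf("non-finite value in '%s'", name), bad[1])
}

#' Validate a prediction set
#'
#' Checks every structural invariant of the container (equal lengths,
#' finite values, positive variances, probabilities in `[0,1]`, labels in
#' `{0,1}`, nondecreasing quantile rows, `lo <= hi`) and reports the first
#' violation with its 0-based example index. Validation is idempotent; the
#' object is returned unchanged when all invariants hold.
#'
#' @param ps a prediction set or [ensemble_stack()].
#' @return `ps`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_predictions <- function(ps) UseMethod("validate_predictions")

#' @export
validate_predictions.gaussian_predictions <- function(ps) {
  n <- length(ps$y_true)
  if (n < 1) stop("prediction set must contain at least one example")
  if (length(ps$mu) != n || length(ps$var) != n)
    stop("y_true, mu and var must have equal length")
  check_finite(ps$y_true, "y_true"); check_finite(ps$mu, "mu")
  check_finite(ps$var, "var")
  bad <- which(ps$var <= 0)
  if (length(bad)) fail_at("variance must be positive", bad[1])
  ps
}

#' @export
validate_predictions.binary_predictions <- function(ps) {
  n <- length(ps$y_true)
  if (n < 1) stop("prediction set must contain at least one example")
  if (length(ps$p1) != n) stop("y_true and p1 must have equal length")
  check_finite(ps$y_true, "y_true"); check_finite(ps$p1, "p1")
  bad <- which(!(ps$y_true %in% c(0, 1)))
  if (length(bad)) fail_at("label outside {0,1}", bad[1])
  bad <- which(ps$p1 < 0 | ps$p1 > 1)
  if (length(bad)) fail_at("p1 outside [0,1]", bad[1])
  if (is.null(ps$logit_mu) != is.null(ps$logit_var))
    stop("logit_mu and logit_var must be present or absent together")
  if (!is.null(ps$logit_mu)) {
    if (length(ps$logit_mu) != n || length(ps$logit_var) != n)
      stop("logit fields must match y_true in length")
    check_finite(ps$logit_mu, "logit_mu"); check_finite(ps$logit_var, "logit_var")
    bad <- which(ps$logit_var < 0)
    if (length(bad)) fail_at("logit variance must be nonnegative", bad[1])
  }
  ps
}

#' @export
validate_predictions.quantile_predictions <- function(ps) {
  n <- length(ps$y_true)
  if (n < 1) stop("prediction set must contain at least one example")
  if (nrow(ps$q) != n) stop("q must have one row per example")
  if (ncol(ps$q) != length(ps$levels))
    stop("q must have one column per level")
  if (any(ps$levels <= 0 | ps$levels >= 1))
    stop("levels must lie strictly inside (0,1)")
  if (length(ps$levels) > 1 && any(diff(ps$levels) <= 0))
    stop("levels must be strictly increasing")
  check_finite(ps$y_true, "y_true"); check_finite(ps$q, "q")
  if (ncol(ps$q) > 1) {
    crossing <- which(apply(ps$q, 1, function(r) any(diff(r) < 0)))
    if (length(crossing))
      fail_at("quantile crossing", crossing[1])
  }
  ps
}

#' @export
validate_predictions.interval_predictions <- function(ps) {
  n <- length(ps$y_true)
  if (n < 1) stop("prediction set must contain at least one example")
  if (length(ps$lo) != n || length(ps$hi) != n)
    stop("y_true, lo and hi must have equal length")
  check_finite(ps$y_true, "y_true"); check_finite(ps$lo, "lo")
  check_finite(ps$hi, "hi")
  bad <- which(ps$lo > ps$hi)
  if (length(bad)) fail_at("interval must satisfy lo <= hi", bad[1])
  if (length(ps$nominal_level) != 1 || ps$nominal_level <= 0 ||
      ps$nominal_level >= 1)
    stop("nominal_level must be a single value in (0,1)")
  ps
}

#' @export
validate_predictions.ensemble_stack <- function(ps) {
  n <- length(ps$y_true)
  if (n < 1) stop("ensemble stack must contain at least one example")
  check_finite(ps$y_true, "y_true")
  if (ps$task == "regression") {
    if (ncol(ps$mu) < 1) stop("ensemble stack must have at least one member")
    if (nrow(ps$mu) != n || !identical(dim(ps$mu), dim(ps$var)))
      stop("member matrices must be n-by-K and agree in shape")
    check_finite(ps$mu, "mu"); check_finite(ps$var, "var")
    bad <- which(ps$var <= 0, arr.ind = TRUE)
    if (nrow(bad)) fail_at("member variance must be positive", bad[1, 1])
  } else {
    if (ncol(ps$logit_mu) < 1) stop("ensemble stack must have at least one member")
    if (nrow(ps$logit_mu) != n ||
        !identical(dim(ps$logit_mu), dim(ps$logit_var)))
      stop("member matrices must be n-by-K and agree in shape")
    check_finite(ps$logit_mu, "logit_mu"); check_finite(ps$logit_var, "logit_var")
    bad <- which(ps$logit_var < 0, arr.ind = TRUE)
    if (nrow(bad)) fail_at("member logit variance must be nonnegative", bad[1, 1])
  }
  ps
}

# ---- printing -------------------------------------------------------------

#' @export
print.prediction_set <- function(x, ...) {
  type <- class(x)[1]
  cat(sprintf("<%s> %d examples\n", type, n_examples(x)))
  if (inherits(x, "gaussian_predictions"))
    cat(sprintf("  mu: [%.4g, %.4g]  sigma: [%.4g, %.4g]\n",
                min(x$mu), max(x$mu), min(sqrt(x$var)), max(sqrt(x$var))))
  if (inherits(x, "binary_predictions"))
    cat(sprintf("  p1: [%.4g, %.4g]  positives: %.3f  logit fields: %s\n",
                min(x$p1), max(x$p1), mean(x$y_true),
                if (is.null(x$logit_mu)) "absent" else "present"))
  if (inherits(x, "quantile_predictions"))
    cat(sprintf("  levels: %s\n", paste(format(x$levels), collapse = ", ")))
  if (inherits(x, "interval_predictions"))
    cat(sprintf("  nominal central coverage: %.4f\n", x$nominal_level))
  invisible(x)
}

#' @export
print.ensemble_stack <- function(x, ...) {
  cat(sprintf("<ensemble_stack> task: %s, %d examples, K = %d members\n",
              x$task, n_examples(x), n_members(x)))
  invisible(x)
}

#' @export
as.data.frame.prediction_set <- function(x, ...) {
  if (inherits(x, "quantile_predictions")) {
    df <- data.frame(y_true = x$y_true)
    qn <- sprintf("q_%.4f", x$levels)
    for (j in seq_along(x$levels)) df[[qn[j]]] <- x$q[, j]
    return(df)
  }
  keep <- !vapply(x, is.null, logical(1)) &
    names(x) != "nominal_level"
  as.data.frame(x[keep], ...)
}
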