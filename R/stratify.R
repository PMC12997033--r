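#' Subset a prediction set by example index
#'
#' @param ps a prediction set.
#' @param idx integer (1-based) index vector; duplicates allowed, so
#'   bootstrap resamples are valid subsets.
#' @return a prediction set of the same type.
#' @export
ps_subset <- function(ps, idx) {
  if (inherits(ps, "gaussian_predictions"))
    return(gaussian_predictions(ps$y_true[idx], ps$mu[idx], ps$var[idx]))
  if (inherits(ps, "binary_predictions"))
    return(binary_predictions(ps$y_true[idx], ps$p1[idx],
                              logit_mu = if (!is.null(ps$logit_mu)) ps$logit_mu[idx],
                              logit_var = if (!is.null(ps$logit_var)) ps$logit_var[idx]))
  if (inherits(ps, "quantile_predictions"))
    return(quantile_predictions(ps$y_true[idx], ps$q[idx, , drop = FALSE],
                                levels = ps$levels))
  if (inherits(ps, "interval_predictions"))
    return(interval_predictions(ps$y_true[idx], ps$lo[idx], ps$hi[idx],
                                ps$nominal_level))
  stop("unsupported prediction-set type")
}

# registry of scalar metrics addressable by name; each entry knows which
# set type it consumes and whether it needs both classes present
metric_registry <- function() {
  list(
    ece = list(fn = function(ps, ...) ece(ps, ...), type = "binary_predictions",
               both_classes = FALSE),
    ace = list(fn = function(ps, ...) ace(ps, ...), type = "binary_predictions",
               both_classes = FALSE),
    smece = list(fn = function(ps, ...) as.numeric(smece(ps)),
                 type = "binary_predictions", both_classes = FALSE),
    uce = list(fn = function(ps, ...) uce(ps, ...), type = "binary_predictions",
               both_classes = FALSE),
    vce = list(fn = function(ps, ...) vce(ps, ...), type = "binary_predictions",
               both_classes = FALSE),
    nll = list(fn = function(ps, ...)
      if (inherits(ps, "binary_predictions")) nll_cls(ps) else nll_gaussian(ps),
      type = c("binary_predictions", "gaussian_predictions"),
      both_classes = FALSE),
    auc = list(fn = function(ps, ...) auc(ps), type = "binary_predictions",
               both_classes = TRUE),
    balanced_accuracy = list(fn = function(ps, ...) balanced_accuracy(ps),
                             type = "binary_predictions", both_classes = TRUE),
    ence = list(fn = function(ps, ...) ence(ps, ...),
                type = "gaussian_predictions", both_classes = FALSE),
    crps = list(fn = function(ps, ...) crps_gaussian(ps),
                type = "gaussian_predictions", both_classes = FALSE),
    cce = list(fn = function(ps, ...) as.numeric(cce(ps)),
               type = "gaussian_predictions", both_classes = FALSE),
    picp_1sigma = list(fn = function(ps, ...) picp(ps, n_sigma = 1),
                       type = c("gaussian_predictions", "interval_predictions"),
                       both_classes = FALSE),
    picp_2sigma = list(fn = function(ps, ...) picp(ps, n_sigma = 2),
                       type = "gaussian_predictions", both_classes = FALSE),
    mae = list(fn = function(ps, ...) mean(abs(ps$y_true - ps$mu)),
               type = "gaussian_predictions", both_classes = FALSE)
  )
}

resolve_metric <- function(metric) {
  if (is.function(metric)) return(list(fn = metric, both_classes = FALSE))
  reg <- metric_registry()
  if (!metric %in% names(reg))
    stop("unknown metric name: ", metric, " (known: ",
         paste(names(reg), collapse = ", "), ")")
  reg[[metric]]
}

#' Adaptive (per-group) metric evaluation
#'
#' Computes each requested metric independently inside each group of
#' examples — typically the ground-truth class, so reliability can be
#' assessed per class rather than only globally — and reports the
#' unweighted macro average across groups alongside the global value. A
#' set can be perfectly calibrated globally yet badly miscalibrated within
#' every class; the per-group table exposes exactly that.
#'
#' Metrics requiring both classes (AUC, balanced accuracy) are skipped
#' with a warning in single-class groups and excluded from that metric's
#' macro average.
#'
#' @param ps a prediction set.
#' @param groups vector of group labels, one per example.
#' @param metrics character vector of registered metric names (see
#'   [uq_metrics()]) or a named list of functions `f(ps) -> scalar`.
#' @param ... passed to each metric (e.g. `n_bins`, `mode`).
#' @return list of class `"adaptive_eval"` with `per_group` (data frame,
#'   one row per group), `macro` (named numeric, unweighted mean over
#'   groups) and `global` (named numeric on the full set).
#' @export
adaptive_evaluate <- function(ps, groups, metrics, ...) {
  validate_predictions(ps)
  if (length(groups) != n_examples(ps))
    stop("groups must have one label per example")
  if (is.character(metrics)) {
    metrics <- stats::setNames(as.list(metrics), metrics)
  }
  gl <- sort(unique(groups))
  rows <- lapply(gl, function(g) {
    sub <- ps_subset(ps, which(groups == g))
    vals <- vapply(names(metrics), function(mn) {
      m <- resolve_metric(metrics[[mn]])
      if (isTRUE(m$both_classes) && length(unique(sub$y_true)) < 2) {
        warning(sprintf("metric '%s' skipped in single-class group '%s'",
                        mn, g))
        return(NA_real_)
      }
      m$fn(sub, ...)
    }, numeric(1))
    c(count = n_examples(sub), vals)
  })
  per_group <- data.frame(group = gl, do.call(rbind, rows),
                          check.names = FALSE)
  macro <- colMeans(per_group[, -(1:2), drop = FALSE], na.rm = TRUE)
  global <- vapply(names(metrics), function(mn)
    resolve_metric(metrics[[mn]])$fn(ps, ...), numeric(1))
  structure(list(per_group = per_group, macro = macro, global = global),
            class = "adaptive_eval")
}

#' @export
print.adaptive_eval <- function(x, ...) {
  cat("<adaptive_eval>\n\nPer-group metrics:\n")
  print(x$per_group, row.names = FALSE)
  cat("\nMacro average (unweighted over groups):\n")
  print(round(x$macro, 6))
  cat("\nGlobal:\n")
  print(round(x$global, 6))
  invisible(x)
}

#' Names of the registered scalar metrics
#' @return character vector of metric names usable in
#'   [adaptive_evaluate()] and [bootstrap_compare()].
#' @export
uq_metrics <- function() names(metric_registry())

#' Paired bootstrap comparison of two prediction sets
#'
#' Assesses whether two models (or UQ methods) differ on a metric by
#' paired resampling: both sets share the same examples, so each bootstrap
#' replicate resamples example indices once and evaluates the metric on
#' both sets, giving a difference `metric(a) - metric(b)` per replicate.
#' Reported are the observed difference, the percentile 95% interval, and
#' a two-sided sign-based p-value
#' `p = 2 min(frac <= 0, frac >= 0)` clipped to `[1/n_boot, 1]`.
#'
#' @param ps_a,ps_b prediction sets over the identical examples (equal
#'   length, shared ground truth).
#' @param metric registered metric name or function `f(ps) -> scalar`.
#' @param n_boot number of bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @param conf confidence level of the percentile interval.
#' @param ... passed to the metric.
#' @return list of class `"bootstrap_compare"` with `estimate`, `ci`
#'   (length-2), `p_value`, `replicates`.
#' @export
bootstrap_compare <- function(ps_a, ps_b, metric, n_boot = 2000, seed = 1,
                              conf = 0.95, ...) {
  validate_predictions(ps_a); validate_predictions(ps_b)
  n <- n_examples(ps_a)
  if (n_examples(ps_b) != n)
    stop("prediction sets must have equal length")
  if (!isTRUE(all.equal(ps_a$y_true, ps_b$y_true)))
    stop("prediction sets must share ground truth")
  m <- resolve_metric(metric)
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    m$fn(ps_subset(ps_a, idx), ...) - m$fn(ps_subset(ps_b, idx), ...)
  }, numeric(1))
  est <- m$fn(ps_a, ...) - m$fn(ps_b, ...)
  ci <- stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  p <- 2 * min(mean(reps <= 0), mean(reps >= 0))
  p <- min(max(p, 1 / n_boot), 1)
  structure(list(estimate = est, ci = ci, p_value = p, replicates = reps,
                 n_boot = n_boot, conf = conf),
            class = "bootstrap_compare")
}

#' @export
print.bootstrap_compare <- function(x, ...) {
  cat(sprintf("<bootstrap_compare> difference %.6g, %d%% CI [%.6g, %.6g], p = %.4g (%d replicates)\n",
              x$estimate, round(100 * x$conf), x$ci[1], x$ci[2], x$p_value,
              x$n_boot))
  invisible(x)
}
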