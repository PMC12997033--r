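#' Full metric report for a prediction set
#'
#' Computes every metric applicable to the input's output type, converting
#' between types where a conversion is defined (interval and quantile sets
#' are refitted to Gaussians under the exact-z convention before
#' variance-based metrics; each conversion applied is recorded in the
#' report). Classification sets get the confidence and entropy calibration
#' suite; Gaussian sets get the variance-calibration, coverage and scoring
#' suite plus reliability tables.
#'
#' @param ps a prediction set.
#' @param n_bins bins for the binned calibration metrics (default 10).
#' @param ece_mode `"squared"` (default) or `"absolute"`.
#' @param baseline_median training-split median of the target; when
#'   supplied, MAE/MASE are included for regression sets.
#' @param groups optional per-example labels; when supplied, a per-group
#'   [adaptive_evaluate()] sub-report is attached.
#' @param cce_levels coverage grid for [cce()].
#' @param seed recorded in the report for provenance.
#' @return list of class `"uq_report"`: `task`, `n`, `metrics` (named
#'   scalars), `tables` (bin tables, coverage curve), `conversions`
#'   (character log), optional `stratified`.
#' @export
evaluate_predictions <- function(ps, n_bins = 10,
                                 ece_mode = c("squared", "absolute"),
                                 baseline_median = NULL, groups = NULL,
                                 cce_levels = seq(0.05, 0.95, by = 0.05),
                                 seed = NULL) {
  validate_predictions(ps)
  ece_mode <- match.arg(ece_mode)
  conversions <- character()
  metrics <- list(); tables <- list()
  if (inherits(ps, "binary_predictions")) {
    task <- "classification"
    metrics <- list(
      ece = ece(ps, n_bins, ece_mode),
      ace = if (n_examples(ps) >= n_bins) ace(ps, n_bins, ece_mode) else NA_real_,
      smece = as.numeric(smece(ps)),
      uce = uce(ps, n_bins, ece_mode),
      vce = vce(ps, n_bins, ece_mode),
      nll = nll_cls(ps))
    if (length(unique(ps$y_true)) > 1) {
      metrics$auc <- auc(ps)
      metrics$balanced_accuracy <- balanced_accuracy(ps)
    }
    tables$confidence_bins <- bin_table_cls(ps, "confidence", "equal-width", n_bins)
    tables$entropy_bins <- bin_table_cls(ps, "entropy", "equal-width", n_bins)
    if (is.null(ps$logit_mu))
      conversions <- c(conversions, "logit fields absent; entropy metrics from p1")
  } else {
    task <- "regression"
    gps <- ps
    if (inherits(ps, "quantile_predictions")) {
      gps <- quantiles_to_gaussian(ps)
      conversions <- c(conversions, "quantiles -> Gaussian (midpoint mean, exact z)")
    } else if (inherits(ps, "interval_predictions")) {
      metrics$picp <- picp(ps)
      gps <- interval_to_gaussian(ps)
      conversions <- c(conversions, "interval -> Gaussian (midpoint mean, exact z)")
    }
    cc <- cce(gps, cce_levels)
    metrics <- c(metrics, list(
      crps = crps_gaussian(gps),
      nll = nll_gaussian(gps),
      ence = if (n_examples(gps) >= n_bins) ence(gps, n_bins) else NA_real_,
      picp_1sigma = picp(gps, 1),
      picp_2sigma = picp(gps, 2),
      cce = as.numeric(cc),
      mae = mean(abs(gps$y_true - gps$mu))))
    if (!is.null(baseline_median))
      metrics$mase <- mae_mase(gps, baseline_median)$mase
    if (n_examples(gps) >= n_bins)
      tables$sigma_bins <- bin_table_reg(gps, n_bins)
    tables$coverage_curve <- attr(cc, "curve")
  }
  report <- structure(
    list(task = task, n = n_examples(ps),
         metrics = lapply(metrics, as.numeric),
         tables = tables, conversions = conversions,
         version = as.character(utils::packageVersion("uqeval")),
         seed = seed),
    class = "uq_report")
  if (!is.null(groups)) {
    mset <- if (task == "classification")
      c("ece", "ace", "smece", "uce", "vce", "nll")
    else c("crps", "nll", "ence", "picp_1sigma", "cce", "mae")
    report$stratified <- adaptive_evaluate(ps, groups, mset)
  }
  report
}

#' @export
print.uq_report <- function(x, ...) {
  cat(sprintf("<uq_report> task: %s, n = %d\n", x$task, x$n))
  m <- unlist(x$metrics)
  for (nm in names(m)) cat(sprintf("  %-18s %.6g\n", nm, m[nm]))
  if (length(x$conversions))
    cat("conversions:", paste(x$conversions, collapse = "; "), "\n")
  if (!is.null(x$stratified)) {
    cat("\nStratified:\n"); print(x$stratified)
  }
  invisible(x)
}

#' Serialize a metric report
#'
#' Writes the scalar metrics (plus provenance: package version, seed,
#' conversions applied) as JSON and each table as CSV next to it.
#'
#' @param report a `"uq_report"`.
#' @param prefix output path prefix; writes `<prefix>.json` and
#'   `<prefix>_<table>.csv`.
#' @return invisible character vector of paths written.
#' @export
write_report <- function(report, prefix) {
  paths <- paste0(prefix, ".json")
  payload <- list(task = report$task, n = report$n,
                  version = report$version, seed = report$seed,
                  conversions = report$conversions,
                  metrics = report$metrics)
  if (!is.null(report$stratified)) {
    payload$stratified <- list(
      macro = as.list(report$stratified$macro),
      per_group = report$stratified$per_group)
  }
  jsonlite::write_json(payload, paths[1], auto_unbox = TRUE, digits = NA)
  for (nm in names(report$tables)) {
    p <- paste0(prefix, "_", nm, ".csv")
    utils::write.csv(report$tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
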