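#' Read and write prediction sets as CSV
#'
#' Prediction sets are exchanged as plain CSV with a header row, one example
#' per line, values written at full double precision so a write/read round
#' trip reproduces the set to machine accuracy. The column layout identifies
#' the output type:
#'
#' * Gaussian: `y_true, mu, var`
#' * binary: `y_true, p1` with optional `logit_mu, logit_var`
#' * quantile: `y_true, q_<level>` with the nominal level encoded in the
#'   column name to 4 decimals (e.g. `q_0.1587`)
#' * interval: `y_true, lo, hi`, with `nominal_level` stored in a JSON
#'   sidecar at `<path>.json`
#' * ensemble stack: long format with a `member_id` column (1..K) and the
#'   member columns of the underlying task.
#'
#' `read_predictions()` infers the type from the header unless `type` is
#' given, and validates the result.
#'
#' @param ps a prediction set or [ensemble_stack()].
#' @param path CSV file path.
#' @param type one of `"auto"`, `"gaussian"`, `"binary"`, `"quantile"`,
#'   `"interval"`, `"ensemble"`.
#' @param nominal_level central coverage for interval sets, used only when
#'   the JSON sidecar is absent.
#' @return `write_predictions()` returns `path` invisibly;
#'   `read_predictions()` returns a validated prediction set.
#' @export
write_predictions <- function(ps, path) {
  if (inherits(ps, "ensemble_stack")) {
    K <- n_members(ps); n <- n_examples(ps)
    if (ps$task == "regression") {
      df <- data.frame(member_id = rep(seq_len(K), each = n),
                       y_true = rep(ps$y_true, K),
                       mu = as.vector(ps$mu), var = as.vector(ps$var))
    } else {
      df <- data.frame(member_id = rep(seq_len(K), each = n),
                       y_true = rep(ps$y_true, K),
                       logit_mu = as.vector(ps$logit_mu),
                       logit_var = as.vector(ps$logit_var))
    }
  } else {
    df <- as.data.frame(ps)
  }
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (inherits(ps, "interval_predictions"))
    jsonlite::write_json(list(nominal_level = ps$nominal_level),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path, type = "auto", nominal_level = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  cols <- names(df)
  if (type == "auto") {
    type <-
      if ("member_id" %in% cols) "ensemble"
      else if (all(c("mu", "var") %in% cols)) "gaussian"
      else if ("p1" %in% cols) "binary"
      else if (any(grepl("^q_", cols))) "quantile"
      else if (all(c("lo", "hi") %in% cols)) "interval"
      else stop("cannot infer prediction-set type from columns: ",
                paste(cols, collapse = ", "))
  }
  switch(type,
    gaussian = gaussian_predictions(df$y_true, df$mu, df$var),
    binary = binary_predictions(df$y_true, df$p1,
                                logit_mu = df[["logit_mu"]],
                                logit_var = df[["logit_var"]]),
    quantile = {
      qcols <- grep("^q_", cols, value = TRUE)
      levels <- as.numeric(sub("^q_", "", qcols))
      ord <- order(levels)
      quantile_predictions(df$y_true, as.matrix(df[qcols[ord]]),
                           levels = levels[ord])
    },
    interval = {
      side <- paste0(path, ".json")
      if (is.null(nominal_level)) {
        if (!file.exists(side))
          stop("interval CSV requires a nominal_level (sidecar ", side,
               " not found)")
        nominal_level <- jsonlite::read_json(side)$nominal_level
      }
      interval_predictions(df$y_true, df$lo, df$hi, nominal_level)
    },
    ensemble = {
      ids <- sort(unique(df$member_id))
      first <- df[df$member_id == ids[1], ]
      task <- if ("mu" %in% cols) "regression" else "classification"
      pick <- function(col) vapply(ids, function(k)
        df[df$member_id == k, col], numeric(nrow(first)))
      if (task == "regression")
        ensemble_stack("regression", first$y_true,
                       mu = pick("mu"), var = pick("var"))
      else
        ensemble_stack("classification", first$y_true,
                       logit_mu = pick("logit_mu"),
                       logit_var = pick("logit_var"))
    },
    stop("unknown prediction-set type: ", type))
}
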