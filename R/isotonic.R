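#' Weighted isotonic regression by pool-adjacent-violators
#'
#' Least-squares nondecreasing fit of `y` on `x` with observation weights.
#' Ties in `x` are pooled (weighted mean) before the PAV sweep so the fit
#' is a single-valued nondecreasing step function of `x`. Written
#' in-package because the Venn-ABERS calibrator needs weighted observations
#' and evaluation of the fitted step function at arbitrary new scores.
#'
#' @param x numeric predictor (scores).
#' @param y numeric response.
#' @param w positive observation weights.
#' @return list with `x` (unique sorted knots), `fit` (nondecreasing fitted
#'   value per knot), and `predict(newx)` evaluating the right-continuous
#'   piecewise-constant step function, clamped to the end values outside
#'   the knot range.
#' @export
isotonic_fit <- function(x, y, w = rep(1, length(y))) {
  stopifnot(length(x) == length(y), length(w) == length(y), all(w > 0))
  ord <- order(x)
  x <- x[ord]; y <- y[ord]; w <- w[ord]
  # pool exact ties in x
  grp <- cumsum(c(TRUE, diff(x) > 0))
  ux <- x[!duplicated(grp)]
  uw <- as.numeric(tapply(w, grp, sum))
  uy <- as.numeric(tapply(w * y, grp, sum)) / uw
  m <- length(ux)
  # stack-based PAVA over blocks
  val <- numeric(m); wt <- numeric(m); len <- integer(m); nb <- 0L
  for (i in seq_len(m)) {
    nb <- nb + 1L
    val[nb] <- uy[i]; wt[nb] <- uw[i]; len[nb] <- 1L
    while (nb > 1L && val[nb] < val[nb - 1L]) {
      val[nb - 1L] <- (val[nb] * wt[nb] + val[nb - 1L] * wt[nb - 1L]) /
        (wt[nb] + wt[nb - 1L])
      wt[nb - 1L] <- wt[nb] + wt[nb - 1L]
      len[nb - 1L] <- len[nb] + len[nb - 1L]
      nb <- nb - 1L
    }
  }
  fit <- rep(val[seq_len(nb)], len[seq_len(nb)])
  structure(list(
    x = ux, fit = fit,
    predict = function(newx) {
      if (length(ux) == 1L) return(rep(fit, length(newx)))
      stats::approx(ux, fit, xout = newx, method = "constant",
                    f = 0, rule = 2, ties = "ordered")$y
    }),
    class = "isotonic_fit")
}

#' @export
print.isotonic_fit <- function(x, ...) {
  cat(sprintf("<isotonic_fit> %d knots, fitted range [%.4g, %.4g]\n",
              length(x$x), min(x$fit), max(x$fit)))
  invisible(x)
}
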