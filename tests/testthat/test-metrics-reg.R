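test_that("sigma bin tables match a sort-and-split oracle", {
  gps <- gaussian_predictions(y_true = c(0, 1, 2, 3, 4, 5),
                              mu = rep(0, 6),
                              var = c(1, 4, 9, 16, 25, 36))
  tab <- bin_table_reg(gps, n_bins = 2)
  expect_equal(tab$count, c(3, 3))
  expect_equal(tab$rmv, c(sqrt(mean(c(1, 4, 9))), sqrt(mean(c(16, 25, 36)))))
  expect_equal(tab$rmse, c(sqrt(mean(c(0, 1, 4))), sqrt(mean(c(9, 16, 25)))))
  expect_equal(sum(tab$count), 6)
  # homoscedastic spread collapses to one effective equal-width bin
  homo <- gaussian_predictions(rnorm(20), rep(0, 20), rep(4, 20))
  expect_equal(nrow(bin_table_reg(homo, 2, scheme = "equal-width")), 1)
})

test_that("ENCE matches hand averages and the analytic distortion value", {
  # two equal-count bins with normalized discrepancies 0.1 and 0.3
  gps <- gaussian_predictions(
    y_true = c(rep(0.9, 50), rep(3.9, 50)),
    mu = rep(0, 100),
    var = c(rep(1, 50), rep(9, 50)))
  tab <- bin_table_reg(gps, 2)
  expect_equal(abs(tab$rmv - tab$rmse) / tab$rmv, c(0.1, 0.3))
  expect_equal(ence(gps, 2), 0.2)
  expect_equal(ence(gps, 2, normalized = FALSE),
               sum(0.5 * abs(tab$rmv - tab$rmse)))

  # residuals equal to sigma in every bin: perfect variance calibration
  perfect <- gaussian_predictions(c(1, 2, 4), c(0, 0, 0), c(1, 4, 16))
  expect_equal(ence(perfect, n_bins = 3), 0)

  # sigma underreported by 2x: RMSE/RMV -> 2, ENCE -> 1
  gps2 <- rand_gaussian_set(1e5, seed = 51, c = 0.5)
  expect_lt(abs(ence(gps2) - 1), 0.05)
})

test_that("Gaussian CRPS closed form matches numerical integration", {
  expect_equal(crps_gaussian(gaussian_predictions(0, 0, 1)),
               2 * dnorm(0) - 1 / sqrt(pi))
  expect_equal(crps_gaussian(gaussian_predictions(0, 0, 1)), 0.2337,
               tolerance = 1e-3)
  # homogeneity: CRPS scales linearly with sigma at fixed z
  z <- 0.8
  for (s in c(0.5, 2, 7)) {
    expect_equal(crps_gaussian(gaussian_predictions(z * s, 0, s^2)),
                 s * crps_gaussian(gaussian_predictions(z, 0, 1)),
                 tolerance = 1e-12)
  }
  crps_quad <- function(y, mu, sigma) {
    # split at the observation where the step CDF jumps
    lo <- min(mu - 12 * sigma, y - 1); hi <- max(mu + 12 * sigma, y + 1)
    integrate(function(t) pnorm(t, mu, sigma)^2, lo, y,
              rel.tol = 1e-10, subdivisions = 2000L)$value +
      integrate(function(t) (pnorm(t, mu, sigma) - 1)^2, y, hi,
                rel.tol = 1e-10, subdivisions = 2000L)$value
  }
  set.seed(52)
  for (k in 1:100) {
    mu <- rnorm(1); sigma <- exp(rnorm(1, 0, 0.5)); y <- rnorm(1, mu, 2 * sigma)
    expect_equal(crps_gaussian(gaussian_predictions(y, mu, sigma^2)),
                 crps_quad(y, mu, sigma), tolerance = 1e-6)
  }
})

test_that("CRPS does not exceed MAE on random sets", {
  for (seed in 53:55) {
    gps <- rand_gaussian_set(500, seed = seed, c = runif(1, 0.5, 2))
    expect_lte(crps_gaussian(gps), mean(abs(gps$y_true - gps$mu)))
  }
})

test_that("PICP is the coverage ratio with optimum one", {
  inside <- interval_predictions(c(0, 1), c(-1, 0), c(1, 2),
                                 nominal_level = 2 * pnorm(1) - 1)
  expect_equal(picp(inside), 1 / (2 * pnorm(1) - 1))
  expect_equal(picp(inside), 1.465, tolerance = 1e-3)
  outside <- interval_predictions(c(5, 5), c(-1, 0), c(1, 2), 0.6827)
  expect_equal(picp(outside), 0)
  gps <- rand_gaussian_set(2e5, seed = 56)
  expect_lt(abs(picp(gps, 1) - 1), 0.01)
})

test_that("CCE integrates squared coverage gaps over the level grid", {
  gps <- rand_gaussian_set(2e5, seed = 57)
  expect_lt(as.numeric(cce(gps)), 1e-3)
  # degenerate zero-width intervals: empirical coverage 0 at every level
  tiny <- gaussian_predictions(c(1, 2), c(0, 0), c(1e-30, 1e-30))
  lv <- seq(0.05, 0.95, by = 0.05)
  expect_equal(as.numeric(cce(tiny, lv)), mean(lv^2))
  # single-level CCE is consistent with PICP at one sigma
  l1 <- 2 * pnorm(1) - 1
  v <- cce(gps, levels = l1)
  emp <- picp(gps, 1) * l1
  expect_equal(as.numeric(v), (l1 - emp)^2, tolerance = 1e-12)
  curve <- attr(cce(gps), "curve")
  expect_true(all(curve$empirical >= 0 & curve$empirical <= 1))
})

test_that("Gaussian NLL evaluates the scoring rule and matches variance scaling", {
  expect_equal(nll_gaussian(gaussian_predictions(3, 3, 1)), 0.5 * log(2 * pi))
  gps <- rand_gaussian_set(2000, seed = 58, c = 0.6)
  # over a constant variance factor, NLL is minimized exactly at the
  # mean squared standardized residual (the variance-scaling fit)
  s_hat <- mean((gps$y_true - gps$mu)^2 / gps$var)
  nll_s <- function(s) nll_gaussian(gaussian_predictions(gps$y_true, gps$mu,
                                                         gps$var * s))
  expect_lt(nll_s(s_hat), nll_s(s_hat * 1.05))
  expect_lt(nll_s(s_hat), nll_s(s_hat * 0.95))
  set.seed(59); perm <- sample(2000)
  expect_equal(nll_gaussian(ps_subset(gps, perm)), nll_gaussian(gps))
})

test_that("MAE and MASE scale against the constant-median baseline", {
  res <- mae_mase(gaussian_predictions(14.91, 14.91 - 10.53, 1),
                  baseline_median = 0)
  expect_equal(res$mae, 10.53)
  expect_equal(res$mase, 10.53 / 14.91)
  expect_equal(round(res$mase, 2), 0.71)
  y <- c(1, 2, 3)
  expect_equal(mae_mase(rep(2, 3), baseline_median = 2, y_true = y)$mase, 1)
  expect_equal(mae_mase(y, baseline_median = 0, y_true = y)$mae, 0)
  expect_error(mae_mase(y, baseline_median = 2, y_true = rep(2, 3)), "zero")
})

test_that("the bivariate error histogram covers and concentrates correctly", {
  set.seed(60)
  n <- 1e4
  sigma <- exp(rnorm(n, 0, 0.3))
  err <- abs(rnorm(n, 0, sigma)) # half-normal errors tracking sigma
  gps <- gaussian_predictions(err, rep(0, n), sigma^2)
  h <- bivariate_error_histogram(gps, 20, 20)
  expect_equal(sum(h), n)
  xb <- attr(h, "x_breaks"); yb <- attr(h, "y_breaks")
  expect_lte(xb[1], min(sigma)); expect_gte(xb[21], max(sigma))
  expect_lte(yb[1], min(err)); expect_gte(yb[21], max(err))
  # small-scale reliability: the factor-2 band around the diagonal holds the
  # half-normal mass 2 (Phi(2) - Phi(0.5)) ~= 0.571
  band <- mean(err >= sigma / 2 & err <= sigma * 2)
  expect_equal(band, 2 * (pnorm(2) - pnorm(0.5)), tolerance = 0.05)
  expect_gte(band, 0.55)
})

test_that("inflating calibrated sigmas strictly increases ENCE and CCE", {
  gps <- rand_gaussian_set(2e4, seed = 61)
  for (cf in c(0.7, 1.4)) {
    inflated <- gaussian_predictions(gps$y_true, gps$mu, gps$var * cf^2)
    expect_gt(ence(inflated), ence(gps))
    expect_gt(as.numeric(cce(inflated)), as.numeric(cce(gps)))
  }
})
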