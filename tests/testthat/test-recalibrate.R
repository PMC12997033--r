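split_halves <- function(ps) {
  n <- n_examples(ps)
  list(calib = ps_subset(ps, seq_len(n %/% 2)),
       test = ps_subset(ps, (n %/% 2 + 1):n))
}

test_that("temperature scaling recovers the generating temperature", {
  for (T_true in c(0.5, 2)) {
    sp <- split_halves(simulate_classification(4e4, T_true = T_true,
                                               seed = 21))
    fit <- fit_temperature_cls(sp$calib, sp$test)
    expect_lt(abs(fit$temperature - T_true), 0.05 * T_true)
  }
  sp <- split_halves(simulate_classification(4e4, T_true = 1, seed = 22))
  fit <- fit_temperature_cls(sp$calib, sp$test)
  expect_lt(abs(fit$temperature - 1), 0.05)
})

test_that("identity temperature leaves probabilities unchanged and NLL never degrades", {
  sp <- split_halves(rand_binary_set(2000, seed = 23))
  fit <- fit_temperature_cls(sp$calib, sp$test)
  # optimizer sanity: calibration NLL at the optimum <= NLL at T = 1
  expect_lte(fit$calib_nll, nll_cls(sp$calib) + 1e-10)
  # applying T = 1 manually is the identity up to probability clipping
  p_id <- plogis(qlogis(pmin(pmax(sp$test$p1, 1e-6), 1 - 1e-6)) / 1)
  expect_equal(p_id, sp$test$p1, tolerance = 1e-9)
  expect_error(fit_temperature_cls(binary_predictions(c(1, 1), c(0.6, 0.7)),
                                   sp$test), "both classes")
})

test_that("variance scaling has the closed-form GNLL minimiser", {
  sp <- split_halves(rand_gaussian_set(1e5, seed = 24, c = 0.5))
  fit <- fit_variance_scale_reg(sp$calib, sp$test)
  expect_lt(abs(fit$scale - 4), 0.15) # reported var = true var / 4
  expect_equal(fit$test$mu, sp$test$mu)

  sp1 <- split_halves(rand_gaussian_set(1e5, seed = 25, c = 1))
  expect_lt(abs(fit_variance_scale_reg(sp1$calib, sp1$test)$scale - 1), 0.05)

  degen <- gaussian_predictions(c(1, 2), c(1, 2), c(1, 1))
  expect_warning(fit <- fit_variance_scale_reg(degen, degen), "clamped")
  expect_equal(fit$scale, 1e-6)

  # scaled-variance NLL on the calibration split never exceeds the original
  nll0 <- nll_gaussian(sp$calib)
  fitc <- suppressWarnings(fit_variance_scale_reg(sp$calib, sp$calib))
  expect_lte(nll_gaussian(fitc$test), nll0 + 1e-10)
})

test_that("isotonic classification calibration reproduces hand PAV fits", {
  calib <- binary_predictions(c(0, 0, 1, 1), c(0.2, 0.3, 0.6, 0.9))
  test <- binary_predictions(1, 0.7)
  fit <- fit_isotonic_cls(calib, test)
  expect_equal(fit$map$fit, c(0, 0, 1, 1))
  expect_equal(fit$test$p1, 1 - 1e-6) # mapped to 1, then clipped

  # anti-calibrated labels pool into a single constant block at 0.5
  anti <- binary_predictions(c(1, 1, 0, 0), c(0.2, 0.3, 0.6, 0.9))
  fit2 <- fit_isotonic_cls(anti, test)
  expect_equal(unique(fit2$map$fit), 0.5)

  # fixed point: probabilities equal to empirical frequencies map to themselves
  fp <- binary_predictions(c(1, 0, 0, 1, 1, 0), rep(c(1/3, 2/3), each = 3))
  fit3 <- fit_isotonic_cls(fp, fp)
  expect_equal(fit3$map$fit, c(1/3, 2/3))
  expect_equal(fit3$test$p1, fp$p1, tolerance = 1e-9)
  # monotone in the input probability
  ord <- order(fp$p1)
  expect_true(all(diff(fit3$test$p1[ord]) >= -1e-12))
})

test_that("PIT recalibration recovers multiplicatively distorted spreads", {
  sp <- split_halves(rand_gaussian_set(1e5, seed = 26, c = 0.5))
  fit <- fit_isotonic_reg(sp$calib, sp$test)
  ratio <- sqrt(fit$test$var) / sqrt(sp$test$var)
  expect_lt(sqrt(mean((ratio - 2)^2)), 0.2) # sigmas roughly doubled
  expect_equal(fit$test$mu, sp$test$mu, tolerance = 1e-9)

  spc <- split_halves(rand_gaussian_set(1e5, seed = 27, c = 1))
  fitc <- fit_isotonic_reg(spc$calib, spc$test)
  rel <- sqrt(fitc$test$var) / sqrt(spc$test$var) - 1
  expect_lt(sqrt(mean(rel^2)), 0.05) # calibrated input barely changes

  expect_error(fit_isotonic_reg(ps_subset(sp$calib, 1:5), sp$test), ">= 20")
  degen <- gaussian_predictions(rep(0, 30), rep(0, 30), rep(1, 30))
  expect_warning(fit_isotonic_reg(degen, degen), "degenerate")
})

test_that("split-conformal quantile uses the finite-sample order statistic", {
  calib <- gaussian_predictions(y_true = c(1, 2, 3, 4), mu = rep(0, 4),
                                var = rep(1, 4)) # scores {1,2,3,4}
  test <- gaussian_predictions(0, 0, 1)
  fit <- conformalize_gaussian(calib, test, alpha = 0.2)
  expect_equal(fit$q_hat, 4) # rank ceil(5 * 0.8) = 4
  expect_equal(c(fit$test$lo, fit$test$hi), c(-4, 4))
  expect_equal(fit$test$nominal_level, 0.8)

  expect_equal(conformalize_gaussian(calib, test, alpha = 0.99)$q_hat, 1)
  expect_error(conformalize_gaussian(calib, test, alpha = 0.01),
               "too small")
})

test_that("CQR widens or shrinks the quantile band by the conformal correction", {
  lv <- c(0.1587, 0.8413)
  calib <- quantile_predictions(rep(0, 5),
                                cbind(rep(-2, 5), rep(2, 5)), lv)
  test <- quantile_predictions(0, matrix(c(-2, 2), 1), lv)
  fit <- conformalize_quantiles(calib, test, alpha = 0.2)
  expect_equal(fit$q_hat, -2) # all scores max(-2 - 0, 0 - 2) = -2: shrink
  expect_equal(c(fit$test$lo, fit$test$hi), c(0, 0))

  # zero correction leaves the band unchanged
  calib2 <- quantile_predictions(c(-2, 2, 0, 1, -1),
                                 cbind(rep(-2, 5), rep(2, 5)), lv)
  fit2 <- conformalize_quantiles(calib2, test, alpha = 0.2)
  expect_equal(fit2$q_hat, 0)
  expect_equal(c(fit2$test$lo, fit2$test$hi), c(-2, 2))
})

test_that("split conformal attains its marginal coverage guarantee", {
  set.seed(28)
  alpha <- 0.1; n_cal <- 1000; n_tst <- 500; reps <- 500
  cov_cmap <- cov_cqr <- numeric(reps)
  z_hi <- qnorm(0.8413)
  for (r in seq_len(reps)) {
    sig <- exp(rnorm(n_cal + n_tst, 0, 0.3))
    y <- rnorm(n_cal + n_tst, 0, sig)
    idc <- seq_len(n_cal); idt <- n_cal + seq_len(n_tst)
    calib <- gaussian_predictions(y[idc], rep(0, n_cal), sig[idc]^2)
    test <- gaussian_predictions(y[idt], rep(0, n_tst), sig[idt]^2)
    f <- conformalize_gaussian(calib, test, alpha)
    cov_cmap[r] <- mean(y[idt] >= f$test$lo & y[idt] <= f$test$hi)
    # deliberately narrow quantile bands; CQR must widen them back
    qc <- cbind(-0.8 * z_hi * sig[idc], 0.8 * z_hi * sig[idc])
    qt <- cbind(-0.8 * z_hi * sig[idt], 0.8 * z_hi * sig[idt])
    fq <- conformalize_quantiles(
      quantile_predictions(y[idc], qc), quantile_predictions(y[idt], qt),
      alpha)
    cov_cqr[r] <- mean(y[idt] >= fq$test$lo & y[idt] <= fq$test$hi)
  }
  for (cv in list(cov_cmap, cov_cqr)) {
    mc_err <- 3 * sd(cv) / sqrt(reps)
    expect_gte(mean(cv), 1 - alpha - mc_err)
    expect_lte(mean(cv), 1 - alpha + 1 / (n_cal + 1) + mc_err)
  }
})

test_that("Venn-ABERS produces ordered probability intervals", {
  # perfectly separating calibration scores; test score above all
  calib <- binary_predictions(c(rep(0, 4), rep(1, 3)),
                              c(0.1, 0.2, 0.3, 0.4, 0.7, 0.8, 0.9))
  test <- binary_predictions(1, 0.95)
  va <- venn_abers_predict(calib, test)
  expect_equal(va$intervals$p1, 1)
  expect_equal(va$intervals$p0, 3 / 4) # n1 / (n1 + 1)

  # balanced calibration with one shared score: merged p = 0.5 within 1/n
  n <- 10
  calib2 <- binary_predictions(rep(c(0, 1), n / 2), rep(0.5, n))
  va2 <- venn_abers_predict(calib2, binary_predictions(0, 0.5))
  expect_lt(abs(va2$intervals$p - 0.5), 1 / n + 1e-12)

  # structural properties on random inputs
  va3 <- venn_abers_predict(rand_binary_set(200, seed = 29),
                            rand_binary_set(50, seed = 30))
  expect_true(all(va3$intervals$p0 <= va3$intervals$p1 + 1e-12))
  expect_true(all(va3$intervals$p >= 0 & va3$intervals$p <= 1))
  expect_error(venn_abers_predict(binary_predictions(1, 0.5), test),
               "both classes")
})
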