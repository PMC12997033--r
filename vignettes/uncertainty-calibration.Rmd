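---
title: "Evaluating and recalibrating predictive uncertainty with uqeval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating and recalibrating predictive uncertainty with uqeval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uqeval)
```

## The problem

A probabilistic predictor attaches a distribution to each example: a
Gaussian $\mathcal N(\mu_i, \sigma_i^2)$ for a continuous target such as
systolic blood pressure, or a class probability $p_i$ for a binary outcome
such as atrial fibrillation. The prediction is *calibrated* when the
stated uncertainty matches observed outcome frequencies — when 68% of
targets fall inside $\mu \pm \sigma$, when events predicted at 0.8 happen
80% of the time. Calibration is distinct from *sharpness* (how
concentrated the distributions are) and can hold globally while failing
within every subgroup, which is why this package evaluates at several
scales: global scalars, binned (local) reliability tables, and adaptive
per-group reports.

`uqeval` covers the full path from raw model outputs to a verdict:
aggregate ensemble members, convert between output types, recalibrate on
a held-out split, score with a battery of metrics, stratify, and compare
methods by paired bootstrap.

## Containers and conventions

Four prediction-set types (Gaussian, binary, quantile, interval) plus an
ensemble stack carry per-example ground truth alongside the model output.
Conventions applied throughout:

- **Variance is canonical** for regression spread; standard deviations are
  derived on demand (`pred_sigma()`), never stored, avoiding unit mix-ups.
- **Optional logit fields** (mean and variance on the logit scale, from
  dropout passes or ensembles) are either both present or both absent.
- **0-based example indices** in validation error messages.
- **Confidence** for binary outputs means the probability of the
  *predicted* class, $\max(p, 1-p) \in [0.5, 1]$, the reliability-diagram
  axis; the predicted class is 1 when $p \ge 0.5$.
- **Entropies are base 2** by default so binary entropy lives in $[0,1]$
  and is unit-compatible with error rates in UCE/VCE.
- The symmetric quantile pairs $(0.1587, 0.8413)$ and $(0.0228, 0.9772)$
  are the central one- and two-standard-deviation bands of a Gaussian;
  conversions use the exact inverse-normal of the supplied level
  ($z(0.8413) = 0.99982$, not snapped to 1 — a $\le 0.02\%$ effect).
- Interval and quantile outputs convert to Gaussians via the **midpoint**
  (not the median prediction) and the halfwidth divided by the exact $z$;
  this keeps point predictions and MAE identical across pre-/post-
  recalibration comparisons.

## Aggregation

For $K$ regression members the law of total variance gives
$\mu^* = \frac1K\sum_k \mu_k$ and
$\sigma^{*2} = \frac1K\sum_k \sigma_k^2 + \frac1K\sum_k (\mu_k - \mu^*)^2$:
the within-member (aleatoric) term plus the between-member (epistemic)
term. The *population* ($K$-denominator) variance of member means is used
because the members are the entire ensemble, not a sample from a larger
population of models.

Classification members carry logit-scale Gaussians; each is propagated
through the logistic function by Monte Carlo (default 100 draws per
member, seeded), and all noise-corrupted probabilities are averaged. The
draw count and seed are configuration because no canonical value exists;
with zero logit variance and one draw the aggregate reduces exactly to
the mean of member probabilities.

## Recalibration methods

All methods fit on a calibration split and transform a disjoint test
split.

- **Temperature scaling**: $p(T) = \mathrm{logistic}(\mathrm{logit}(p)/T)$
  with $T$ minimising calibration NLL, found by bounded scalar search on
  $[0.05, 20]$. $T$ is fitted on the post-aggregation probability.
- **Variance scaling**: the regression analogue, with the closed-form
  Gaussian-NLL minimiser $s = \overline{(y-\mu)^2/\sigma^2}$ — exact and
  deterministic, so no iterative optimiser is involved. Degenerate
  zero-residual calibration sets clamp $s$ to $10^{-6}$ with a warning.
- **Isotonic regression** (classification): nondecreasing least-squares
  fit of labels on probabilities by pool-adjacent-violators; the fitted
  step function is right-continuous and piecewise constant, ties in the
  score are pooled, and outputs are clipped to $[10^{-6}, 1-10^{-6}]$ so
  log scores stay finite.
- **PIT recalibration** (regression): the empirical CDF of calibration
  PIT values $\Phi((y-\mu)/\sigma)$, fitted isotonically against the
  nominal level, defines the monotone correction; recalibrated 1σ
  quantiles are refitted to a Gaussian. Means are deliberately left
  unchanged — only the spread is corrected (see conventions above).
- **Split conformal (CMAP)**: standardized absolute scores
  $|y-\mu|/\sigma$, correction $\hat q$ = the $\lceil(n+1)(1-\alpha)\rceil$-th
  smallest calibration score, intervals $\mu \pm \hat q \sigma$. The
  score function and order statistic are the standard split-conformal
  choices, giving finite-sample marginal coverage $\ge 1-\alpha$ under
  exchangeability (verified by simulation in the tests, 500 replicates).
- **CQR**: scores $\max(q_{lo}-y,\; y-q_{hi})$; the band is widened (or
  shrunk, when $\hat q < 0$) by $\hat q$ on both sides.
- **Venn-ABERS**: for each test score $s$, isotonic fits on the
  calibration set augmented with $(s,0)$ and with $(s,1)$ give the
  bracket $(p_0, p_1)$, merged as $p = p_1/(1-p_0+p_1)$. The underlying
  score defaults to the predicted probability, with the raw logit mean as
  an option, since either is a valid ordering.

The weighted pool-adjacent-violators routine behind the isotonic methods
is implemented in the package (Venn-ABERS needs observation weights and
point evaluation at new scores); it is cross-checked against
`stats::isoreg` in the test suite.

## Metrics

Classification (defaults: 10 bins, squared per-bin discrepancy — absolute
is available for comparison with literature that defines ECE with $|\cdot|$):

| metric | axis / binning | compares |
|---|---|---|
| ECE | confidence, equal-width | mean confidence vs accuracy |
| ACE | confidence, equal-mass | as ECE, adaptive bins |
| smECE | confidence, kernel-smoothed | smoothed residual mass |
| UCE | entropy, equal-width | mean entropy vs error rate |
| VCE | entropy, equal-width | mean entropy vs entropy of accuracy |
| NLL | — | mean $-\ln p(\text{target})$ |
| AUC | — | Mann–Whitney ranking probability |

smECE smooths the residuals $\mathrm{correct}_i - \mathrm{conf}_i$ with a
Gaussian kernel reflected at both ends of $[0,1]$ and integrates the
absolute smoothed mass; the bandwidth solves the fixed point
$\sigma = \mathrm{smECE}(\sigma)$ by bisection on $[10^{-4}, 1]$
(evaluation on a 1001-node grid with nearest-node residual accumulation).
UCE knowingly compares entropy against a misclassification *rate* — not a
like-for-like pair; VCE repairs this by expressing the observed variation
as the binary entropy of within-bin accuracy, which is this package's
concrete choice of variation estimator.

Regression:

- **ENCE** $= \sum_m \frac{n_m}{N} |RMV_m - RMSE_m| / RMV_m$ over
  equal-mass bins of predicted sigma. The normalized, count-weighted form
  is the default — the metric's own name says "normalized" — but both the
  normalization and the weighting are flags, since uniform bin averaging
  is also used in the literature. Equal-mass binning is the default for
  robustness to heavy-tailed sigma distributions.
- **CRPS** via the Gaussian closed form
  $\sigma\left(z(2\Phi(z)-1) + 2\varphi(z) - 1/\sqrt\pi\right)$, verified
  against direct quadrature of the CDF-difference integral to $10^{-6}$.
- **PICP** = empirical coverage divided by nominal coverage, optimum 1.
- **CCE** = mean squared gap between nominal and empirical central
  coverage over a level grid; the default grid is the 19 levels
  $0.05, 0.10, \ldots, 0.95$ (a choice, not a canon — the grid is an
  argument), and the observed curve is returned for plotting.
- **MAE/MASE** with the constant training-median baseline in the
  denominator.
- The **bivariate histogram** of $(\sigma_i, |y_i - \mu_i|)$ exposes
  small-scale reliability: for a reliable model, mass concentrates around
  the diagonal. With half-normal errors the factor-2 diagonal band holds
  $2(\Phi(2)-\Phi(0.5)) \approx 57\%$ of the mass — a useful reference
  value when reading these plots.

## Adaptive evaluation and comparison

`adaptive_evaluate()` computes any registered metric within each group
(typically the ground-truth class) and reports the unweighted macro
average — unweighted because a minority class should not be discounted by
its size. Metrics needing both classes are skipped in single-class groups
with a warning. `bootstrap_compare()` resamples example indices (paired —
both methods see the same replicate), reporting the percentile interval
and a two-sided sign-based p-value clipped to $[1/B, 1]$. Percentile
rather than BCa intervals: the comparison is of simple plug-in statistics
at large $n$, where the refinement is not worth the opacity. Resampling
is at example level; patient-level resampling can be had by passing a
patient column as the group.

## The synthetic test bed

The generators produce prediction sets with *known* defects:

- `simulate_regression(n, c)`: means
  $\mu_i \sim \mathcal N(115.48, 18.92^2)$ (a blood-pressure-like scale),
  true sigmas lognormal with meanlog $\log 12$ and sdlog 0.3 — chosen so
  the residual MAE lands near 10 mmHg, the magnitude reported for real
  cuffless-BP models — targets drawn from the *true* Gaussian, and
  reported variance $(c\,\sigma_{true})^2$. $c=1$ is perfectly calibrated
  by construction; $c = 0.5$ makes RMSE/RMV $= 2$ in every bin, hence
  ENCE $\to 1$ analytically.
- `simulate_classification(n, pos_ratio, T_true)`: true probabilities
  $\pi_i \sim \mathrm{Beta}$ with mean 0.38 (an AF-like imbalance) and
  concentration 2 (spread enough to populate all confidence bins), labels
  $y_i \sim \mathrm{Bernoulli}(\pi_i)$, reported
  $p_i = \mathrm{logistic}(T_{true}\,\mathrm{logit}\,\pi_i)$. Because
  temperature scaling *divides* logits by its fitted $T$, the fit
  recovers $T_{true}$ exactly in expectation; $T_{true} > 1$ produces
  overconfidence. Per-example logit variances are exponential with mean
  0.25 — small relative to the logit range, as dropout-induced spread
  typically is.
- `simulate_ensemble(n, K, jitter)`: member means jittered around a base
  mean, so aggregation must recover total variance = within-member
  variance + jitter² in expectation.

Each generator is a pure function of its arguments: one seed, identical
bytes. What the test bed does *not* emulate: covariate-dependent
miscalibration (the defects here are global and multiplicative),
distribution shift between calibration and test splits (conformal
guarantees assume exchangeability and will degrade under shift), serial
correlation between examples from the same patient, and non-Gaussian
predictive families. Passing the suite therefore demonstrates
correctness of the machinery under controlled defects, not performance
on any particular clinical dataset.

## Numerical choices and degenerate inputs

- Probabilities are clipped to $[10^{-6}, 1-10^{-6}]$ before logits and
  logs; the bias is negligible at realistic scales and every NLL is
  finite.
- Zero-width quantile pairs and intervals are rejected (zero-variance
  errors) rather than silently producing infinite z-scores.
- The conformal correction errors out when
  $\lceil(n+1)(1-\alpha)\rceil > n$ — the requested coverage is
  unattainable at that calibration size.
- Equal-mass bins assign sorted examples to $\lceil r\,B/n\rceil$; ties
  straddling a boundary stay in rank order.
- Test-suite problem sizes: recovery simulations use $n$ between
  $2\times10^4$ and $2\times10^5$; the conformal guarantee uses 500
  replicates at $n_{calib} = 1000$. These sizes put Monte-Carlo error
  well inside the asserted tolerances while keeping the suite quick.

## Known limitations

Binary classification only (no multi-class generalisations of the
calibration metrics); Gaussian parametric assumption in all
interval/quantile conversions; no Mondrian (class-conditional) conformal
variants; Venn-ABERS cost grows as $n_{test}$ isotonic fits of size
$n_{calib}$, fine at clinical-study scale but worth batching beyond
$10^5$ examples; the CLI is a thin wrapper — programmatic use is the
primary interface.
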