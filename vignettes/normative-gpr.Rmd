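---
title: "What the GPR predictive variance measures, and how to correct it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{What the GPR predictive variance measures, and how to correct it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gprnorm)
```

## The problem

A normative model scores an individual observation against a reference
population: a residual `y - y_reference` is divided by a local standard
deviation to produce a z-score, on the understanding that this standard
deviation tracks the *conditional outcome variability* `Var(y | x)` —
aleatoric uncertainty, the irreducible spread of the population itself.

Gaussian process regression is attractive for this purpose because its
posterior comes with a variance at every input. That variance, however, is
the wrong quantity. For a zero-mean GP prior `f ~ GP(0, k)` and observations
`y = f(x) + e`, `e ~ N(0, s2_noise)`, conditioning the joint Gaussian gives

```
mu*(x*)  = K(x*, X) [K(X,X) + S2_train]^-1 y
S2*(x*)  = k(x*, x*) + s2_test - K(x*, X) [K(X,X) + S2_train]^-1 K(X, x*)
```

The outputs `y` appear in the mean but *nowhere in the variance*: `S2*` is a
function of the kernel and the training inputs only. It quantifies epistemic
uncertainty — how well the regression surface is pinned down by the design —
and shrinks as points are added. It cannot, even in principle, track
`Var(y | x)`. Dividing residuals by it ("`z_gpr_only`" in this package)
produces normalized deviations only in the special case where the two
quantities happen to coincide.

The package makes this claim executable in three ways: an algebraic
reduction of the variance that exposes its structure, a synthetic benchmark
where `Var(y | x)` is known exactly, and a corrected decomposition that adds
the missing aleatoric term.

## The SVD quadratic form

Every kernel is an inner product of feature coordinates,
`k(x1, x2) = z(x1) z(x2)^T`. Substituting and applying an SVD to
`S_train^-1 Z(X) = U S V^T`, the predictive variance reduces to

```
S2*(x*) = z(x*) V [I - S^T (S S^T + I)^-1 S] V^T z(x*)^T + s2_test
```

a quadratic form in the feature coordinates of the test point plus a
constant. `V` and the singular values depend only on the training inputs,
the training noise and the feature map. The bracketed matrix has eigenvalues
`1/(s_i^2 + 1)` on the singular directions and 1 on their complement, so it
is positive semi-definite: the variance is never below `s2_test`.
`svd_variance_form()` implements this form; tests assert its equivalence to
direct conditioning to 1e-10 for the exact (linear) feature map and to 1e-6
for the truncated RBF map.

For the 1-D linear kernel the feature map is the identity, there is a single
singular value `s = ||X|| / s_train`, and the form collapses to

```
S2*(x*) = x*^2 / (s^2 + 1) + s2_test
```

(`linear_variance_closed_form()`): a parabola with its minimum `s2_test` at
the origin, wherever the data lie and whatever the outputs are.

### The truncated RBF feature map

The 1-D RBF feature space has coordinates
`z_j(x) = exp(-x^2/(2 l^2)) x^j / (l^j sqrt(j!))`, `j = 0, 1, ...`. The
infinite product `sum_j z_j(x1) z_j(x2)` telescopes to the kernel. The
truncation order is fixed at `J = 40`, which brings the worst-case
truncation error below 1e-10 on `|x| <= pi` with `l = 1` (asserted in the
test suite, together with monotone decrease of the error in `J`). Terms are
accumulated in log space so that `x^j / sqrt(j!)` never overflows. The
printed general multi-index form of the map exists for d > 1, but only the
1-D specialisation is implemented, matching the 1-D benchmark.

## The synthetic benchmark

Four seeded generators create the study conditions (defaults `n = 1000`,
`sigma_noise = 0.05`):

* **Dataset 1** — `(x, f)` bivariate standard normal with correlation 0.75;
  `y = f + e`. Conditional mean `0.75 x`, homoskedastic residuals.
* **Dataset 2** — Dataset 1 with its `x >= 0` half translated along `y = x`
  until that half's maximum input is 0, and the `x < 0` half translated
  until its minimum input is 0: dense at the two outer ends, sparse in the
  middle. Translation along `y = x` preserves every point's `y - x` offset.
* **Dataset 3** — `x`, `y` independently uniform on `[-pi, pi)`:
  reference mean 0, homoskedastic `Var(y|x) = pi^2/3 ~ 3.29`.
* **Dataset 4** — Dataset 3's outputs multiplied by `sin(x)/2 + 1`, inputs
  *identical* to Dataset 3: heteroskedastic
  `Var(y|x) = (sin(x)/2 + 1)^2 pi^2/3`, with a 9-fold variance ratio
  between `x = pi/2` and `x = -pi/2`.

`undersample()` keeps a seeded 5% subset (50 of 1000), and accepts a
pre-drawn index vector so Datasets 3-4 keep sharing inputs after
undersampling. Each generator draws from its own sub-seeded stream
(`seed + dataset offset`) inside a wrapper that restores the caller's RNG
state, so generators never disturb one another and every dataset is
bit-reproducible from `(seed, n)`.

Two generator conventions were open and are fixed as follows. First, the
observation noise for Datasets 1-2 is added on top of the correlated pair
(`y = f + e`); at `sigma_noise = 0.05` against unit signal variance the
alternative reading (0.05 as the model's assumed noise only) is numerically
indistinguishable. Second, Datasets 3-4 also receive the additive
`N(0, 0.05^2)` noise so that all four datasets follow the same observation
model; its variance (0.0025) is negligible against 3.29. Points with
`x = 0` belong to the right-hand subset in the Dataset 2 split.

Because inputs of Datasets 3 and 4 coincide and the predictive variance
depends only on inputs, the variance curves of any fixed kernel on the two
datasets are *identical to machine precision* — a 9-fold difference in true
conditional variance leaves no trace. The test suite asserts this at 1e-12
for all four kernels, on the original and the undersampled pair.

## Two scenarios

**Known noise** (`run_known_noise()`): the generator's noise level is
supplied as `s2_train = s2_test = 0.05^2`, and kernel hyperparameters are
held fixed at `l = 1` (RBF), `nu = 1.5`, `alpha = 1`, `l = 1` (Matern,
rational-quadratic). The linear-kernel variance is the parabola above; the
stationary kernels produce variance curves that track training-input
density (low where dense), with floor `0.05^2`. None of them responds to
the outputs.

**Unknown noise** (`run_unknown_noise()`): the noise variance becomes a
hyperparameter of the hybrid kernel

```
k_hybrid = w_linear k_linear + w_rbf k_rbf + k_white
```

where the white component contributes `s2_noise` on self-covariance
diagonals only (a structural `same` flag on Gram construction, never
floating-point coordinate equality — coordinate matching would be fragile
and would wrongly inject noise into the train/test cross-block).
Hyperparameters `(w_linear, w_rbf, l, s2_noise)` are tuned by maximising
the log marginal likelihood `log N(y; 0, K_hybrid(X,X))`.

On Datasets 3-4 the mean structure is flat and the likelihood drives both
kernel weights toward their lower bound while `s2_noise` absorbs the
*overall* residual variance `Var(y - y_reference)`: about `pi^2/3 ~ 3.29`
on Dataset 3 and `9/8 pi^2/3 ~ 3.70` in expectation on Dataset 4. This is
the central bias phenomenon: the fitted "noise" hyperparameter is an
overall residual variance, which equals the aleatoric variance only under
homoskedasticity. On Dataset 3 the naive z-scores therefore behave; on
Dataset 4 their binned variance still spans the 9-fold envelope.

### Optimizer choices

All four hyperparameters are optimised in log space by L-BFGS-B (numerical
gradients; analytic gradients are unnecessary at n = 1000, d = 1) from 10
log-uniform random restarts, seeded and fully audited (every restart's
start, optimum and convergence code is returned). Bounds are
`[1e-8, 1e2]` for the weights, `[1e-4, 1e2]` for the noise variance, and
`[1e-2, 1e2]` for the length-scale. The length-scale lower bound is a
deliberate identifiability restriction: once `l` falls below the smallest
gap between training inputs, the RBF Gram matrix is exactly the identity,
the kernel is indistinguishable from white noise, and the likelihood is
constant along the ridge `w_rbf + s2_noise = const` — any split of the
noise between the two is equally likely, and the reported noise
hyperparameter becomes meaningless. Bounding `l` at 0.01 (far below any
structure resolvable by 1000 points on a range of order 1, far above the
typical minimum gap of order 1e-5) removes the ridge without constraining
any interpretable fit. The Cholesky factorisation behind every likelihood
evaluation uses jitter escalation from `1e-12 * mean(diag)`, doubling to at
most `1e-6 * mean(diag)` before reporting the system ill-conditioned.

## The corrected decomposition

The usable normative variance adds an aleatoric term to the epistemic one:

```
Var(y* | x*) = S2*(x*) + s2_aleatoric(x*)
```

`estimate_aleatoric_sliding_window()` estimates `s2_aleatoric` as the
sample variance of reference-model residuals inside the half-open window
`[x* - w/2, x* + w/2)` (half-open so boundary points are never double
counted). Defaults: `window = range(X)/10`, `min_points = 20` — the window
width is genuinely a judgment call, so both are configurable and recorded
in the output. Windows holding fewer than `min_points` residuals are
flagged `unreliable` and yield `NA` rather than an extrapolated number:
where data are sparse (the emptied middle of Dataset 2, or outside the
data range) a local variance cannot be estimated honestly, and the flag
propagates through `total_var` and the corrected z-score.

One subtlety governs `include_noise` in `decompose_uncertainty()`. When
the noise level is genuinely known, `S2*` includes `s2_test` and the
decomposition simply adds the aleatoric estimate. But when `s2_noise` was
*fitted*, it has already absorbed `Var(y - y_reference)` — the aleatoric
variance itself — so keeping it inside the epistemic term would count that
variability twice. The corrected pipeline therefore uses the noise-free
epistemic term `k(x*,x*) - K(x*,X)[K(X,X) + S2]^-1 K(X,x*)` in the
unknown-noise scenario (`include_noise = FALSE`). The naive z-score, by
contrast, always divides by the full predictive variance, because that is
the practice under critique. Whether the noise-free term remains a good
epistemic approximation under a biased noise estimate is an open question;
the package exposes it as an experiment (compare
`predict_var(fit, x, include_noise = FALSE)` across scenarios) and asserts
nothing about it.

`run_corrected_pipeline()` chains these steps and appends a diagnostic:
training points are cut into 8 equal-width input bins (bins under 20
points dropped — sized for n = 1000), and the variance of each flavour of
z-score is tabulated per bin. On Dataset 4 the naive scores show a binned
variance ratio of about 9 between bins at `x = +/- pi/2`; the corrected
scores are flat to within sampling noise.

## What the tests do and do not show

All empirical claims in this vignette are computed by the test suite or
the acceptance script at the sizes stated there: the benchmark datasets at
n = 1000 (the study conditions), large-sample checks of the generators and
of sliding-window consistency at n = 1e5 (estimates within 5% of the
analytic envelope `(sin(x)/2+1)^2 pi^2/3` at interior points), and
equivalence of the implementation against an independent GPR
implementation (kernlab) to 1e-6 on small random problems. The generators
emulate the benchmark's idealised conditions — exact distributional forms,
1-D inputs, iid noise, known reference functions. They do not emulate real
normative-modeling data: covariate-dependent sampling density, non-Gaussian
residuals, measurement batch effects, or multi-dimensional covariates.
Passing tests demonstrate the mathematical claims and the estimators'
behaviour under the stated conditions, not performance on such data.

Known limitations: the explicit RBF feature map (and hence the SVD route)
is 1-D; the sliding-window estimator has no principled bandwidth selector
and inherits the usual boundary bias of local variance estimators;
hyperparameter optimisation reports local optima of a multimodal
likelihood (mitigated, not solved, by restarts); and printed hyperparameter
values other than the noise variance — in particular the RBF length-scale
when its weight is near zero — are not reproducible quantities, since the
likelihood is flat in them.
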