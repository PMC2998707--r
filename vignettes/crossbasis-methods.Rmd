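---
title: "Modelling delayed non-linear exposure effects with cross-bases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling delayed non-linear exposure effects with cross-bases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(distlag)
```

## The model

Daily counts $Y_t$ are assumed overdispersed Poisson, $E(Y_t)=\mu_t$,
$V(Y_t)=\varphi\mu_t$, with log link. The linear predictor contains
confounder terms (a smooth function of calendar time for season and trend,
day-of-week indicators, further covariates) plus a term describing the
exposure of interest in two dimensions at once: the shape of the
exposure–response relationship and its distribution over lags
$\ell = 0,\dots,L$.

Write $z(x) \in \mathbb{R}^{v_x}$ for a basis in the space of the
exposure, and $c(\ell) \in \mathbb{R}^{v_\ell}$ for a basis evaluated on
the integer lag vector. The *cross-basis* is the set of
$v_x \cdot v_\ell$ product functions; its design matrix has entries
$$ w_{t,(j,k)} \;=\; \sum_{\ell=0}^{L} z_j(x_{t-\ell})\, c_k(\ell). $$
Columns are stored predictor-basis-major, index $(j-1)v_\ell + k$, named
`v<j>.l<k>`; the order is arbitrary in principle but must be mirrored
exactly at prediction time, so it is fixed, recorded in the object, and
verified when a fit is matched to a cross-basis.

The construction is symmetric — lagging the transformed series or
transforming the lagged series gives the same matrix — and the test suite
asserts this property as well as cell-by-cell agreement with a naive
quadruple loop over $(t, j, k, \ell)$.

This parameterization nests the familiar models. With a linear exposure
basis ($v_x = 1$, $z(x) = x$): an identity lag basis (one indicator per
lag) gives the unconstrained distributed lag model, whose design matrix is
exactly the lag matrix $Q$ with $q_{t\ell} = x_{t-\ell}$; a constant lag
basis gives the lag-sum model, i.e. $(L+1)$ times the moving average. The
sum is deliberately exposed unscaled — the general formula with a constant
basis literally yields the sum — and the coefficient relationship
$\hat\beta_{MA} = (L+1)\hat\beta_{sum}$ is documented and tested rather
than hidden behind a rescaling. For the constrained DLM the implied
per-unit lag effects are recovered as $\hat\beta = C\hat\eta$, which the
prediction machinery reproduces exactly.

## One-dimensional bases

`basis_spec()` declares a basis; `evaluate_basis()` materializes it on
data. Available kinds: linear, polynomial, natural cubic spline, linear
threshold (hockey stick), strata (interval indicators), constant, and
identity (lag space only). Natural cubic splines are built from a B-spline
representation with natural boundary constraints (via `splines::ns`);
their function space is validated in the tests against an independent
truncated-power-basis construction, together with the defining property
that the second derivative vanishes at and beyond the boundary knots
(linear extrapolation).

The degrees-of-freedom convention is
$df = \#\text{internal knots} + 1$, plus one if an intercept is included.
Under this convention an 11-df exposure spline crossed with a 5-df lag
spline spends $11 \times 5 = 55$ parameters, and a 5-df/5-df pairing 25 —
the bookkeeping by which model complexity is reported and compared.

Where the intercept lives is a genuine convention choice: only the product
$v_x v_\ell$ is constrained by the parameter count. Here neither basis
takes an intercept unless asked; analyses in this package's examples give
the *lag* basis the intercept (`intercept = TRUE`), so that effects
constant in $\ell$ are representable while the exposure-space intercept
remains absorbed by the model's own intercept. Either choice yields the
same column counts.

Knot placement defaults: in the exposure space, equally spaced values
across the observed range (an equally-spaced-quantiles option exists, the
usual choice for humidity-type covariates); in the lag space, knots
equally spaced on the log scale of lags, $\exp(\text{equally spaced in }
[\log 1, \log L])$, giving more resolution at short lags where effects
change fastest. Lag 0 always lies inside the first interval; the boundary
knots of a lag spline are 0 and $L$. All materialized knots are recorded
in the returned spec so that the identical transform can be rebuilt at
prediction time, and the full recipe (both specs, $L$, exposure range,
column order) serializes to JSON and is embedded in every output bundle.
In-memory rebuilds from the same inputs are bit-identical; a JSON
round-trip preserves knots only to the last unit of least precision, so
reconstruction from serialized recipes is exact to about $10^{-12}$ —
far below any statistical resolution.

Missing exposures propagate to missing basis rows, and any missing value
inside a lag window makes that cross-basis row missing; in particular the
first $L$ rows are always missing. This is a deliberate refusal to invent
pre-sample exposure history; fitting simply drops incomplete rows
(`n - L` complete rows for a complete series).

## Fitting and the extraction contract

The package does not implement GLM fitting: the cross-basis matrix is an
ordinary design-matrix block, and any backend that returns coefficients, a
covariance matrix, a dispersion estimate and a likelihood can stand behind
it (`stats::glm` with `family = quasipoisson()` is the default route).
`extract_fit()` pulls out the cross-basis sub-vector and sub-matrix by
column name — robust to reordering and to other covariates — and records
dispersion, log-likelihood, sample size and the total mean-model parameter
count. For quasi-likelihood fits no likelihood exists; the Poisson
log-likelihood at the fitted means is used, the convention of the
criteria below, and flagged as such in serialized output. Fits can also
be imported from plain interchange files (`coef.csv`, `vcov.csv`,
`scalars.json`), with order restored by name, so estimation can happen in
any environment.

Model comparison across basis dimensions uses dispersion-adjusted
criteria,
$$ QAIC = -2\mathcal{L} + 2\hat\varphi k, \qquad
   QBIC = -2\mathcal{L} + \log(n)\,\hat\varphi k, $$
with $k$ counting *all* mean-model parameters (confounders included,
since whole models are compared). At $\hat\varphi = 1$ they reduce to
AIC/BIC exactly, which the tests verify against `stats::AIC`/`BIC`.
`run_model_search()` tabulates both criteria over a df grid and flags each
criterion's minimizer without auto-selecting when they disagree — the
larger-penalty QBIC will often prefer the smaller model, and that tension
is a parsimony judgement for the analyst, not the software.

## Prediction

Effects are reported as contrasts against a reference exposure
$x_{ref}$: the contrast vector for cell $(x_p, \ell)$ is
$a(x_p,\ell) = (z(x_p) - z(x_{ref})) \otimes c(\ell)$ in the stored column
order, giving effect $a^\top\hat\eta$ and standard error
$\sqrt{a^\top V(\hat\eta) a}$. The overall effect at $x_p$ uses
$a_{tot} = \sum_\ell a(x_p,\ell)$, so its variance carries all
covariances among coefficients — materially different from summing
per-lag variances, and validated in the tests against a 100,000-draw
Monte-Carlo simulation from $N(\hat\eta, V)$. Centering is the default
because exponentiated contrasts are the only interpretable relative
risks for curved bases; an uncentered mode exists for bases through the
origin (linear, threshold), where effects per unit of exposure are
meaningful on their own.

In the prediction array the transformed exposure is repeated across lags:
the grid answers "what is the effect profile of a day at $x_p$", not
"what happens after this particular exposure sequence". The default grid
is 50 equally spaced exposures over the observed range plus any values the
user adds (percentile-based summaries being typical). Values outside the
observed range are permitted with a warning; natural splines extrapolate
linearly there by construction. Confidence intervals use normal
quantiles (1.96 at 95%) — sample sizes in this field are in the
thousands, so no small-sample correction is applied. The covariance
matrix is checked for positive semidefiniteness (eigenvalue tolerance
$10^{-8}$ relative) before any quadratic form is computed, and the
reference row of a grid is identically zero with zero standard error.

## The synthetic-data generator

Validation needs data with known truth. The generator emulates the
structure of an environmental time-series study:

* **Exposure**: $x_t = \mu_x + A\cos(2\pi t/365.25) + e_t$, with $e_t$ a
  stationary AR(1) process parameterized by its lag-1 autocorrelation
  $\rho$ and *marginal* sd. Defaults ($\mu_x = 12$, $A = 8$, sd $= 3$,
  $\rho = 0.7$) give a mid-latitude temperature-like series.
* **Outcome**: $\log \mu_t$ adds a baseline (intercept $\log 50$, mild
  seasonal cycle of amplitude 0.15, optional trend) and the accumulated
  surface contributions $\sum_{\ell} f(x_{t-\ell}, \ell)$. Counts are
  Poisson at dispersion 1, otherwise negative binomial with
  $V(Y) = \varphi\mu$ (quasi-Poisson defines no generative law; the
  negative binomial is the standard stand-in). The default
  $\varphi = 1.5$ matches typical city mortality series.
* **Surface presets**: null; linear $\times$ exponential decay; U-shape
  $\times$ exponential decay; and a U-shape whose heat arm acts
  immediately while the cold arm peaks at lag 2–3 and persists — echoing
  the qualitative temperature–mortality shapes reported in this
  literature without claiming any published numbers. Surfaces are stored
  as contrasts ($f(x_{ref}, \ell) = 0$), which `sim_config()` enforces.

Every draw is determined by the seed (the count stream is offset by one
from the exposure stream so the pair is jointly reproducible). The first
$L$ days are emitted but flagged burn-in, and excluded from fitting.

What the generator does *not* emulate: multi-pollutant confounding,
measurement error, missing data runs, autocorrelated outcome residuals
beyond what the exposure process induces, or harvesting feedback (the
surface is exogenous). Passing recovery tests therefore demonstrates
correctness of the estimation machinery under a correctly specified
model, not robustness to the full messiness of observational series.

## Validation design and numerical choices

The statistical acceptance checks in the test suite are sized to run in a
couple of minutes on one core, and their designs are worth recording:

* **Coverage**: 200 series of $n = 5000$ days from the U-shape/decay
  surface at $\varphi = 1.5$, $L = 10$, fitted with a quadratic exposure
  basis and an *identity* lag basis plus annual harmonics. With the truth
  exactly representable at integer lags, pointwise 95% intervals should
  cover at their nominal rate; pooled coverage is required to fall in
  [0.93, 0.97]. An exactly specified design is used deliberately: spline
  approximation bias is a modelling trade-off, not an estimator defect,
  and would contaminate a calibration check.
* **Error shrinkage**: the overall-contrast mean absolute error at
  $n = 5000$ (200 replicates) must undercut that at $n = 1000$
  (100 replicates).
* **Variance algebra**: analytic overall-effect standard errors against a
  $10^5$-draw Monte-Carlo within 2% (Monte-Carlo error of the sd itself
  is about 0.2%).
* **Reductions**: the DLM special cases above to $10^{-10}$, brute-force
  cross-basis agreement to $10^{-12}$, criteria reductions to machine
  precision.

Degenerate inputs are handled explicitly: non-increasing knots, identity
bases on non-integer values, lags exceeding the series length,
all-missing exposures and non-positive dispersions are errors; knots
outside the data range and out-of-range prediction exposures are
warnings; spline knots derived from too few distinct values fail with a
pointer to reduce the df.

## Limitations

* Completely parametric bases: no penalized/low-rank smoothers or
  tensor-product penalties, and no nonparametric GAM representation of
  the confounder smooths.
* Regular daily series only; no cohort-style per-subject exposure
  histories, and no irregular spacing.
* The identity lag basis at large $L$ inherits the collinearity of
  day-to-day exposures; its per-lag estimates are imprecise by nature,
  which is precisely the motivation for smooth lag constraints.
* Quasi-Poisson inference relies on large-$n$ asymptotics; the normal
  intervals carry no small-sample correction.
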