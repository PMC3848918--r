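---
title: "Growth-curve models and bounded estimation: methods"
author: "GrowthCurveFit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-curve models and bounded estimation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GrowthCurveFit)
```

This vignette is the package's own account of its science: the models and
their assumptions, how the bounded estimator works and why it is built the
way it is, what the synthetic-data generator does and does not emulate, and
the numerical choices that matter in practice.

## The problem

A growth curve is a time series of population size or a biomass proxy —
optical density for bacteria in a plate reader, radius or weight for a
tumor — passing through lag, exponential and stationary phases. The
quantities experimentalists want are the maximum specific growth rate
$\mu_{max}$ (the largest slope of log-population versus time), the lag
time $\lambda$ (the intercept of the maximal-slope tangent with the
baseline) and the asymptotic maximum $A$. Different laboratories favour
different parametric families, so the package treats the model catalogue
as data: every model is a registry entry with the same two-function
contract (simulate, estimate), and fits are compared on one common scale,
the root mean square error.

## The model catalogue

**Gompertz, logistic, Richards.** All three sigmoids use the
growth-parameter reparameterization in $(A, \mu_{max}, \lambda)$ so that
the fitted quantities are directly the biological ones:

$$y_G(t) = A\,\exp\!\big[-\exp\big(\tfrac{\mu_{max} e}{A}(\lambda - t) + 1\big)\big],
\qquad
y_L(t) = \frac{A}{1 + \exp\big(\tfrac{4\mu_{max}}{A}(\lambda - t) + 2\big)}$$

$$y_R(t) = A\,\big[1 + v\,e^{1+v}\exp\big(\tfrac{\mu_{max}}{A}(1+v)^{1+1/v}(\lambda - t)\big)\big]^{-1/v}$$

Richards adds a shape parameter $v > 0$ and reduces exactly to the
logistic at $v = 1$ (a property the tests assert). Useful identities:
$y_G(\lambda) = A e^{-e}$ and $y_L(\lambda) = A/(1+e^2)$.

**Baranyi.** The adaptation-function model on the log-population scale,

$$y(t) = y_0 + \mu_{max} A(t) - \frac{1}{m}\ln\!\Big(1 +
  \frac{e^{m \mu_{max} A(t)} - 1}{e^{m(y_{max}-y_0)}}\Big),
\qquad
A(t) = t + \frac{1}{\rho}\ln\big(e^{-vt} + e^{-h_0} - e^{-vt-h_0}\big),$$

where $h_0$ encodes the initial physiological state of the inoculum and
$v$ the adaptation rate. Two conventions circulate for the rate $\rho$
dividing the log in $A(t)$: the package's default `baranyi` uses
$\rho = \mu_{max}$, and `baranyi_classic` uses $\rho = v$ as in the
original Baranyi–Roberts formulation. Both are registered because
published fits exist under both readings and they coincide when
$v = \mu_{max}$; the default follows the form the package's catalogue
documents. Note $y(0) = y_0$ and $y(\infty) = y_{max}$ exactly.

**Hyperbolastic type III (H3).** A flexible saturating law used for tumor
growth,

$$P(t) = M - \alpha\exp\!\big(-\delta t^{\gamma} - \mathrm{arcsinh}(\theta t)\big),
\qquad
\alpha = (M - P_0)\exp\!\big(\delta t_0^{\gamma} + \mathrm{arcsinh}(\theta t_0)\big).$$

$\alpha$ is never a free parameter: it is recomputed from the initial
condition $P(t_0) = P_0$, so the curve passes through the initial point
exactly by construction. With $\theta = 0$ and $\gamma = 1$ the curve
degenerates to plain exponential saturation; this is permitted and not
special-cased. Because $t^\gamma$ is undefined for negative $t$ at
non-integer $\gamma$, negative times raise a domain error in that case.

**Live cell fraction (LCF).** An ODE for the radius of a tumor spheroid in
which only a viable rim of depth $\lambda$ proliferates at rate $\alpha$
while cells die everywhere at rate $\delta$:

$$\frac{dr}{dt} = \frac{r}{3}\Big(\frac{(\alpha+\delta)\,3\lambda}{3\lambda + r} - \delta\Big).$$

The unique positive fixed point is $r^* = 3\lambda\alpha/\delta$;
trajectories approach it monotonically from either side, and for
$r \ll 3\lambda$ growth is exponential at rate $\alpha/3$.

**Baselines.** First- and second-order polynomials and exponential decay
$y(t) = c + (y_0 - c)e^{-kt}$ round out the catalogue as reference models
for comparison. The exponential-decay form is the standard offset decay;
the offset $c$ lets plateauing death-phase data be described without
forcing decay to zero. The manual log-linear regression —
`manualLogRegression()` — is the traditional estimate: ordinary least
squares of $\ln y$ on $t$ restricted to a user-chosen window, whose slope
is the specific growth rate.

## Estimation

The estimator minimizes the sum of squared residuals between the data and
the simulated curve over the box defined by the parameter specs
(`parameterSpec()`), using Levenberg–Marquardt with box constraints
(`minpack.lm::nls.lm`). The paper-level contract "a range set for the
parameters" maps to these box constraints.

Design choices that matter:

* **Multi-start.** Growth-model likelihoods are multimodal. The default
  budget is 20 starts: the first is the default guess (configured value,
  else the midpoint of the box in optimization space; initial-condition
  parameters start at the first observed value), the rest a Latin
  hypercube over the box, seeded from `fitOptions(seed=)`. All starts in
  the budget are run and the lowest cost wins, ties broken by start
  order; this is deterministic and guards against multimodality better
  than stopping at the first success. A fit is flagged non-converged when
  the winning start did not report optimizer success.
* **Log-scale parameters.** Positive parameters whose range spans at
  least one decade (rates, scale coefficients) are searched and optimized
  on the log scale: starts are log-uniform and LM steps act on
  $\log\theta$. This matters for H3, whose rate coefficient $\delta$ is
  of order $10^{-9}$ while $\gamma$ is of order 1: in linear space the
  $\delta$–$\gamma$ trade-off forms a sharply curved valley that pins
  $\delta$ against the box edge, while in log space the valley is nearly
  straight and reliably descended.
* **Polish step.** After the multi-start loop the winner is refined once
  at machine-level tolerances with a wider finite-difference step
  (`epsfcn = 1e-8`); the default $\sqrt{\varepsilon}$ jacobian step
  limits parameter accuracy to about $10^{-9}$.
* **Linear models are solved linearly.** The polynomial models carry
  their own contract estimator that solves the normal equations by QR —
  a squared-error cost cannot numerically distinguish parameter vectors
  closer than $\sim 10^{-9}$, so an iterative optimizer can never match
  the closed form to $10^{-10}$; the exact solve can. Pins, log-scale
  fitting, rank deficiency or active bounds fall back to the generic
  bounded estimator.
* **Fit scale.** Residuals are formed on the raw signal scale by default;
  `fitOptions(scale = "log")` fits on the natural-log scale instead,
  since microbiology practice varies. The reported RMSE is always on the
  raw scale, and always equals an independent recomputation from the
  stored fitted curve — there is no cached value to drift.
* **RMSE denominator is $n$,** not $n - p$: RMSE serves as a baseline for
  comparing models with different parameter counts, and a
  degrees-of-freedom correction would mix parsimony into a quantity used
  purely as a goodness-of-fit baseline. No AIC/BIC is offered — RMSE
  ranking is deliberately the only comparison criterion.
* **Pooled (aggregate) fitting** concatenates the residuals of all
  replicate series, so replicates are weighted by their point counts.
  With one dataset it is bit-identical to the single fit. Equal-weighting
  of replicates regardless of length was considered and rejected: pooled
  least squares answers "one average model for all observed points",
  which is the natural reading of simultaneous estimation of replicates.
* **Input hygiene.** Non-finite values are rejected at entry, never
  silently dropped. Constant-valued series and series with fewer points
  than free parameters are refused as degenerate. Pinned parameters
  (`fitOptions(pin=)`) are held fixed and must lie inside their range.

Convergence bookkeeping: optimizer cost tolerance `ftol = 1e-10`
(parameter tolerance capped at $10^{-12}$), iteration cap 1000 per start.
LM termination codes 1–4, 6, 7 count as success; reaching the iteration
cap does not.

## ODE integration

The LCF trajectory is integrated with `deSolve` (lsoda) at relative
tolerance $10^{-8}$ and absolute tolerance $10^{-10}$, overridable per
call in `lcfSimulate()`. These defaults keep solver error orders of
magnitude below fitting error: on a 40-time-unit horizon the default
solve stays within $10^{-6}$ of a solve 100× tighter (asserted in the
tests against a frozen external high-precision reference). Solver
failures (step-size underflow, non-finite states) raise an integration
error carrying the solver diagnostic rather than returning a partial
curve.

All `exp()` arguments throughout the catalogue are clamped to $\pm 700$,
just inside the double-precision overflow boundary, so extreme inputs
saturate at the model's asymptote instead of producing `Inf`/`NaN`.

## The synthetic-data generator

`generateCurve()` simulates a registered model on a regular grid and
perturbs the values — never the times — with either additive Gaussian
noise or multiplicative lognormal noise
($y \cdot e^{N(0,\sigma^2)}$, positivity-preserving so log-scale fitting
stays well-defined). Each replicate draws from its own substream whose
seed is derived deterministically from the spec seed, and the manifest
records truth, grid, noise and all seeds, so any dataset can be
regenerated byte-identically.

The default benchmark suite (`makeBenchmarkSuite()`) writes one noisy CSV
per dynamic model. Its conditions are the package's study conditions: a
plate-reader-like grid of 97 points over 48 h with $\sigma = 0.02$ OD of
additive noise for the three-parameter sigmoids (a typical shaken
microplate noise floor); a denser 0–24 h grid with $\sigma = 0.05$ on the
log-population scale for the Baranyi variants; a 0–60 day grid with
$\sigma = 0.05$ for the H3 tumor-weight curve at the benchmark parameter
set $(M = 7.547,\ \delta = 5.103\times 10^{-9},\ \gamma = 4.630,\
\theta = 0.004)$; 41 daily points for the LCF spheroid; and a 0–20 h
decay series. These values were chosen once as field-realistic and are
not tuned.

What the generator does *not* emulate: plate-reader artifacts such as
evaporation drift, edge effects, condensation steps, or heteroscedastic
noise growing with the signal. Passing the recovery and noise-consistency
tests therefore demonstrates the estimator's correctness under clean
sampling assumptions, not robustness to instrument pathology; real data
should still be inspected against the fitted curve.

## Data store

The hierarchy mirrors three layers: *projects* define global properties,
*experiments* aggregate results in folders, *measurements* hold the actual
data and may carry a third numeric dimension plus per-row free-text
annotations. Only (time, value) ever reach a model; the third dimension
and annotations are stored verbatim and round-tripped untouched (the tests
verify that fitting with and without them is bit-identical). Persistence
is plain CSV for data and JSON for metadata and fit results — diffable,
serverless, and lossless: numeric fields are written with shortest
round-trip formatting (15 significant digits, escalating to 17 when
needed), and JSON doubles with 17 significant digits.

Import rules: delimiter auto-detected among comma, semicolon and tab; a
single header line auto-detected; rows sorted by time with pairing
preserved; duplicate time points rejected — replicates belong in separate
measurements, which is what pooled fitting consumes. Times are arbitrary
real numbers; no date parsing, and unit tracking is the user's metadata.

## The plugin contract

A model extension implements exactly two functions: simulation
(parameters + times → curve) and, optionally, estimation (data + ranges +
options → fit result); models without their own estimator inherit the
generic bounded one. `validateContract()` probes a definition at its
default guesses on a 25-point grid and reports per-clause pass/fail
(finite output, length agreement, determinism, estimates within bounds)
instead of throwing, so broken plugins are diagnosable. The registry is an
immutable value: registration returns a new registry, and simulate/fit
calls never mutate it. The catalogue's default search ranges ship as a
YAML metadata file (`inst/extdata/model_ranges.yaml`) with units
documented inline.

## Problem sizes and limitations

The shipped tests and the acceptance script run recovery at about 100
points per series, 20 optimizer starts, 20 noise replicates of 200 points
for the RMSE-consistency check, and a 61-point benchmark grid for H3 —
sizes chosen to exercise every code path at interactive speed on one core.

Known limitations:

* No confidence intervals or bootstrap on parameters; point estimates and
  RMSE only.
* No weighted regression or heteroscedastic noise models in the
  objective.
* The Lumry–Eyring LENP type Ib aggregation model has a natural home in
  the registry but no built-in implementation; users can register their
  own.
* H3's $\delta$ and $\gamma$ are strongly correlated; with short or
  truncated series several $(\delta, \gamma)$ pairs fit almost equally
  well, and only $M$ and $\gamma$ should be interpreted with confidence
  unless the series covers the inflection.
* The estimator treats the time grid as exact; timing jitter in the
  instrument is absorbed into the residuals.
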