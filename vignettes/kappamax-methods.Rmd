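---
title: "Flux calculation schemes for static chambers: models, decisions and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flux calculation schemes for static chambers: models, decisions and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kappamax)
```

## The measurement and the model

A static chamber traps the soil-atmosphere gas exchange in a known
headspace.  If the soil source were unaffected by the chamber, the
concentration would rise linearly with slope `f0 / h` (flux over
effective height).  In reality the accumulating headspace concentration
flattens the diffusion gradient, and lateral transport and small leaks
flatten the curve further.  The Hutchinson–Mosier (HMR) model lumps all
of these into one exponential saturation,

$$C(t) = \varphi + \frac{f_0\,e^{-\kappa t}}{-\kappa h},$$

with $\varphi$ the concentration the chamber converges to, $f_0$ the
initial (undisturbed) flux and $\kappa > 0$ the nonlinearity parameter.
As $\kappa \to 0$ the curve degenerates to the straight line of slope
$f_0/h$; the instantaneous flux at time $t$ is $f_0 e^{-\kappa t}$.
The model is an approximation, not a diffusion simulation: it assumes a
pseudo-steady source at fixed depth, vertically uniform soil, and
exponential relaxation.  Its virtue is that one parameter spans
everything from near-linear to strongly saturating curves.

**Units.**  All computation uses seconds, ppb and nmol.  Fluxes are
nmol s⁻¹ m⁻²; the ppb ↔ nmol m⁻³ conversion uses the ideal gas law at
the system's temperature and pressure (defaults 293.15 K and
101 325 Pa — chamber studies rarely report the conditions of this
conversion, so they are explicit, configurable fields of
`chamber_system()`).  The effective height defaults to volume/area with
an explicit override, because deployed chambers often sit on extension
rings that change the quotient.

## Base estimators

`fit_linear()` is ordinary least squares of concentration on time; the
flux is the slope times height times the gas-law conversion.
`fit_robust_linear()` is a Huber M-estimator (tuning constant 1.345)
iterated by reweighted least squares with the scale re-estimated each
iteration from the median absolute residual; with the minimal four
samples the first and last point always keep full weight, because at
n = 4 down-weighting an endpoint lets a single middle outlier leverage
the slope arbitrarily.  The IRLS stops at a 10⁻⁶ relative coefficient
change or 100 iterations (the degenerate exact-line-plus-outlier corner
converges geometrically and needs about 55); on non-convergence the OLS
fit is returned and flagged.

`fit_hmr()` exploits that for fixed $\kappa$ the model is linear in
$(\varphi, \beta)$ with $\beta = f_0/(-\kappa h)$, so the conditional
least-squares solution (`hmr_profile_sse()`) is exact and the whole
problem reduces to a one-dimensional search in $\kappa$.

### What counts as a converged HMR fit

The profile $SSE(\kappa)$ always has two boundary asymptotes: at
$\kappa \to 0$ it approaches the linear-fit SSE, and at
$\kappa \to \infty$ the regressor $e^{-\kappa t}$ collapses to an
indicator of the first sample and the SSE approaches the "two-level"
fit (first point exact, remaining points at their mean).  In floating
point the large-$\kappa$ tail is *exactly* flat once the exponential
underflows, and a naive global minimiser happily reports a point on
that plateau as an interior optimum.  Such "fits" are scientifically
meaningless — the implied flux $f_0 = -\beta\kappa h$ grows linearly in
$\kappa$ with no data support — and on pure-noise series they inflate
upper flux quantiles by an order of magnitude.

`fit_hmr()` therefore implements the nonlinear fit the way the original
tools describe it, as a *local* optimisation from a starting value:

1. scan the profile on a 101-point log-spaced grid over
   $\kappa \in [10^{-7}, 1]$ s⁻¹ (one decade beyond the commonly
   observed range on each side, wide enough to detect boundary
   non-convergence);
2. walk downhill from the mild-curvature start
   $\kappa_0 = \ln(1.5)/t_{range}$ (the $\kappa$ at which the
   exponential decays by a third over the deployment) to the nearest
   grid minimum;
3. accept only a **strict** interior minimum — both neighbours strictly
   larger, which a flat underflow plateau can never satisfy — and
   refine it by 1-D minimisation on $\log\kappa$ (about 10⁻⁶ relative);
4. declare convergence only if the refined $\kappa$ is strictly inside
   the bounds and its SSE is below *both* boundary asymptotes.

Exactly linear series have no interior optimum and correctly return
`converged = FALSE`; every decision scheme then falls back to the
linear estimate, which is part of the scheme, not an error.  Noiseless
curved series are inverted to better than 10⁻⁴ relative error in all
three parameters (the test suite checks this, along with agreement of
the median fitted flux with a dense 10⁴-point global-grid oracle on
noisy replicates).

**AIC.**  Model comparison uses $n\log(SSE/n) + 2k$ with $k$ counting
the error variance: 3 for the linear fits, 4 for HMR.  An SSE floor of
$(10^{-6}\ \text{ppb})^2 n$ keeps the criterion finite on noiseless
fixtures.  The small-sample correction AICc is *not* used: at n = 4 its
linear-model term divides by $n - k - 1 = 0$.

## Decision schemes

All schemes choose between the linear and the HMR flux of the same
closure (`RLM` uses the robust slope instead of OLS).  `HMR` takes the
nonlinear estimate whenever it converged; `AIC` additionally requires
the lower AIC; `GFACTOR` rejects HMR fits whose flux magnitude exceeds
`g_max` (default 4) times the absolute linear estimate; `FIXEDKAPPA`
rejects fitted $\kappa$ above a fixed threshold quoted in h⁻¹ (default
20, converted internally to s⁻¹) — the published fixed-threshold
practice the dynamic rule is meant to replace.

The **kappa.max** rule bounds the fitted nonlinearity by

$$\kappa_{max} = \frac{|f_{lin}|}{f_{det}\; t_{meas}},$$

which follows from expressing the equilibrium concentration $\varphi$
at the detection-limit boundary condition: when the linear flux equals
the minimal detectable flux, the acceptable curvature collapses to
$1/t_{meas}$, and it scales linearly in the flux from there.  Design
choices: the absolute value extends the rule symmetrically to uptake
fluxes; $t_{meas}$ is the time difference between first and last sample
(with a config override, since this factor is the least settled part of
the rule); a fitted $\kappa$ exactly at the threshold is accepted — the
bound is an upper limit, and ties occur with probability zero on real
data.  In the limits the rule behaves correctly: $f_{det} \to \infty$
reproduces `LR` on every series, $f_{det} \to 0$ reproduces `HMR`
(both are tested exactly).

## The minimal detectable flux

`simulate_f_det()` prescribes a zero flux, generates `n_sim` (default
1000) closures of ambient concentration plus i.i.d. Gaussian noise of
the instrument's `sd_gc`, runs the chosen scheme on each, and takes an
upper empirical quantile (type-7, linear interpolation) of the signed
flux distribution.  Defaults: quantile 0.975 and the HMR scheme with
linear fallback, the population the kappa.max rule is defined on;
`population = "hmr_only"` restricts to converged fits, and an
absolute-value option exists, because reported detection limits in the
literature are not always explicit about either choice.  For the LR
scheme the zero-flux estimate is exactly normal, giving the closed-form
oracle `analytic_f_det_linear()` =
$z_q\, sd_{GC}/\sqrt{\sum(t-\bar t)^2}\; h\, p/(RT)$ against which the
simulation is tested (within three standard errors of the empirical
quantile).  `KAPPAMAX` is rejected as a bare detection-limit scheme —
its threshold consumes an f_det — and must be given one explicitly,
conventionally the HMR-based value.

## The simulation framework

`run_grid()` simulates, for every cell of a (f0 × κ) grid, `n_mc` noisy
closures and judges the *same* series under every scheme (base fits are
computed once), so scheme contrasts are paired.  Per cell it stores the
median and mean estimate, IQ90 (95th − 5th percentile), bias (mean −
true f0), population variance, MSE (= bias² + variance, exactly, by
construction), and the fraction of replicates in which the HMR estimate
was selected.  Default grid: 25 flux levels — 0 plus a log-spaced
sequence from 0.01 to 5 nmol s⁻¹ m⁻², since field flux distributions
are right-skewed with a mass of near-zero values — and 25 log-spaced κ
from 10⁻⁶ to 10⁻² s⁻¹, 50 replicates per cell.  Reproducibility uses
one master seed with per-cell substreams derived by counter, so results
do not depend on evaluation order (re-running a scheme twice in one
call is bit-identical; tested).

`sweep_parameter()` re-runs the grid across instrument precisions
(`sd_gc`) or deployment times (`t_max`, minutes; the four sample times
rescale to 0, t/3, 2t/3, t, mirroring the equidistant case-study
protocol).  For kappa.max the f_det is re-simulated per swept value —
it depends on both parameters.

`project_dataset()` bins a processed dataset's (flux, fitted κ) pairs
onto the grid: cell edges sit at geometric midpoints between grid
values (arithmetic midpoint against a zero grid value), fluxes beyond
the range land in the extreme flux bin, and closures without a fitted κ
land in the largest-κ row (they were calculated linearly).  Count-
weighted cell metrics then estimate the uncertainty, bias and MSE the
scheme imposes on that particular dataset.

## The fixture generator

`generate_fixture_dataset()` emulates a multi-year manual-chamber N₂O
campaign: true fluxes from a log-normal (meanlog = log 0.15,
sdlog = 1.2) clipped to [0.01, 5] nmol s⁻¹ m⁻² with a 10 % point mass
of exact zeros — reproducing the scale of arable N₂O datasets whose
linear-mean flux sits around 0.2 nmol s⁻¹ m⁻² — and κ log-uniform over
[10⁻⁶, 10⁻²] s⁻¹.  It returns the noisy series *and* the ground truth,
enabling parameter-recovery tests (with sd_gc = 0.5 ppb the median
relative κ error for κ ∈ [10⁻⁴, 10⁻³] stays below 25 %; tested).

What the generator deliberately does **not** emulate: curvature shapes
outside the HMR family, heteroscedastic or correlated noise, drifting
baselines, vial-handling blunders, or any dependence of κ on soil
state.  Tests passing on these fixtures therefore demonstrate that the
estimators and decision rules behave as designed *under the model's own
assumptions* — they do not certify performance on data that violates
them, which is precisely why the projection tools exist: they let users
see where their data falls in the (f0, κ) plane and how much scheme
uncertainty lives there.

## Problem sizes and numerical tolerances used by the tests

The test suite exercises the framework at sizes chosen to keep the full
run in a few minutes while leaving Monte-Carlo error well below the
asserted effects: detection limits at n_sim = 1000; scheme-ranking and
map checks on 13 × 13 grids with 20 replicates per cell; sensitivity
sweeps on 9 × 9 grids with 15 replicates; a 5470-closure fixture for
the campaign-scale ordering checks.  Exact identities (MSE
decomposition, threshold limits, noiseless inversion, OLS oracle) are
asserted at 10⁻¹²–10⁻¹⁴; stochastic comparisons carry tolerances
derived from their quantile standard errors.

## Known limitations

* With four samples the HMR fit has one residual degree of freedom;
  goodness-of-fit statistics (AIC included) discriminate weakly, and
  the detection limits of the nonlinear schemes are upper quantiles of
  heavy-tailed distributions — expect double-digit percent variation
  between simulation runs at n_sim = 1000.
* The conditional (fixed-κ) standard error reported for HMR fluxes
  understates the full uncertainty because it ignores the κ estimation
  error; treat it as a lower bound.
* The kappa.max rule inherits every limitation of its f_det input: an
  optimistic detection limit loosens the restriction.
* Chamber-bias corrections based on soil diffusion modelling, quadratic
  regression, and gap-filling of time series are out of scope.
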